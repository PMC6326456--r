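# Regenerates the small packaged fixture under inst/extdata from the
# synthetic-data generator (fixed seed). Run from the package root.
# Ground truth is not packaged: tests regenerate it with the same seed.
library(nutricate)

cfg <- simulation_config(n_children = 300, n_clusters_per_round = 12,
                         seed = 613L)
pop <- generate_population(cfg)
ref <- generate_reference(cfg$seed)

write_children(pop$children, "inst/extdata/synthetic_children.csv")
ev <- dplyr::mutate(pop$events, lon = round(lon, 4), lat = round(lat, 4))
readr::write_csv(ev, "inst/extdata/synthetic_events.csv")
ser <- dplyr::mutate(pop$series, drought_index = round(drought_index, 2),
                     surface_runoff = round(surface_runoff, 3))
readr::write_csv(ser, "inst/extdata/synthetic_series.csv")
readr::write_csv(ref, "inst/extdata/synthetic_reference.csv")
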