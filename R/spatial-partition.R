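# Voronoi tessellation by iterative half-plane clipping, and the
# survey-constrained partition built on top of it.
#
# Each site's cell starts as the (convex) region polygon and is clipped by
# the perpendicular-bisector half-plane against every other site; edges
# created by a clip are labelled with the opposing site, so the surviving
# labels are exactly the cell's Voronoi neighbours. This avoids any
# external computational-geometry dependency and is exact for the
# survey-scale site counts used here.

# clip polygon (V: m x 2, L: edge labels, L[k] labels edge V[k] -> V[k+1])
# by half-plane f(p) = (p - m0) . d <= 0; new edges get label j
clip_halfplane <- function(V, L, m0, d, j) {
  m <- nrow(V)
  if (m == 0) return(list(V = V, L = L))
  f <- (V[, 1] - m0[1]) * d[1] + (V[, 2] - m0[2]) * d[2]
  scale <- max(abs(f), 1e-12)
  eps <- 1e-12 * max(scale, 1)
  edges <- list()
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    p <- V[k, ]; q <- V[k2, ]; fp <- f[k]; fq <- f[k2]
    pin <- fp <= eps; qin <- fq <= eps
    if (pin && qin) {
      edges[[length(edges) + 1L]] <- list(p = p, q = q, lab = L[k])
    } else if (pin || qin) {
      t <- fp / (fp - fq)
      x <- p + t * (q - p)
      if (pin) {
        edges[[length(edges) + 1L]] <- list(p = p, q = x, lab = L[k])
      } else {
        edges[[length(edges) + 1L]] <- list(p = x, q = q, lab = L[k])
      }
    }
  }
  if (length(edges) == 0) {
    return(list(V = matrix(numeric(), 0, 2), L = integer()))
  }
  # close gaps along the clip line with label-j edges
  out <- list()
  Tn <- length(edges)
  tol <- 1e-9 * max(1, scale)
  for (t in seq_len(Tn)) {
    out[[length(out) + 1L]] <- edges[[t]]
    nxt <- edges[[if (t == Tn) 1L else t + 1L]]
    if (sqrt(sum((edges[[t]]$q - nxt$p)^2)) > tol) {
      out[[length(out) + 1L]] <- list(p = edges[[t]]$q, q = nxt$p, lab = j)
    }
  }
  V2 <- do.call(rbind, lapply(out, `[[`, "p"))
  L2 <- vapply(out, `[[`, integer(1), "lab")
  # drop zero-length edges
  keep <- vapply(seq_along(out), function(t) {
    sqrt(sum((out[[t]]$q - out[[t]]$p)^2)) > tol
  }, logical(1))
  list(V = V2[keep, , drop = FALSE], L = L2[keep])
}

# Voronoi cells of sites (x, y) clipped to a convex region polygon.
# Returns per-site polygon vertex matrices and integer neighbour sets.
voronoi_cells <- function(x, y, region) {
  n <- length(x)
  if (anyDuplicated(cbind(x, y)) > 0) {
    abort_nutricate("Voronoi sites must have distinct coordinates")
  }
  polys <- vector("list", n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    V <- region
    L <- rep(0L, nrow(region))
    ord <- order((x - x[i])^2 + (y - y[i])^2)
    for (j in ord) {
      if (j == i) next
      m0 <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2)
      d <- c(x[j] - x[i], y[j] - y[i])
      res <- clip_halfplane(V, L, m0, d, j)
      V <- res$V; L <- res$L
      if (nrow(V) == 0) break
    }
    polys[[i]] <- V
    nbrs[[i]] <- sort(unique(L[L > 0L]))
  }
  # symmetrize (numerical edge cases)
  for (i in seq_len(n)) for (j in nbrs[[i]]) {
    if (!(i %in% nbrs[[j]])) nbrs[[j]] <- sort(c(nbrs[[j]], i))
  }
  list(polygons = polys, neighbors = nbrs)
}

# connectivity of a member set under an adjacency list
is_connected_set <- function(members, neighbors) {
  if (length(members) <= 1) return(TRUE)
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier) > 0) {
    nxt <- setdiff(intersect(unique(unlist(neighbors[frontier])), members),
                   seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}

# exact maximum-cardinality partition into connected feasible parts
# (subset dynamic programming; used for small instances)
exact_partition <- function(neighbors, feasible_fn, n) {
  memo <- new.env(parent = emptyenv())
  bits <- 2^(seq_len(n) - 1)
  members_of <- function(S) which(bitwAnd(S, bits) != 0)
  best_split <- function(S) {
    key <- as.character(S)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (S == 0) return(list(count = 0L, parts = list()))
    v <- bits[members_of(S)[1]]
    best <- list(count = -1L, parts = NULL)
    sub <- S
    repeat {
      if (bitwAnd(sub, v) != 0) {
        mem <- members_of(sub)
        if (feasible_fn(mem) && is_connected_set(mem, neighbors)) {
          rest <- best_split(bitwAnd(S, bitwNot(sub)))
          if (rest$count >= 0 && rest$count + 1L > best$count) {
            best <- list(count = rest$count + 1L,
                         parts = c(list(mem), rest$parts))
          }
        }
      }
      if (sub == 0) break
      sub <- bitwAnd(sub - 1, S)
    }
    memo[[key]] <- best
    best
  }
  best_split(sum(bits))
}

# greedy merge: repeatedly take the infeasible area with fewest clusters
# and merge it with the adjacent area that keeps the merged area smallest
# (ties: lowest area id)
greedy_partition <- function(neighbors, feasible_fn, n) {
  area_of <- seq_len(n)
  repeat {
    ids <- sort(unique(area_of))
    members <- lapply(ids, function(a) which(area_of == a))
    ok <- vapply(members, feasible_fn, logical(1))
    if (all(ok)) break
    if (length(ids) == 1) {
      abort_nutricate("partition infeasible: no split contains both rounds")
    }
    sizes <- lengths(members)
    cand <- which(!ok)
    pick <- cand[order(sizes[cand], ids[cand])][1]
    adj_areas <- setdiff(unique(area_of[unlist(neighbors[members[[pick]]])]),
                         ids[pick])
    if (length(adj_areas) == 0) {
      abort_nutricate("partition infeasible: isolated infeasible area")
    }
    merged_size <- vapply(adj_areas, function(a) {
      sizes[pick] + sum(area_of == a)
    }, numeric(1))
    target <- adj_areas[order(merged_size, adj_areas)][1]
    area_of[area_of == ids[pick]] <- target
  }
  ids <- sort(unique(area_of))
  lapply(ids, function(a) which(area_of == a))
}

#' Build the survey-constrained Voronoi-merge partition
#'
#' Tessellates the region into Voronoi cells seeded at survey-cluster
#' locations and merges adjacent cells until every resulting area contains
#' at least one cluster from each survey round, aiming to maximize the
#' number of areas. Small instances (<= `exact_max` clusters) are solved
#' exactly by subset search; larger instances use a deterministic greedy
#' merge (smallest infeasible area first, merged with the adjacent area
#' that keeps the result smallest).
#'
#' @param clusters Tibble with columns `cluster_id`, `survey_round`,
#'   `lon`, `lat` (one row per cluster; distinct locations).
#' @param region Optional convex region boundary: either a length-4 vector
#'   `c(lon_min, lon_max, lat_min, lat_max)` or an m x 2 matrix of polygon
#'   vertices. Defaults to the clusters' bounding box padded by 0.2 deg.
#' @param exact_max Largest instance solved exactly (default 10).
#' @return A `conflict_partition`: list with `areas` (tibble `area_id`,
#'   `cluster_ids` list-column, per-round counts), `assignment` (tibble
#'   `cluster_id` -> `area_id`), per-cluster Voronoi `polygons`, and the
#'   cell `adjacency` list.
#' @export
build_partition <- function(clusters, region = NULL, exact_max = 10L) {
  rounds <- unique(clusters$survey_round)
  if (length(rounds) < 2) {
    abort_nutricate("infeasible: clusters from a single survey round")
  }
  n <- nrow(clusters)
  if (is.null(region)) {
    region <- c(min(clusters$lon) - 0.2, max(clusters$lon) + 0.2,
                min(clusters$lat) - 0.2, max(clusters$lat) + 0.2)
  }
  if (!is.matrix(region)) {
    region <- matrix(c(region[1], region[3], region[2], region[3],
                       region[2], region[4], region[1], region[4]),
                     ncol = 2, byrow = TRUE)
  }
  vor <- voronoi_cells(clusters$lon, clusters$lat, region)
  r1 <- min(rounds); r2 <- max(rounds)
  feasible <- function(members) {
    any(clusters$survey_round[members] == r1) &&
      any(clusters$survey_round[members] == r2)
  }
  parts <- if (n <= exact_max) {
    res <- exact_partition(vor$neighbors, feasible, n)
    if (res$count < 1) {
      abort_nutricate("partition infeasible: no split contains both rounds")
    }
    res$parts
  } else {
    greedy_partition(vor$neighbors, feasible, n)
  }
  # deterministic area order: by smallest member index
  parts <- parts[order(vapply(parts, min, 0L))]
  area_ids <- sprintf("A%03d", seq_along(parts))
  assignment <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    area_id = NA_character_
  )
  for (k in seq_along(parts)) assignment$area_id[parts[[k]]] <- area_ids[k]
  areas <- tibble::tibble(
    area_id = area_ids,
    cluster_ids = lapply(parts, function(m) clusters$cluster_id[m]),
    n_clusters = lengths(parts),
    n_round1 = vapply(parts, function(m) {
      sum(clusters$survey_round[m] == r1)
    }, 0L),
    n_round2 = vapply(parts, function(m) {
      sum(clusters$survey_round[m] == r2)
    }, 0L)
  )
  structure(list(areas = areas, assignment = assignment,
                 polygons = vor$polygons, adjacency = vor$neighbors,
                 clusters = tibble::as_tibble(clusters)),
            class = "conflict_partition")
}

#' @export
print.conflict_partition <- function(x, ...) {
  cat("Survey-constrained Voronoi partition:", nrow(x$areas), "areas from",
      nrow(x$assignment), "clusters\n")
  invisible(x)
}

#' Export a partition as GeoJSON
#'
#' Writes a FeatureCollection with one MultiPolygon feature per area (the
#' member clusters' Voronoi cells) carrying `area_id` and the member
#' cluster ids.
#'
#' @param partition A `conflict_partition` from [build_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_geojson <- function(partition, path) {
  close_ring <- function(V) {
    rbind(V, V[1, , drop = FALSE])
  }
  features <- purrr::map(seq_len(nrow(partition$areas)), function(k) {
    members <- match(partition$areas$cluster_ids[[k]],
                     partition$clusters$cluster_id)
    rings <- purrr::map(partition$polygons[members], function(V) {
      list(apply(close_ring(V), 1, as.list))
    })
    list(
      type = "Feature",
      geometry = list(type = "MultiPolygon", coordinates = rings),
      properties = list(area_id = partition$areas$area_id[k],
                        clusters = partition$areas$cluster_ids[[k]])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
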