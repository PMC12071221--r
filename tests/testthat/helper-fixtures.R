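# Shared fixtures: packaged registry/calendar plus small builders used
# across test files.

hamburg_registry <- function() load_station_table()

calendar_2019 <- function() build_calendar(2019L)

# A small two-station registry for generator and aggregation tests.
toy_registry <- function(volumes = c(500L, 200L)) {
  station_registry(data.frame(
    name = c("Alpha", "Beta"),
    abbr = c("Alp", "Bet"),
    area = c("East", "South"),
    population = c(1000L, 2000L),
    area_km2 = c(10, 20),
    density = c(100, 100),
    ops_total = volumes,
    ops_with = round(volumes * 0.8),
    ops_without = volumes - round(volumes * 0.8)
  ))
}

# Hand-built event table: explicit rows, all fields valid.
toy_events <- function(registry = toy_registry()) {
  data.frame(
    station = c("Alp", "Alp", "Alp", "Bet", "Bet"),
    date = as.Date(c("2019-01-01", "2019-01-01", "2019-03-05",
                     "2019-01-02", "2019-12-31")),
    hour_slot = c(0L, 10L, 10L, 23L, 12L),
    transported = c(TRUE, FALSE, TRUE, TRUE, FALSE)
  )
}

# Brute-force UPGMA: recompute every average inter-cluster distance at each
# step; independent of hclust's NN-chain implementation.
brute_average_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merges <- c(merges, list(sort(unlist(clusters[best]))))
    clusters[[best[1L]]] <- sort(unlist(clusters[best]))
    clusters[[best[2L]]] <- NULL
  }
  list(heights = heights, members = merges)
}

# Exhaustive Kruskal-Wallis permutation p-value for tiny samples: the share
# of distinct group assignments with H at least as large as observed.
# Supports two or three groups (enumeration by nested combinations).
kw_permutation_p <- function(groups) {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  stopifnot(length(sizes) %in% 2:3)
  h_of <- function(values) kruskal_wallis(split(values, rep(seq_along(sizes), sizes)))$H
  h_obs <- h_of(pooled)
  idx <- seq_along(pooled)
  hs <- c()
  sel1 <- utils::combn(length(pooled), sizes[1L])
  for (j in seq_len(ncol(sel1))) {
    rest <- setdiff(idx, sel1[, j])
    if (length(sizes) == 2L) {
      hs <- c(hs, h_of(pooled[c(sel1[, j], rest)]))
    } else {
      sel2 <- utils::combn(length(rest), sizes[2L])
      for (k in seq_len(ncol(sel2))) {
        ord <- c(sel1[, j], rest[sel2[, k]], setdiff(rest, rest[sel2[, k]]))
        hs <- c(hs, h_of(pooled[ord]))
      }
    }
  }
  mean(hs >= h_obs - 1e-12)
}
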