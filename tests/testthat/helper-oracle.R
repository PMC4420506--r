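# Brute-force UPGMA oracle: naive O(n^3) agglomeration recomputing every
# cluster-pair average distance from the full |x_i - x_j| matrix, with the
# same deterministic tie rule as the implementation (among minimal pairs,
# merge the one whose leftmost member coordinate is smallest). Completely
# independent of the package's adjacent-centroid shortcut.
brute_upgma <- function(positions) {
  n <- length(positions)
  D <- abs(outer(positions, positions, "-"))
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- Inf
    best_pair <- NULL
    best_key <- NULL
    for (a in seq_len(m - 1L)) {
      for (b in seq((a + 1L), m)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        key <- c(min(positions[c(clusters[[a]], clusters[[b]])]),
                 min(positions[clusters[[b]]]))
        if (d < best - 1e-9 ||
            (abs(d - best) <= 1e-9 &&
             (key[1] < best_key[1] - 1e-12 ||
              (key[1] <= best_key[1] + 1e-12 && key[2] < best_key[2])))) {
          best <- d
          best_pair <- c(a, b)
          best_key <- key
        }
      }
    }
    a <- best_pair[1]; b <- best_pair[2]
    coph[clusters[[a]], clusters[[b]]] <- best
    coph[clusters[[b]], clusters[[a]]] <- best
    heights <- c(heights, best)
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  list(cophenetic = coph, heights = heights)
}

# Flat clusters at threshold t from the brute-force cophenetic matrix:
# connected components of the "cophenetic distance <= t" graph (exactly the
# tree cut, because the cophenetic matrix is ultrametric).
brute_flat_clusters <- function(positions, t) {
  coph <- brute_upgma(positions)$cophenetic
  n <- length(positions)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(coph[i, ] <= t)
      target <- min(comp[linked], comp[i])
      if (any(comp[c(i, linked)] != target)) {
        comp[c(i, linked)] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# Canonical form of a partition membership vector (label by first occurrence)
canon_partition <- function(m) match(m, unique(m))

expect_same_partition <- function(a, b) {
  expect_identical(canon_partition(a), canon_partition(b))
}
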