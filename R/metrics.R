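#' Cluster power: size over the median inter-SNV distance
#'
#' Power measures cluster density: the number of SNVs divided by the median
#' distance (bp) between SNVs within the cluster. By default the median is
#' taken over consecutive inter-SNV distances after sorting by position; the
#' all-pairs variant is available via `gaps = "allpairs"`. Degenerate cases:
#' a single-member cluster gets denominator 1, and a median distance of 0
#' (duplicate pooled positions) is clamped to 1 bp.
#'
#' @param positions Numeric vector of member coordinates (bp), or a cluster
#'   member tibble with a `pos` column.
#' @param gaps `"consecutive"` (default) or `"allpairs"`.
#' @return Power in SNVs per bp.
#' @examples
#' cluster_power(c(0, 100, 200, 300, 400))  # 5 / 100 = 0.05
#' @export
cluster_power <- function(positions, gaps = c("consecutive", "allpairs")) {
  gaps <- match.arg(gaps)
  if (is.data.frame(positions)) positions <- positions$pos
  n <- length(positions)
  if (!n) stop("cluster_power() needs a non-empty cluster")
  if (n == 1L) return(n / 1)
  pos <- sort(as.numeric(positions))
  d <- if (gaps == "consecutive") diff(pos) else as.numeric(stats::dist(pos))
  med <- stats::median(d)
  if (med <= 0) med <- 1
  n / med
}

#' Cluster homogeneity: strand polarity of deamination classes
#'
#' The fraction of a cluster's deaminase-like members (C->T or G->A)
#' belonging to the majority class. Homogeneity 1 means a fully polar
#' cluster (one class only, i.e. one deaminated strand); 0.5 means an even
#' split. Non-deaminase-like (OTHER) members are excluded; a cluster with no
#' CT/GA members has undefined homogeneity (`NA`).
#'
#' @param mclass Character vector of mutation classes (`"CT"`, `"GA"`,
#'   `"OTHER"`), or a cluster member tibble with an `mclass` column.
#' @return Homogeneity in `[0.5, 1]`, or `NA` if undefined.
#' @examples
#' cluster_homogeneity(rep(c("CT", "GA"), c(5, 5)))  # 0.5
#' cluster_homogeneity(rep("CT", 7))                 # 1
#' @export
cluster_homogeneity <- function(mclass) {
  if (is.data.frame(mclass)) mclass <- mclass$mclass
  n_ct <- sum(mclass == "CT")
  n_ga <- sum(mclass == "GA")
  if (n_ct + n_ga == 0L) return(NA_real_)
  max(n_ct, n_ga) / (n_ct + n_ga)
}

#' Majority deamination class of a cluster
#'
#' @inheritParams cluster_homogeneity
#' @return `"CT"`, `"GA"`, `"tie"`, or `NA` if the cluster has no CT/GA
#'   members.
#' @export
majority_class <- function(mclass) {
  if (is.data.frame(mclass)) mclass <- mclass$mclass
  n_ct <- sum(mclass == "CT")
  n_ga <- sum(mclass == "GA")
  if (n_ct + n_ga == 0L) return(NA_character_)
  if (n_ct > n_ga) "CT" else if (n_ga > n_ct) "GA" else "tie"
}

#' Summarize clusters on a size-by-power (or size-by-homogeneity) grid
#'
#' A 2-D histogram of cluster counts, the tabular form of the usual
#' size/power and size/homogeneity heatmaps. Default binning: unit-width
#' size bins up to the 95th percentile with an open-ended final bin, and a
#' log-spaced power grid (homogeneity gets linear bins of 0.05). The bin
#' edges used are always part of the result.
#'
#' @param clusters A cluster tibble from [detect_clusters()].
#' @param y `"power"` or `"homogeneity"`.
#' @param size_breaks,y_breaks Optional numeric bin edges.
#' @return A list of class `cluster_grid` with `counts` (matrix, size bins x
#'   y bins), `size_breaks` and `y_breaks`.
#' @export
summarize_grid <- function(clusters, y = c("power", "homogeneity"),
                           size_breaks = NULL, y_breaks = NULL) {
  y <- match.arg(y)
  sizes <- clusters$size
  yv <- clusters[[y]]
  if (is.null(size_breaks)) {
    if (length(sizes)) {
      hi <- max(stats::quantile(sizes, 0.95), min(sizes) + 1)
      size_breaks <- c(seq(floor(min(sizes)), ceiling(hi)), Inf)
    } else {
      size_breaks <- c(5, 10, Inf)
    }
  }
  if (is.null(y_breaks)) {
    y_breaks <- if (y == "homogeneity") {
      seq(0.5, 1, by = 0.05)
    } else if (length(yv)) {
      exp(seq(log(max(min(yv) * 0.999, 1e-6)), log(max(yv) * 1.001), length.out = 11))
    } else {
      exp(seq(log(0.05), log(10), length.out = 11))
    }
  }
  sb <- cut(sizes, size_breaks, right = FALSE, include.lowest = TRUE)
  yb <- cut(yv, y_breaks, right = FALSE, include.lowest = TRUE)
  counts <- table(size = sb, y = yb)
  out <- list(counts = unclass(counts), size_breaks = size_breaks,
              y_breaks = y_breaks, y = y,
              n_unbinned = sum(is.na(sb) | is.na(yb)))
  class(out) <- "cluster_grid"
  out
}

#' @export
print.cluster_grid <- function(x, ...) {
  cat(sprintf("<cluster_grid> size x %s, %d clusters\n", x$y, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Histogram of cluster lengths
#'
#' Counts clusters by span (end - start, bp) in fixed-width bins
#' `[k*bin, (k+1)*bin)`.
#'
#' @param clusters A cluster tibble from [detect_clusters()].
#' @param bin Bin width in bp (default 100).
#' @return A tibble with `bin_start`, `bin_end`, `count`.
#' @export
length_distribution <- function(clusters, bin = 100) {
  spans <- clusters$span
  if (!length(spans)) {
    return(tibble::tibble(bin_start = numeric(), bin_end = numeric(), count = integer()))
  }
  idx <- floor(spans / bin)
  all_bins <- seq(0, max(idx))
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  tibble::tibble(
    bin_start = all_bins * bin,
    bin_end = (all_bins + 1) * bin,
    count = counts
  )
}
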