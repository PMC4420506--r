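#' Parameters of the cluster-detection cascade
#'
#' Defaults are the published operating point of the method: a 1000 bp
#' cophenetic cutoff (chosen where the count of clusters with three or more
#' mutations plateaus), inconsistency threshold 0.8 at depth 2 for border
#' refinement, and retention filters of at least five SNVs and power at
#' least 0.05 per bp (both inclusive).
#'
#' @param t Cophenetic-distance extraction threshold, bp.
#' @param inconsistency_threshold,inconsistency_depth Border-refinement
#'   parameters.
#' @param min_size Minimum cluster size (SNVs).
#' @param min_power Minimum cluster power (SNVs per bp).
#' @param max_nondeaminase Maximum tolerated non-deaminase-like members in
#'   deaminase mode before a cluster is discarded as a likely calling error.
#' @param power_gaps Gap definition for the power denominator;
#'   see [cluster_power()].
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(t = 1000, inconsistency_threshold = 0.8,
                           inconsistency_depth = 2, min_size = 5,
                           min_power = 0.05, max_nondeaminase = 1,
                           power_gaps = c("consecutive", "allpairs")) {
  stopifnot(t > 0, min_size >= 1, min_power >= 0, max_nondeaminase >= 0)
  out <- list(
    t = t,
    inconsistency_threshold = inconsistency_threshold,
    inconsistency_depth = inconsistency_depth,
    min_size = min_size,
    min_power = min_power,
    max_nondeaminase = max_nondeaminase,
    power_gaps = match.arg(power_gaps)
  )
  class(out) <- "cluster_params"
  out
}

cluster_stats <- function(members, power_gaps = "consecutive") {
  tibble::tibble(
    chrom = members$chrom[1],
    start = min(members$pos),
    end = max(members$pos),
    span = max(members$pos) - min(members$pos),
    size = nrow(members),
    power = cluster_power(members$pos, gaps = power_gaps),
    homogeneity = cluster_homogeneity(members$mclass),
    majority_class = majority_class(members$mclass),
    n_ct = sum(members$mclass == "CT"),
    n_ga = sum(members$mclass == "GA"),
    n_other = sum(members$mclass == "OTHER"),
    n_samples = length(unique(members$sample_id)),
    members = list(members)
  )
}

#' Filter candidate clusters against masks, class composition, size and power
#'
#' The final stage of the detection cascade: (a) clusters with one or more
#' SNV in a masked region are removed; (b) in deaminase mode clusters with
#' more than `max_nondeaminase` non-deaminase-like (OTHER) members are
#' removed as likely sequencing/call errors, while a cluster whose single
#' OTHER member is carried by a single sample keeps the cluster and drops
#' that SNV; (c) statistics are recomputed; (d) clusters below `min_size` or
#' `min_power` are dropped (inclusive thresholds: kept when size >= min_size
#' and power >= min_power); (e) the SNVs of every cluster surviving (a)-(b)
#' are restored per sample.
#'
#' @param member_list A list of cluster member tibbles (columns as in
#'   [snv_set]).
#' @param masks Optional `GRanges` of masked intervals.
#' @param params A [cluster_params] object.
#' @param deaminase_mode Apply the class-composition filter (b)?
#' @return A list with `clusters` (tibble, one row per kept cluster),
#'   `removed_snvs` (tibble with a `reason` column) and `restored`
#'   (per-sample tibble of surviving SNVs).
#' @export
filter_clusters <- function(member_list, masks = NULL, params = cluster_params(),
                            deaminase_mode = TRUE) {
  removed <- list()
  restored <- list()
  kept <- list()
  for (members in member_list) {
    if (!nrow(members)) next
    # (a) mask filter
    if (!is.null(masks) && length(masks)) {
      in_mask <- GenomicRanges::countOverlaps(snv_granges(members), masks,
                                             ignore.strand = TRUE) > 0
      if (any(in_mask)) {
        removed[[length(removed) + 1L]] <-
          dplyr::mutate(members, reason = "cluster_overlaps_mask")
        next
      }
    }
    # (b) non-deaminase-like composition; distinct variants are counted, so
    # the same substitution recurring in several samples is one SNV
    if (deaminase_mode) {
      is_other <- members$mclass == "OTHER"
      other_variant <- unique(paste(members$chrom, members$pos, members$ref,
                                    members$alt)[is_other])
      if (length(other_variant) > params$max_nondeaminase) {
        removed[[length(removed) + 1L]] <-
          dplyr::mutate(members, reason = "too_many_nondeaminase")
        next
      }
      if (length(other_variant) == 1L) {
        carriers <- unique(members$sample_id[is_other])
        if (length(carriers) == 1L) {
          removed[[length(removed) + 1L]] <- dplyr::mutate(
            members[is_other, , drop = FALSE],
            reason = "single_sample_nondeaminase_snv"
          )
          members <- members[!is_other, , drop = FALSE]
        } else {
          removed[[length(removed) + 1L]] <-
            dplyr::mutate(members, reason = "recurrent_nondeaminase_snv")
          next
        }
      }
    }
    if (!nrow(members)) next
    restored[[length(restored) + 1L]] <- members
    # (c) recompute, (d) size/power filter
    st <- cluster_stats(members, params$power_gaps)
    if (st$size >= params$min_size && st$power >= params$min_power) {
      kept[[length(kept) + 1L]] <- st
    }
  }
  empty_members <- tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample_id = character(), mclass = character()
  )
  empty_clusters <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(), span = integer(),
    size = integer(), power = numeric(), homogeneity = numeric(),
    majority_class = character(), n_ct = integer(), n_ga = integer(),
    n_other = integer(), n_samples = integer(), members = list()
  )
  list(
    clusters = if (length(kept)) dplyr::bind_rows(kept) else empty_clusters,
    removed_snvs = if (length(removed)) dplyr::bind_rows(removed) else
      dplyr::mutate(empty_members, reason = character()),
    restored = if (length(restored)) {
      dplyr::arrange(dplyr::bind_rows(restored), .data$sample_id, .data$chrom, .data$pos)
    } else empty_members
  )
}

#' Detect mutation clusters in a pooled SNV set
#'
#' The full three-stage cascade, run per chromosome: (1) UPGMA clustering of
#' SNV coordinates and flat-cluster extraction at the cophenetic threshold;
#' (2) inconsistency-coefficient border refinement of every extracted
#' cluster (re-clustered from scratch); (3) the filtering cascade of
#' [filter_clusters()]. Clusters never span chromosomes.
#'
#' @param pooled An [snv_set] (typically from [pool_samples()]).
#' @param masks Optional `GRanges` of masked intervals.
#' @param params A [cluster_params] object.
#' @param deaminase_mode Apply the non-deaminase-like composition filter?
#' @param refine Apply stage 2? (Default TRUE, the published pipeline.)
#' @return A tibble with one row per cluster, sorted by (chrom, start):
#'   `cluster_id`, `chrom`, `start`, `end`, `span`, `size`, `power`,
#'   `homogeneity`, `majority_class`, class counts and a `members`
#'   list-column. Attributes `removed_snvs`, `restored` and `params` carry
#'   the filter by-products.
#' @export
detect_clusters <- function(pooled, masks = NULL, params = cluster_params(),
                            deaminase_mode = TRUE, refine = TRUE) {
  snvs <- tibble::as_tibble(pooled)
  member_list <- list()
  for (chr in unique(snvs$chrom)) {
    sub <- snvs[snvs$chrom == chr, , drop = FALSE]
    dend <- upgma_linkage(sub$pos)
    memb <- extract_flat_clusters(dend, params$t)
    for (cl in unique(memb)) {
      cl_members <- sub[memb == cl, , drop = FALSE]
      if (refine && nrow(cl_members) > 2L) {
        sub_memb <- refine_by_inconsistency(
          cl_members$pos,
          threshold = params$inconsistency_threshold,
          depth = params$inconsistency_depth
        )
        for (s in unique(sub_memb)) {
          member_list[[length(member_list) + 1L]] <-
            cl_members[sub_memb == s, , drop = FALSE]
        }
      } else {
        member_list[[length(member_list) + 1L]] <- cl_members
      }
    }
  }
  res <- filter_clusters(member_list, masks, params, deaminase_mode)
  clusters <- dplyr::arrange(res$clusters, .data$chrom, .data$start)
  ids <- if (nrow(clusters)) {
    sprintf("cl_%s_%03d", clusters$chrom,
            stats::ave(seq_len(nrow(clusters)), clusters$chrom, FUN = seq_along))
  } else character()
  clusters <- dplyr::mutate(clusters, cluster_id = ids, .before = 1)
  attr(clusters, "removed_snvs") <- res$removed_snvs
  attr(clusters, "restored") <- res$restored
  attr(clusters, "params") <- params
  clusters
}

#' Sweep the cophenetic extraction threshold
#'
#' Counts flat clusters (stage 1 only: no refinement, no filtering) with at
#' least `min_count` members over a grid of cophenetic thresholds. Plotted
#' against the threshold this curve plateaus where further merging stops
#' creating new multi-SNV clusters, which is how the operating threshold was
#' chosen.
#'
#' @param pooled An [snv_set].
#' @param t_min,t_max,step Threshold grid in bp (default 50-5000 by 50).
#' @param min_count Minimum members for a cluster to be counted (default 3).
#' @return A tibble with `threshold`, `n_clusters` (>= min_count members)
#'   and `n_total` (all flat clusters, singletons included).
#' @export
threshold_sweep <- function(pooled, t_min = 50, t_max = 5000, step = 50,
                            min_count = 3) {
  if (t_min <= 0) stop("t_min must be > 0")
  snvs <- tibble::as_tibble(pooled)
  if (!nrow(snvs)) stop("threshold_sweep() needs a non-empty SNV set")
  grid <- seq(t_min, t_max, by = step)
  dends <- lapply(split(snvs$pos, snvs$chrom), upgma_linkage)
  counts <- vapply(grid, function(t) {
    per_chrom <- vapply(dends, function(d) {
      sizes <- tabulate(extract_flat_clusters(d, t))
      c(sum(sizes >= min_count), length(sizes))
    }, numeric(2))
    rowSums(per_chrom)
  }, numeric(2))
  tibble::tibble(
    threshold = grid,
    n_clusters = as.integer(counts[1, ]),
    n_total = as.integer(counts[2, ])
  )
}
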