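#' UPGMA (average-linkage) clustering of 1-D genomic coordinates
#'
#' Agglomerates SNV coordinates on a single chromosome by repeatedly merging
#' the pair of clusters with the smallest average inter-point distance
#' d(u,v) = sum_ij d(u_i, v_j) / (|u|*|v|); the merge height is that average
#' distance. In one dimension the average distance between two clusters that
#' do not interleave equals the difference of their member means, so clusters
#' stay contiguous along the chromosome and only adjacent cluster pairs need
#' to be considered; this makes the agglomeration O(n^2) with no distance
#' matrix. Ties are broken toward the pair whose leftmost member has the
#' smallest coordinate, which makes the merge order deterministic.
#'
#' @param positions Numeric vector of coordinates (bp). Need not be sorted;
#'   duplicates are allowed.
#' @return An object of class `snv_dendrogram`: a list with elements
#'   * `n`: number of leaves;
#'   * `merge`: (n-1) x 2 matrix in `hclust` convention (negative entries are
#'     leaves numbered in sorted-coordinate order, positive entries earlier
#'     merge rows);
#'   * `height`: merge heights in bp (non-decreasing);
#'   * `positions`: the sorted coordinates;
#'   * `order`: mapping from sorted-order leaves to the input order, i.e.
#'     `positions[i] == input[order[i]]`.
#' @examples
#' d <- upgma_linkage(c(0, 10, 20))
#' d$height  # 10, 15
#' @export
upgma_linkage <- function(positions) {
  positions <- as.numeric(positions)
  if (!length(positions)) stop("upgma_linkage() needs at least one position")
  if (anyNA(positions)) stop("positions must not contain NA")
  ord <- order(positions)
  pos <- positions[ord]
  n <- length(pos)
  out <- list(
    n = n,
    merge = matrix(integer(), 0, 2),
    height = numeric(0),
    positions = pos,
    order = ord
  )
  class(out) <- "snv_dendrogram"
  if (n == 1L) return(out)

  m <- pos            # cluster means, left-to-right
  cnt <- rep(1L, n)   # cluster sizes
  node <- -seq_len(n) # hclust node codes
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    gaps <- m[-1L] - m[-length(m)]
    j <- which.min(gaps) # first minimum = leftmost tied pair
    height[k] <- gaps[j]
    merge[k, ] <- c(node[j], node[j + 1L])
    tot <- cnt[j] + cnt[j + 1L]
    m[j] <- (m[j] * cnt[j] + m[j + 1L] * cnt[j + 1L]) / tot
    cnt[j] <- tot
    node[j] <- k
    m <- m[-(j + 1L)]
    cnt <- cnt[-(j + 1L)]
    node <- node[-(j + 1L)]
  }
  out$merge <- merge
  out$height <- height
  out
}

#' @export
print.snv_dendrogram <- function(x, ...) {
  cat(sprintf(
    "<snv_dendrogram> %d leaves, root height %s bp\n",
    x$n, if (x$n > 1) format(max(x$height)) else "0"
  ))
  invisible(x)
}

# Leaves (sorted-order indices) under each internal node; list of length n-1.
dendro_leaf_sets <- function(dend) {
  n <- dend$n
  sets <- vector("list", max(n - 1L, 0L))
  leaves_of <- function(code) {
    if (code < 0L) -code else sets[[code]]
  }
  for (k in seq_len(n - 1L)) {
    sets[[k]] <- c(leaves_of(dend$merge[k, 1L]), leaves_of(dend$merge[k, 2L]))
  }
  sets
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance between two SNVs is the merge height at which they
#' first belong to the same nested cluster (the height of the lowest common
#' ancestor of the two leaves).
#'
#' @param dend An [upgma_linkage()] dendrogram.
#' @param input_order Return the matrix over the original input order
#'   (default) rather than sorted-coordinate order.
#' @return An n x n symmetric matrix with zero diagonal.
#' @export
cophenetic_matrix <- function(dend, input_order = TRUE) {
  n <- dend$n
  cm <- matrix(0, n, n)
  if (n > 1L) {
    sets <- dendro_leaf_sets(dend)
    leaves_of <- function(code) if (code < 0L) -code else sets[[code]]
    for (k in seq_len(n - 1L)) {
      a <- leaves_of(dend$merge[k, 1L])
      b <- leaves_of(dend$merge[k, 2L])
      cm[a, b] <- dend$height[k]
      cm[b, a] <- dend$height[k]
    }
  }
  if (input_order) {
    inv <- integer(n)
    inv[dend$order] <- seq_len(n)
    cm <- cm[inv, inv, drop = FALSE]
  }
  cm
}

#' Extract flat clusters by cutting the dendrogram at a cophenetic threshold
#'
#' Cuts the tree at height `t`: each maximal subtree whose root merge height
#' is at most `t` becomes one flat cluster, so every within-cluster pair has
#' cophenetic distance <= t and no two clusters could be merged without
#' exceeding it.
#'
#' @param dend An [upgma_linkage()] dendrogram.
#' @param t Cophenetic-distance threshold in bp (> 0).
#' @return Integer vector of cluster memberships in the *input* order of the
#'   positions given to [upgma_linkage()], numbered left-to-right along the
#'   chromosome.
#' @examples
#' d <- upgma_linkage(c(0, 10, 20, 2000))
#' extract_flat_clusters(d, 1000)  # 1 1 1 2
#' @export
extract_flat_clusters <- function(dend, t) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0) stop("t must be a positive number")
  n <- dend$n
  memb_sorted <- seq_len(n)
  if (n > 1L) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    rep_of <- integer(n - 1L) # representative leaf per internal node
    for (k in seq_len(n - 1L)) {
      if (dend$height[k] > t) break # heights are non-decreasing
      l <- dend$merge[k, 1L]
      r <- dend$merge[k, 2L]
      rl <- if (l < 0L) -l else rep_of[l]
      rr <- if (r < 0L) -r else rep_of[r]
      parent[find(rr)] <- find(rl)
      rep_of[k] <- find(rl)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    memb_sorted <- match(roots, unique(roots)) # numbered left-to-right
  }
  memb <- integer(n)
  memb[dend$order] <- memb_sorted
  memb
}

#' Inconsistency coefficient of each merge link
#'
#' Characterizes each link by comparing its height with the heights of nearby
#' links below it: for depth d the reference set H contains the link itself
#' and all descendant links fewer than d levels below it (leaves contribute
#' nothing). The coefficient is `(h - mean(H)) / sd(H)` with the sample
#' standard deviation; links whose reference set has zero spread get
#' coefficient 0. This matches the behaviour of the standard
#' hierarchical-clustering toolkits.
#'
#' @param dend An [upgma_linkage()] dendrogram.
#' @param depth Number of tree levels included (default 2: the link and its
#'   direct children).
#' @return Numeric vector of length n-1, in merge order.
#' @export
inconsistency <- function(dend, depth = 2) {
  n <- dend$n
  if (n <= 1L) return(numeric(0))
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  # heights_below[[k]]: heights of link k and descendants < depth levels below
  collect <- function(code, lev) {
    if (code < 0L || lev > depth) return(numeric(0))
    c(dend$height[code],
      collect(dend$merge[code, 1L], lev + 1L),
      collect(dend$merge[code, 2L], lev + 1L))
  }
  vapply(seq_len(n - 1L), function(k) {
    H <- collect(k, 1L)
    s <- stats::sd(H)
    if (length(H) < 2L || is.na(s) || s == 0) return(0)
    (dend$height[k] - mean(H)) / s
  }, numeric(1))
}

#' Refine a cluster by inconsistency-coefficient subcluster extraction
#'
#' Re-clusters the member coordinates from scratch and extracts subclusters
#' to adjust cluster borders: a subtree is kept whole only if every merge
#' link inside it has inconsistency coefficient at most `threshold`;
#' otherwise it is broken at its root, recursively. Clusters of one or two
#' members are returned unchanged (their only link always has coefficient 0).
#'
#' @param positions Member coordinates (bp) of one cluster.
#' @param threshold Inconsistency threshold (default 0.8).
#' @param depth Depth for [inconsistency()] (default 2).
#' @return Integer vector of subcluster memberships in input order, numbered
#'   left-to-right.
#' @examples
#' refine_by_inconsistency(c(0, 10, 20, 400, 410, 420))  # 1 1 1 2 2 2
#' @export
refine_by_inconsistency <- function(positions, threshold = 0.8, depth = 2) {
  n <- length(positions)
  if (n <= 2L) return(rep(1L, n))
  dend <- upgma_linkage(positions)
  R <- inconsistency(dend, depth)
  # max inconsistency over each node's subtree
  maxR <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) { # children precede parents in merge order
    m <- R[k]
    for (code in dend$merge[k, ]) {
      if (code > 0L) m <- max(m, maxR[code])
    }
    maxR[k] <- m
  }
  sets <- dendro_leaf_sets(dend)
  memb_sorted <- integer(n)
  nxt <- 0L
  assign_node <- function(code) {
    if (code < 0L) {
      nxt <<- nxt + 1L
      memb_sorted[-code] <<- nxt
    } else if (maxR[code] <= threshold) {
      nxt <<- nxt + 1L
      memb_sorted[sets[[code]]] <<- nxt
    } else {
      assign_node(dend$merge[code, 1L])
      assign_node(dend$merge[code, 2L])
    }
  }
  assign_node(n - 1L)
  # renumber left-to-right along the chromosome (leaves are in sorted order)
  memb_sorted <- match(memb_sorted, unique(memb_sorted))
  memb <- integer(n)
  memb[dend$order] <- memb_sorted
  memb
}
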