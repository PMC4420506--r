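#' Which DNA strand was deaminated, relative to transcription?
#'
#' A C->T call means the deaminated cytosine lies on the Watson (reference)
#' strand; a G->A call places it on the Crick strand. For a gene on the
#' Watson (+) strand the transcribed (template) strand is Crick, so a C->T
#' inside a + gene is a non-transcribed-strand deamination, and so on by
#' complementarity. OTHER-class substitutions are undefined.
#'
#' @param mclass Character vector of mutation classes (`"CT"`/`"GA"`/
#'   `"OTHER"`).
#' @param gene_strand Character vector of gene strands (`"+"`/`"-"`),
#'   recycled.
#' @return Character vector: `"non_transcribed"`, `"transcribed"` or
#'   `"undefined"`.
#' @examples
#' assign_deaminated_strand("CT", "+")  # non_transcribed
#' assign_deaminated_strand("GA", "+")  # transcribed
#' @export
assign_deaminated_strand <- function(mclass, gene_strand) {
  n <- max(length(mclass), length(gene_strand))
  mclass <- rep_len(mclass, n)
  gene_strand <- rep_len(gene_strand, n)
  dplyr::case_when(
    mclass == "CT" & gene_strand == "+" ~ "non_transcribed",
    mclass == "GA" & gene_strand == "-" ~ "non_transcribed",
    mclass == "GA" & gene_strand == "+" ~ "transcribed",
    mclass == "CT" & gene_strand == "-" ~ "transcribed",
    TRUE ~ "undefined"
  )
}

# Gene-relative offsets of SNVs around per-gene anchor coordinates.
# anchor: genomic coordinate of offset 0 per gene; offsets run 5'->3' along
# the gene (mirrored for - strand genes). Window is [off_min, off_max) in
# offset space. Returns one row per (snv, gene) pair.
gene_relative_offsets <- function(snvs, genes, anchor, off_min, off_max) {
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, anchor + off_min, anchor - off_max + 1)
  win_end <- ifelse(plus, anchor + off_max - 1, anchor - off_min)
  wg <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(win_start, win_end))
  ov <- GenomicRanges::findOverlaps(snv_granges(snvs), wg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  offset <- ifelse(plus[si], snvs$pos[qi] - anchor[si], anchor[si] - snvs$pos[qi])
  tibble::tibble(
    snv_idx = qi, gene_idx = si, offset = as.numeric(offset),
    mclass = snvs$mclass[qi], gene_strand = genes$strand[si]
  )
}

bin_offsets <- function(pairs, off_min, off_max, bin, n_total, strand_layers) {
  edges <- seq(off_min, off_max, by = bin)
  starts <- edges[-length(edges)]
  layer_tbl <- function(p, layer) {
    idx <- findInterval(p$offset, edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1 & idx <= length(starts)]
    counts <- tabulate(idx, nbins = length(starts))
    tibble::tibble(
      bin_start = starts, bin_end = starts + bin,
      fraction = counts / n_total, layer = layer
    )
  }
  out <- layer_tbl(pairs, "all")
  if (strand_layers) {
    ds <- assign_deaminated_strand(pairs$mclass, pairs$gene_strand)
    out <- dplyr::bind_rows(
      out,
      layer_tbl(pairs[ds == "non_transcribed", , drop = FALSE], "non_transcribed"),
      layer_tbl(pairs[ds == "transcribed", , drop = FALSE], "transcribed")
    )
  }
  out
}

#' Mutation density around CDS start codons
#'
#' Pools all genes into a metagene profile anchored at the first base of the
#' start codon (offset 0), binned in 5 bp bins on the gene's own 5'->3' axis
#' (offsets are mirrored for Crick-strand genes). Bin values are fractions
#' of *all* SNVs in the analyzed set, not of the SNVs in the window, so an
#' SNV upstream of two divergent genes counts once in each gene's window.
#'
#' @param snvs An [snv_set].
#' @param annotation A [genome_annotation].
#' @param window Offset window `c(min, max)` in bp around the CDS start
#'   (default -600..600; bins are half-open `[k*bin, (k+1)*bin)`).
#' @param bin Bin width, bp (default 5).
#' @param strand_layers Also compute transcribed / non-transcribed layers?
#' @return A tibble with `bin_start`, `bin_end`, `fraction`, `layer`;
#'   attribute `n_total` is the denominator.
#' @export
density_around_cds_start <- function(snvs, annotation, window = c(-600, 600),
                                     bin = 5, strand_layers = FALSE) {
  genes <- annotation$genes[annotation$genes$kind == "protein_coding", , drop = FALSE]
  anchor <- ifelse(genes$strand == "+", genes$cds_start, genes$cds_end)
  pairs <- gene_relative_offsets(snvs, genes, anchor, window[1], window[2])
  out <- bin_offsets(pairs, window[1], window[2], bin, nrow(snvs), strand_layers)
  attr(out, "n_total") <- nrow(snvs)
  attr(out, "anchor") <- "cds_start"
  out
}

#' Mutation density across pre-5'-UTR, 5'-UTR and CDS start
#'
#' The three-panel metagene profile of transcription-initiation regions:
#' 5 bp bins over `pre_len` bp upstream of the 5'-end of the 5'-UTR, percent
#' bins (width 10%) across the 5'-UTR, and 5 bp bins over the first
#' `cds_len` bp of the CDS. Only genes with an annotated 5'-UTR of at least
#' 10 bp enter the analysis; in the pre-UTR and UTR panels SNVs that overlap
#' a different gene's body are excluded, so those panels show only the
#' unambiguous signal. Values are fractions of all SNVs in the set.
#'
#' @param snvs An [snv_set].
#' @param annotation A [genome_annotation].
#' @param pre_len,cds_len Panel widths in bp (defaults 300).
#' @param bin Bin width for the bp panels (default 5).
#' @param utr_bin_pct Percent bin width for the UTR panel (default 10).
#' @param min_utr_len Minimum 5'-UTR length (default 10 bp; shorter UTRs are
#'   excluded).
#' @param strand_layers Also compute transcribed / non-transcribed layers?
#' @return A named list of three profile tibbles: `pre`, `utr5`, `cds`.
#' @export
tss_tripanel_density <- function(snvs, annotation, pre_len = 300, cds_len = 300,
                                 bin = 5, utr_bin_pct = 10, min_utr_len = 10,
                                 strand_layers = FALSE) {
  g <- annotation$genes
  g <- g[g$kind == "protein_coding" & !is.na(g$utr5_start) &
           (g$utr5_end - g$utr5_start + 1) >= min_utr_len, , drop = FALSE]
  n_total <- nrow(snvs)
  snvs <- tibble::as_tibble(snvs)

  # SNVs overlapping any gene body: used to drop ambiguous pre-UTR/UTR signal
  ov <- GenomicRanges::findOverlaps(snv_granges(snvs), annotation$body,
                                    ignore.strand = TRUE)
  overlapping_gene <- split(
    S4Vectors::mcols(annotation$body)$gene_id[S4Vectors::subjectHits(ov)],
    S4Vectors::queryHits(ov)
  )
  hits_other_gene <- function(pairs) {
    gid <- g$gene_id[pairs$gene_idx]
    other <- mapply(function(i, id) {
      hit <- overlapping_gene[[as.character(i)]]
      !is.null(hit) && any(hit != id)
    }, pairs$snv_idx, gid)
    if (!length(other)) logical(0) else as.logical(other)
  }

  tss <- ifelse(g$strand == "+", g$utr5_start, g$utr5_end)
  pre_pairs <- gene_relative_offsets(snvs, g, tss, -pre_len, 0)
  pre_pairs <- pre_pairs[!hits_other_gene(pre_pairs), , drop = FALSE]
  pre <- bin_offsets(pre_pairs, -pre_len, 0, bin, n_total, strand_layers)
  attr(pre, "anchor") <- "utr5_5prime_end"

  utr_len <- g$utr5_end - g$utr5_start + 1
  utr_pairs <- gene_relative_offsets(snvs, g, tss, 0, max(c(utr_len, 1)))
  utr_pairs <- utr_pairs[utr_pairs$offset < utr_len[utr_pairs$gene_idx], , drop = FALSE]
  utr_pairs <- utr_pairs[!hits_other_gene(utr_pairs), , drop = FALSE]
  utr_pairs$offset <- 100 * utr_pairs$offset / utr_len[utr_pairs$gene_idx]
  utr5 <- bin_offsets(utr_pairs, 0, 100, utr_bin_pct, n_total, strand_layers)
  attr(utr5, "anchor") <- "utr5_percent"

  cds_anchor <- ifelse(g$strand == "+", g$cds_start, g$cds_end)
  cds_pairs <- gene_relative_offsets(snvs, g, cds_anchor, 0, cds_len)
  cds <- bin_offsets(cds_pairs, 0, cds_len, bin, n_total, strand_layers)
  attr(cds, "anchor") <- "cds_start"

  attr(pre, "n_total") <- n_total
  attr(utr5, "n_total") <- n_total
  attr(cds, "n_total") <- n_total
  list(pre = pre, utr5 = utr5, cds = cds)
}

#' Transcriptional strand bias of deaminations in a feature class
#'
#' Builds the 2x2 contingency table of mutation class (C->T / G->A) against
#' gene strand (+ / -) for SNVs of one feature category that lie in genes of
#' a single orientation, and returns the phi correlation coefficient
#' `phi = (n11*n22 - n12*n21) / sqrt(r1*r2*c1*c2)`. Positive phi means C->T
#' mutations preferentially hit genes on the Watson strand (i.e.
#' deamination of the non-transcribed strand). The p-value comes from the
#' chi-square test of independence (1 df, no continuity correction), or
#' Fisher's exact test when any expected cell count is below 5.
#'
#' @param snvs An [snv_set].
#' @param annotation A [genome_annotation].
#' @param category Feature class: `"CDS"`, `"UTR5"`, `"UTR3"`, `"ncRNA"` or
#'   `"intergenic"` (the latter uses SNVs inside gene bodies only, so it is
#'   normally empty).
#' @return A list of class `strand_bias` with `category`, `table`, `phi`,
#'   `p_value`, `test` and `n`.
#' @export
strand_bias_phi <- function(snvs, annotation, category = "UTR5") {
  af <- assign_features(snvs, annotation)
  af <- af[af$category == category & af$mclass %in% c("CT", "GA") &
             af$strand_context %in% c("plus_only", "minus_only"), , drop = FALSE]
  tab <- matrix(0L, 2, 2, dimnames = list(mclass = c("CT", "GA"), strand = c("+", "-")))
  if (nrow(af)) {
    tt <- table(
      factor(af$mclass, c("CT", "GA")),
      factor(ifelse(af$strand_context == "plus_only", "+", "-"), c("+", "-"))
    )
    tab[] <- as.integer(tt)
  }
  out <- list(category = category, table = tab, n = sum(tab))
  tabn <- matrix(as.numeric(tab), 2, 2)
  r <- rowSums(tabn); cl <- colSums(tabn)
  if (any(r == 0) || any(cl == 0)) {
    out$phi <- NA_real_
    out$p_value <- NA_real_
    out$test <- "undefined"
  } else {
    out$phi <- (tabn[1, 1] * tabn[2, 2] - tabn[1, 2] * tabn[2, 1]) /
      sqrt(prod(c(r, cl)))
    expected <- outer(r, cl) / sum(tab)
    if (any(expected < 5)) {
      out$p_value <- stats::fisher.test(tab)$p.value
      out$test <- "fisher"
    } else {
      out$p_value <- stats::chisq.test(tab, correct = FALSE)$p.value
      out$test <- "chisq"
    }
  }
  class(out) <- "strand_bias"
  out
}

#' @export
print.strand_bias <- function(x, ...) {
  cat(sprintf("<strand_bias> %s: phi = %s, p = %s (%s test, n = %d)\n",
              x$category, format(x$phi, digits = 3),
              format(x$p_value, digits = 3), x$test, x$n))
  invisible(x)
}

#' GC-normalized sequence context of deamination sites
#'
#' Extracts the reference sequence around every deaminase-like SNV,
#' reverse-complementing G->A windows so that all are centered on the
#' deaminated cytosine, and tabulates per-offset base frequencies. The
#' frequencies are normalized for background composition: with background
#' probabilities bg(C) = bg(G) = gc/2 and bg(A) = bg(T) = (1-gc)/2, the
#' normalized probability is `p(b) = (f(b)/bg(b)) / sum_b' (f(b')/bg(b'))`.
#' At gc = 0.5 the normalization is the identity.
#'
#' @param snvs An [snv_set]; only CT/GA records are used.
#' @param genome A `DNAStringSet` (names must match chromosome names) or a
#'   FASTA path.
#' @param halfwidth Window half-width in bp (default 3, a 7-mer logo).
#' @param gc Background GC fraction (default 0.38, the yeast genome).
#' @return A list of class `context_matrix` with `counts`, `freq`, `prob`
#'   (4 x (2*halfwidth+1) matrices over offsets -halfwidth..halfwidth),
#'   `gc`, `n_used` and `n_skipped` (windows beyond contig ends or
#'   containing ambiguous bases).
#' @export
context_matrix <- function(snvs, genome, halfwidth = 3, gc = 0.38) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  snvs <- tibble::as_tibble(snvs)
  snvs <- snvs[snvs$mclass %in% c("CT", "GA"), , drop = FALSE]
  w <- as.integer(halfwidth)
  offsets <- -w:w
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4, 2 * w + 1, dimnames = list(bases, offsets))
  n_skipped <- 0L
  for (chr in unique(snvs$chrom)) {
    if (!chr %in% names(genome)) {
      n_skipped <- n_skipped + sum(snvs$chrom == chr)
      next
    }
    sub <- snvs[snvs$chrom == chr, , drop = FALSE]
    len <- Biostrings::width(genome[chr])
    ok <- sub$pos - w >= 1 & sub$pos + w <= len
    n_skipped <- n_skipped + sum(!ok)
    sub <- sub[ok, , drop = FALSE]
    if (!nrow(sub)) next
    win <- Biostrings::extractAt(
      genome[[chr]],
      IRanges::IRanges(sub$pos - w, sub$pos + w)
    )
    win[sub$mclass == "GA"] <- Biostrings::reverseComplement(win[sub$mclass == "GA"])
    keep_n <- !grepl("[^ACGT]", as.character(win))
    n_skipped <- n_skipped + sum(!keep_n)
    win <- win[keep_n]
    if (!length(win)) next
    m <- Biostrings::consensusMatrix(win)
    present <- intersect(rownames(m), bases)
    counts[present, ] <- counts[present, ] + m[present, , drop = FALSE]
  }
  n_used <- if (sum(counts)) sum(counts[, 1]) else 0L
  freq <- if (n_used) sweep(counts, 2, colSums(counts), "/") else counts * NA_real_
  bg <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  rel <- freq / bg[bases]
  prob <- sweep(rel, 2, colSums(rel), "/")
  out <- list(counts = counts, freq = freq, prob = prob, gc = gc,
              halfwidth = w, n_used = as.integer(n_used),
              n_skipped = n_skipped)
  class(out) <- "context_matrix"
  out
}

#' @export
print.context_matrix <- function(x, ...) {
  cat(sprintf("<context_matrix> %d-mer, %d windows (gc = %.2f), %d skipped\n",
              2 * x$halfwidth + 1, x$n_used, x$gc, x$n_skipped))
  print(round(x$prob, 3))
  invisible(x)
}

#' Association between gene expression and mutation load
#'
#' Counts SNVs per gene body (UTRs included), joins per-gene FPKM values,
#' reports median FPKM stratified by SNV count, and tests FPKM of mutated
#' (>= 1 SNV) against non-mutated genes with the two-sided
#' Wilcoxon-Mann-Whitney rank-sum test.
#'
#' @param snvs An [snv_set].
#' @param annotation A [genome_annotation].
#' @param fpkm A data frame whose first column is `gene_id` and whose
#'   remaining numeric columns are FPKM values (replicates are averaged when
#'   `average_replicates` is TRUE).
#' @param average_replicates Average replicate columns? (default TRUE)
#' @return A list of class `expression_association` with `genes` (per-gene
#'   tibble), `strata` (medians by SNV count), `median_mutated`,
#'   `median_unmutated`, `statistic`, `p_value` and `n_missing_fpkm`.
#' @export
expression_association <- function(snvs, annotation, fpkm,
                                   average_replicates = TRUE) {
  fpkm <- tibble::as_tibble(fpkm)
  names(fpkm)[1] <- "gene_id"
  num_cols <- names(fpkm)[-1][vapply(fpkm[-1], is.numeric, logical(1))]
  if (!length(num_cols)) stop("fpkm table has no numeric value column")
  vals <- if (average_replicates) {
    rowMeans(fpkm[num_cols], na.rm = TRUE)
  } else {
    fpkm[[num_cols[1]]]
  }
  fpkm <- tibble::tibble(gene_id = fpkm$gene_id, fpkm = vals)
  g <- annotation$genes
  counts <- GenomicRanges::countOverlaps(annotation$body, snv_granges(snvs),
                                         ignore.strand = TRUE)
  genes <- tibble::tibble(
    gene_id = S4Vectors::mcols(annotation$body)$gene_id,
    n_snvs = as.integer(counts)
  )
  genes <- dplyr::left_join(genes, fpkm, by = "gene_id")
  n_missing <- sum(is.na(genes$fpkm))
  genes <- genes[!is.na(genes$fpkm), , drop = FALSE]
  if (!nrow(genes)) stop("no overlap between the FPKM table and the annotation")
  strata <- dplyr::summarise(
    dplyr::group_by(genes, .data$n_snvs),
    n_genes = dplyr::n(),
    median_fpkm = stats::median(.data$fpkm),
    .groups = "drop"
  )
  mutated <- genes$fpkm[genes$n_snvs > 0]
  unmutated <- genes$fpkm[genes$n_snvs == 0]
  if (length(mutated) && length(unmutated)) {
    wt <- suppressWarnings(stats::wilcox.test(mutated, unmutated))
    statistic <- unname(wt$statistic)
    p_value <- wt$p.value
    # fully tied samples degenerate to no evidence against the null
    if (is.nan(p_value)) p_value <- 1
  } else {
    statistic <- NA_real_
    p_value <- NA_real_
  }
  out <- list(
    genes = genes, strata = strata,
    median_mutated = if (length(mutated)) stats::median(mutated) else NA_real_,
    median_unmutated = if (length(unmutated)) stats::median(unmutated) else NA_real_,
    statistic = statistic, p_value = p_value,
    n_missing_fpkm = n_missing
  )
  class(out) <- "expression_association"
  out
}

#' @export
print.expression_association <- function(x, ...) {
  cat(sprintf(
    "<expression_association> median FPKM mutated %.1f vs unmutated %.1f (rank-sum p = %s)\n",
    x$median_mutated, x$median_unmutated, format(x$p_value, digits = 3)
  ))
  invisible(x)
}
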