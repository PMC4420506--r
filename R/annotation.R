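#' Construct a genome annotation from a gene table
#'
#' Holds gene models (strand, CDS, optional 5'/3'-UTRs, ncRNAs) together with
#' interval indices for overlap queries. Coordinates are 1-based inclusive
#' throughout, matching GFF3. For a Watson (+) strand gene the 5'-UTR lies
#' immediately left of the CDS; for a Crick (-) strand gene it lies
#' immediately right of it.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `kind` (`"protein_coding"` or `"ncRNA"`), `cds_start`,
#'   `cds_end`, and optional `utr5_start`, `utr5_end`, `utr3_start`,
#'   `utr3_end` (NA when absent). For ncRNAs only `body_start`/`body_end`
#'   are required; they default to the CDS columns otherwise.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes) {
  genes <- tibble::as_tibble(genes)
  for (col in c("utr5_start", "utr5_end", "utr3_start", "utr3_end")) {
    if (!col %in% names(genes)) genes[[col]] <- NA_integer_
  }
  if (!"kind" %in% names(genes)) genes$kind <- "protein_coding"
  if (!"body_start" %in% names(genes)) {
    genes$body_start <- pmin(genes$cds_start, genes$utr5_start, genes$utr3_start, na.rm = TRUE)
    genes$body_end <- pmax(genes$cds_end, genes$utr5_end, genes$utr3_end, na.rm = TRUE)
  }
  pc <- genes[genes$kind == "protein_coding", , drop = FALSE]
  bad <- with(pc, which(
    (strand == "+" & !is.na(utr5_end) & utr5_end >= cds_start) |
    (strand == "-" & !is.na(utr5_start) & utr5_start <= cds_end)
  ))
  if (length(bad)) {
    stop("5'-UTR does not lie upstream of the CDS for gene(s): ",
         paste(pc$gene_id[bad], collapse = ", "))
  }
  gr <- function(df, s, e) {
    keep <- !is.na(df[[s]])
    df <- df[keep, , drop = FALSE]
    g <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df[[s]], df[[e]]),
      strand = df$strand
    )
    S4Vectors::mcols(g)$gene_id <- df$gene_id
    g
  }
  out <- list(
    genes = genes,
    body = gr(genes, "body_start", "body_end"),
    cds = gr(pc, "cds_start", "cds_end"),
    utr5 = gr(pc, "utr5_start", "utr5_end"),
    utr3 = gr(pc, "utr3_start", "utr3_end"),
    ncrna = gr(genes[genes$kind == "ncRNA", , drop = FALSE], "body_start", "body_end")
  )
  class(out) <- "genome_annotation"
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d genes (%d protein-coding, %d ncRNA) on %d chromosome(s); %d with 5'-UTR\n",
    nrow(x$genes), sum(x$genes$kind == "protein_coding"),
    sum(x$genes$kind == "ncRNA"), length(unique(x$genes$chrom)),
    sum(!is.na(x$genes$utr5_start))
  ))
  invisible(x)
}

#' Read a genome annotation from GFF3
#'
#' Expects `gene` (and optionally `ncRNA`/`ncRNA_gene`) records carrying an
#' `ID`, with `CDS`, `five_prime_UTR` and `three_prime_UTR` children whose
#' `Parent` names the gene (an mRNA level in between is followed through).
#' Multi-interval CDS records are collapsed to their min/max extent.
#'
#' @param path Path to a GFF3 file.
#' @return A [genome_annotation].
#' @export
read_annotation <- function(path) {
  gff <- rtracklayer::import(path)
  type <- as.character(gff$type)
  id <- if (!is.null(gff$ID)) as.character(gff$ID) else rep(NA_character_, length(gff))
  parent <- if (!is.null(gff$Parent)) {
    vapply(gff$Parent, function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gff))

  is_gene <- type %in% c("gene", "ncRNA_gene", "ncRNA")
  # map every feature to its ancestor gene (resolve one mRNA/transcript level)
  parent_of <- stats::setNames(parent, id)
  to_gene <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% id[is_gene]) return(p)
    gp <- parent_of[p]
    if (!is.na(gp) && gp %in% id[is_gene]) gp else p
  }
  gene_idx <- which(is_gene)
  if (!length(gene_idx)) stop("no gene records found in ", path)
  genes <- tibble::tibble(
    gene_id = id[gene_idx],
    chrom = as.character(GenomeInfoDb::seqnames(gff))[gene_idx],
    strand = as.character(BiocGenerics::strand(gff))[gene_idx],
    kind = ifelse(type[gene_idx] == "gene", "protein_coding", "ncRNA"),
    body_start = GenomicRanges::start(gff)[gene_idx],
    body_end = GenomicRanges::end(gff)[gene_idx],
    cds_start = NA_integer_, cds_end = NA_integer_,
    utr5_start = NA_integer_, utr5_end = NA_integer_,
    utr3_start = NA_integer_, utr3_end = NA_integer_
  )
  fill <- function(genes, ftype, s_col, e_col) {
    sel <- which(type == ftype)
    if (!length(sel)) return(genes)
    gid <- vapply(parent[sel], to_gene, character(1))
    agg_s <- tapply(GenomicRanges::start(gff)[sel], gid, min)
    agg_e <- tapply(GenomicRanges::end(gff)[sel], gid, max)
    m <- match(genes$gene_id, names(agg_s))
    genes[[s_col]] <- ifelse(is.na(m), genes[[s_col]], as.integer(agg_s[m]))
    genes[[e_col]] <- ifelse(is.na(m), genes[[e_col]], as.integer(agg_e[m]))
    genes
  }
  genes <- fill(genes, "CDS", "cds_start", "cds_end")
  genes <- fill(genes, "five_prime_UTR", "utr5_start", "utr5_end")
  genes <- fill(genes, "three_prime_UTR", "utr3_start", "utr3_end")
  pc_no_cds <- genes$kind == "protein_coding" & is.na(genes$cds_start)
  if (any(pc_no_cds)) {
    # genes without CDS children: treat the gene body as the CDS
    genes$cds_start[pc_no_cds] <- genes$body_start[pc_no_cds]
    genes$cds_end[pc_no_cds] <- genes$body_end[pc_no_cds]
  }
  genome_annotation(genes)
}

#' Write a genome annotation to GFF3
#'
#' @param annotation A [genome_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  g <- annotation$genes
  rows <- list()
  add <- function(type, s, e, id, par, keep) {
    if (!any(keep)) return()
    gr <- GenomicRanges::GRanges(
      g$chrom[keep], IRanges::IRanges(s[keep], e[keep]), strand = g$strand[keep]
    )
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- id[keep]
    S4Vectors::mcols(gr)$phase <- if (type == "CDS") 0L else NA_integer_
    if (!is.null(par)) S4Vectors::mcols(gr)$Parent <- par[keep]
    rows[[length(rows) + 1L]] <<- gr
  }
  pc <- g$kind == "protein_coding"
  add("gene", g$body_start, g$body_end, g$gene_id, NULL, pc)
  add("ncRNA", g$body_start, g$body_end, g$gene_id, NULL, !pc)
  add("CDS", g$cds_start, g$cds_end, paste0(g$gene_id, ".cds"), g$gene_id,
      pc & !is.na(g$cds_start))
  add("five_prime_UTR", g$utr5_start, g$utr5_end, paste0(g$gene_id, ".utr5"),
      g$gene_id, pc & !is.na(g$utr5_start))
  add("three_prime_UTR", g$utr3_start, g$utr3_end, paste0(g$gene_id, ".utr3"),
      g$gene_id, pc & !is.na(g$utr3_start))
  all <- suppressWarnings(do.call(c, rows))
  all <- BiocGenerics::sort(all, ignore.strand = TRUE)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read a repeat/low-confidence mask from BED
#'
#' BED intervals (0-based half-open on disk) become 1-based inclusive
#' `GRanges` in memory.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` of masked intervals.
#' @export
read_mask <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write mask intervals to BED
#' @param mask A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  rtracklayer::export(mask, path, format = "bed")
  invisible(path)
}

snv_granges <- function(snvs) {
  GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos, snvs$pos))
}

#' Assign each SNV to a genomic feature category
#'
#' Each SNV gets exactly one category under the fixed priority
#' CDS > UTR5 > UTR3 > ncRNA > intergenic, plus a gene-strand context
#' describing the strands of all gene bodies (UTRs included) covering the
#' position: `plus_only`, `minus_only`, `both` or `none`. Chromosomes absent
#' from the annotation are categorized intergenic with a warning.
#'
#' @param snvs An [snv_set] (or tibble with `chrom`, `pos`).
#' @param annotation A [genome_annotation].
#' @return The input tibble with `category` and `strand_context` columns
#'   appended.
#' @export
assign_features <- function(snvs, annotation) {
  gr <- snv_granges(snvs)
  miss <- !(snvs$chrom %in% unique(annotation$genes$chrom))
  if (any(miss)) {
    warning(sum(miss), " SNV(s) on chromosome(s) absent from the annotation; ",
            "categorized as intergenic")
  }
  hits <- function(x) {
    suppressWarnings(GenomicRanges::countOverlaps(gr, x, ignore.strand = TRUE) > 0)
  }
  category <- rep("intergenic", nrow(snvs))
  category[hits(annotation$ncrna)] <- "ncRNA"
  category[hits(annotation$utr3)] <- "UTR3"
  category[hits(annotation$utr5)] <- "UTR5"
  category[hits(annotation$cds)] <- "CDS"
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, annotation$body, ignore.strand = TRUE)
  )
  st <- as.character(BiocGenerics::strand(annotation$body))[S4Vectors::subjectHits(ov)]
  has_plus <- tabulate(S4Vectors::queryHits(ov)[st == "+"], nbins = nrow(snvs)) > 0
  has_minus <- tabulate(S4Vectors::queryHits(ov)[st == "-"], nbins = nrow(snvs)) > 0
  strand_context <- dplyr::case_when(
    has_plus & has_minus ~ "both",
    has_plus ~ "plus_only",
    has_minus ~ "minus_only",
    TRUE ~ "none"
  )
  out <- tibble::as_tibble(snvs)
  out$category <- category
  out$strand_context <- strand_context
  out
}

#' Write detected clusters to BED6 and TSV
#'
#' The BED file is 0-based half-open with the cluster id as name and
#' `round(1000 * power)` (capped at 1000) as score; the TSV carries the full
#' per-cluster statistics.
#'
#' @param clusters A cluster tibble from [detect_clusters()].
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.tsv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_clusters <- function(clusters, prefix) {
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  if (nrow(clusters)) {
    bed <- data.frame(
      chrom = clusters$chrom,
      start = clusters$start - 1L,
      end = clusters$end,
      name = clusters$cluster_id,
      score = pmin(round(1000 * clusters$power), 1000),
      strand = "."
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  tab <- clusters[, setdiff(names(clusters), "members")]
  readr::write_tsv(tab, tsv_path)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
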