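#' Classify a base substitution by deamination signature
#'
#' In a uracil-glycosylase-deficient (ung1) background every cytosine
#' deamination is read out directly as a substitution: a C deaminated on the
#' Watson (reference) strand appears as C->T, one deaminated on the Crick
#' strand as G->A. All other substitutions are non-deaminase-like.
#'
#' @param ref,alt Character vectors of single reference/alternative bases
#'   (A, C, G or T). Recycled to a common length.
#' @return Character vector with elements `"CT"`, `"GA"` or `"OTHER"`.
#' @examples
#' classify_substitution("C", "T")  # "CT"
#' classify_substitution("G", "A")  # "GA"
#' classify_substitution("A", "G")  # "OTHER"
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt must be single bases in {A, C, G, T}")
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ")
  }
  out <- rep("OTHER", length(ref))
  out[ref == "C" & alt == "T"] <- "CT"
  out[ref == "G" & alt == "A"] <- "GA"
  out
}

new_snv_set <- function(df, label = NULL, sample_ids = NULL) {
  df <- dplyr::arrange(df, .data$chrom, .data$pos)
  df <- tibble::as_tibble(df)
  attr(df, "label") <- label
  attr(df, "sample_ids") <- sample_ids %||% sort(unique(df$sample_id))
  class(df) <- c("snv_set", class(df))
  df
}

#' Construct a set of SNV calls
#'
#' The basic container of the package: one row per substitution call, sorted
#' by (chromosome, position). Several samples may contribute records at the
#' same position; duplicates are retained, so zero inter-mutation distances
#' are legal downstream.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Single reference/alternative bases.
#' @param sample_id Sample labels (recycled).
#' @param label Optional label for the set (e.g. mutagen/genotype).
#' @return A tibble of class `snv_set` with columns `chrom`, `pos`, `ref`,
#'   `alt`, `sample_id` and `mclass` (CT / GA / OTHER).
#' @examples
#' snv_set("chrI", c(100, 250), c("C", "G"), c("T", "A"), "clone1")
#' @export
snv_set <- function(chrom, pos, ref, alt, sample_id = "sample1", label = NULL) {
  pos <- as.integer(pos)
  if (length(pos) && any(pos < 1L)) stop("positions must be >= 1")
  df <- tibble::tibble(
    chrom = as.character(chrom),
    pos = pos,
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    sample_id = as.character(rep_len(sample_id, length(pos)))
  )
  df$mclass <- if (nrow(df)) classify_substitution(df$ref, df$alt) else character()
  new_snv_set(df, label = label)
}

#' @export
print.snv_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "<snv_set>%s %d SNVs, %d sample(s), %d chromosome(s)\n",
    if (!is.null(lab)) paste0(" [", lab, "]") else "",
    nrow(x), length(attr(x, "sample_ids")), length(unique(x$chrom))
  ))
  NextMethod()
}

#' Read SNV calls from VCF or a minimal tab-separated dialect
#'
#' VCF input is parsed with `VariantAnnotation::readVcf()`; only biallelic
#' single-nucleotide records are kept, and the number of skipped records
#' (indels, multi-allelic or symbolic alleles) is reported and stored in the
#' `n_skipped` attribute. The TSV dialect is five tab-separated columns --
#' chrom, 1-based position, ref, alt, sample id -- with `#` comment lines.
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param sample_id Sample label; overrides the VCF sample column and fills
#'   in for TSVs without one.
#' @param label Optional set label.
#' @return An [snv_set].
#' @export
read_snvs <- function(path, format = c("auto", "vcf", "tsv"),
                      sample_id = NULL, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_snvs_vcf(path, sample_id, label) else read_snvs_tsv(path, sample_id, label)
}

read_snvs_vcf <- function(path, sample_id, label) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- VariantAnnotation::ref(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  alt1 <- rep(NA_character_, length(rr))
  alt1[n_alt == 1L] <- as.character(unlist(alt[n_alt == 1L]))
  keep <- Biostrings::width(ref) == 1L & n_alt == 1L &
    !is.na(alt1) & alt1 %in% c("A", "C", "G", "T") &
    as.character(ref) != alt1
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(n_skipped, " non-SNV (indel/multi-allelic/symbolic) record(s) skipped in ", path)
  }
  vcf_samples <- VariantAnnotation::samples(VariantAnnotation::header(vcf))
  sid <- sample_id %||% (if (length(vcf_samples)) vcf_samples[1] else "sample1")
  out <- snv_set(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = as.character(ref)[keep],
    alt = alt1[keep],
    sample_id = sid,
    label = label
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

read_snvs_tsv <- function(path, sample_id, label) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos", "ref", "alt", "sample_id"),
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE
  )
  if (!nrow(df)) {
    return(snv_set(character(), integer(), character(), character(), label = label))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | is.na(df$chrom) | is.na(df$ref) | is.na(df$alt))
  if (length(bad)) {
    stop("unparseable SNV record at data row ", bad[1], " of ", path)
  }
  sid <- if (all(is.na(df$sample_id))) sample_id %||% "sample1" else df$sample_id
  snv_set(df$chrom, pos, df$ref, df$alt, sid, label = label)
}

#' Write SNV calls to TSV or single-sample VCF
#'
#' The TSV form is the package's five-column dialect and round-trips through
#' [read_snvs()] exactly. The VCF form is a minimal sites-format VCF 4.2 and
#' requires a single-sample set (pooled sets lose sample identity in VCF).
#'
#' @param x An [snv_set].
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_snvs <- function(x, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- c(
      "# chrom\tpos\tref\talt\tsample_id",
      sprintf("%s\t%d\t%s\t%s\t%s", x$chrom, x$pos, x$ref, x$alt, x$sample_id)
    )
    writeLines(lines, path)
  } else {
    sids <- unique(x$sample_id)
    if (length(sids) > 1) {
      stop("VCF output requires a single-sample set; split by sample_id first")
    }
    lines <- c(
      "##fileformat=VCFv4.2",
      sprintf("##source=mutclust"),
      sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
              if (length(sids)) sids else "sample1"),
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0/1", x$chrom, x$pos, x$ref, x$alt)
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Pool per-sample SNV sets
#'
#' Mutation clustering gains sensitivity when clones induced by the same
#' mutagen are pooled; records at the same position contributed by different
#' samples are kept as distinct rows.
#'
#' @param sets A list of [snv_set] objects (or a single one).
#' @param label Label for the pooled set.
#' @return An [snv_set] whose size is the sum of the input sizes.
#' @export
pool_samples <- function(sets, label = NULL) {
  if (inherits(sets, "snv_set")) sets <- list(sets)
  if (!length(sets)) stop("pool_samples() needs at least one input set")
  if (!all(vapply(sets, inherits, logical(1), "snv_set"))) {
    stop("all inputs must be snv_set objects")
  }
  df <- dplyr::bind_rows(lapply(sets, function(s) tibble::as_tibble(s)))
  new_snv_set(df, label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
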