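#' Configuration of the synthetic mutagenized-genome generator
#'
#' The generator emulates a pooled SNV call set from deaminase-mutagenized
#' diploid clones: a random genome at yeast GC content, non-overlapping gene
#' models with UTRs on both strands, a repeat mask, log-normal per-gene
#' expression, and SNVs made of (i) planted clusters of strand-coordinated
#' deaminations anchored near transcription starts of expression-weighted
#' genes and (ii) a uniform deamination background with a small
#' non-deaminase-like fraction. `sub1_mode` mimics the loss of the Sub1
#' ssDNA-binding factor: half of the planted clusters move to a second peak
#' upstream of the 5'-UTR, clustered deaminations shift toward the
#' transcribed strand, and the background rate inside CDS is halved.
#'
#' Defaults give ~400 SNVs on a 1 Mb chromosome (20 clusters of 5-15 SNVs
#' within <= 500 bp spans plus a 2e-4/bp background), matching the
#' per-genome density scale of heavily mutagenized yeast clones.
#'
#' @param n_chromosomes,chrom_length,gc Genome layout and base composition.
#' @param n_genes,n_ncrna Gene counts (protein-coding / ncRNA).
#' @param cds_len_range,utr5_len_range,utr3_len_range Uniform length ranges
#'   (bp) for gene parts.
#' @param p_plus_strand Probability a gene lies on the Watson strand.
#' @param mask_fraction Fraction of the genome masked (placed intergenically,
#'   away from gene starts).
#' @param fpkm_meanlog,fpkm_sdlog Log-normal expression parameters.
#' @param background_rate Background SNVs per unmasked bp.
#' @param other_frac Fraction of background SNVs that are
#'   non-deaminase-like.
#' @param n_clusters,cluster_size_range,cluster_span_range Planted-cluster
#'   layout.
#' @param tss_window Offset window (bp, relative to the CDS start) in which
#'   cluster centers are placed.
#' @param sub1_window Second-peak window used for half the clusters in
#'   `sub1_mode`.
#' @param p_nt Probability that a clustered deamination hits the
#'   non-transcribed strand.
#' @param sub1_p_nt Replacement for `p_nt` in `sub1_mode` (bias suppressed).
#' @param expression_coupling Exponent of the FPKM weighting used to pick
#'   anchor genes.
#' @param sub1_mode Logical.
#' @param n_samples Number of clones the records are distributed over.
#' @param seed Integer seed (< 2^30); the whole dataset is a deterministic
#'   function of the configuration.
#' @param label Label for the pooled set.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 1, chrom_length = 1e6, gc = 0.38,
                              n_genes = 300, n_ncrna = 10,
                              cds_len_range = c(300, 1500),
                              utr5_len_range = c(20, 200),
                              utr3_len_range = c(50, 200),
                              p_plus_strand = 0.5,
                              mask_fraction = 0.02,
                              fpkm_meanlog = 4, fpkm_sdlog = 1,
                              background_rate = 2e-4, other_frac = 0.02,
                              n_clusters = 20,
                              cluster_size_range = c(5, 15),
                              cluster_span_range = c(100, 500),
                              tss_window = c(-100, 0),
                              sub1_window = c(-250, -100),
                              p_nt = 0.8, sub1_p_nt = 0.5,
                              expression_coupling = 1,
                              sub1_mode = FALSE, n_samples = 4,
                              seed = 1, label = "synthetic") {
  cfg <- as.list(environment())
  stopifnot(
    cfg$gc > 0, cfg$gc < 1, cfg$mask_fraction >= 0, cfg$mask_fraction < 1,
    cfg$background_rate >= 0, cfg$other_frac >= 0, cfg$other_frac <= 1,
    cfg$p_nt >= 0, cfg$p_nt <= 1, cfg$n_samples >= 1,
    cfg$seed == as.integer(cfg$seed), abs(cfg$seed) < 2^30
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic reference: genome, annotation, masks, expression
#'
#' Deterministic given the configuration (`set.seed(config$seed)` is called
#' internally).
#'
#' @param config A [simulation_config].
#' @return A list of class `sim_reference` with `genome` (`DNAStringSet`),
#'   `annotation` ([genome_annotation]), `masks` (`GRanges`), `fpkm`
#'   (tibble) and `config`.
#' @export
generate_reference <- function(config) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  seqs <- lapply(chroms, function(ch) {
    paste(sample(bases, config$chrom_length, replace = TRUE, prob = probs),
          collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  # distribute genes over chromosomes, then place left to right with random
  # intergenic gaps
  n_total <- config$n_genes + config$n_ncrna
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n_total))
  kind <- sample(rep(c("protein_coding", "ncRNA"),
                     c(config$n_genes, config$n_ncrna)))
  runi <- function(n, r) round(stats::runif(n, r[1], r[2]))
  cds_len <- runi(n_total, config$cds_len_range)
  utr5_len <- runi(n_total, config$utr5_len_range)
  utr3_len <- runi(n_total, config$utr3_len_range)
  nc_len <- runi(n_total, c(200, 1000))
  foot <- ifelse(kind == "protein_coding", cds_len + utr5_len + utr3_len, nc_len)
  strand <- ifelse(stats::runif(n_total) < config$p_plus_strand, "+", "-")

  rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    idx <- which(chrom_of == ci)
    if (!length(idx)) next
    free <- config$chrom_length - sum(foot[idx])
    if (free < 50 * (length(idx) + 1)) {
      stop("cannot place ", length(idx), " genes without overlap on a ",
           config$chrom_length, " bp chromosome")
    }
    w <- stats::rgamma(length(idx) + 1, 1) + 0.05
    gaps <- floor(free * w / sum(w))
    start <- cumsum(c(1 + gaps[1], utils::head(foot[idx] + gaps[-1], -1)))
    for (j in seq_along(idx)) {
      i <- idx[j]
      s <- start[j]
      if (kind[i] == "ncRNA") {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = sprintf("nc%04d", i), chrom = chroms[ci],
          strand = strand[i], kind = "ncRNA",
          body_start = s, body_end = s + foot[i] - 1L,
          cds_start = NA_integer_, cds_end = NA_integer_,
          utr5_start = NA_integer_, utr5_end = NA_integer_,
          utr3_start = NA_integer_, utr3_end = NA_integer_
        )
      } else {
        e <- s + foot[i] - 1L
        if (strand[i] == "+") {
          u5 <- c(s, s + utr5_len[i] - 1L)
          cds <- c(u5[2] + 1L, u5[2] + cds_len[i])
          u3 <- c(cds[2] + 1L, e)
        } else {
          u3 <- c(s, s + utr3_len[i] - 1L)
          cds <- c(u3[2] + 1L, u3[2] + cds_len[i])
          u5 <- c(cds[2] + 1L, e)
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gene_id = sprintf("g%04d", i), chrom = chroms[ci],
          strand = strand[i], kind = "protein_coding",
          body_start = s, body_end = e,
          cds_start = cds[1], cds_end = cds[2],
          utr5_start = u5[1], utr5_end = u5[2],
          utr3_start = u3[1], utr3_end = u3[2]
        )
      }
    }
  }
  genes <- dplyr::bind_rows(rows)
  annotation <- genome_annotation(genes)

  # masks: random intervals in intergenic space, kept >= 300 bp away from
  # gene bodies so planted TSS-proximal clusters are never masked
  masks <- list()
  target <- config$mask_fraction * config$n_chromosomes * config$chrom_length
  if (target > 0) {
    pad <- GenomicRanges::resize(annotation$body,
                                 BiocGenerics::width(annotation$body) + 600,
                                 fix = "center")
    allowed <- GenomicRanges::gaps(GenomicRanges::reduce(pad, ignore.strand = TRUE))
    allowed <- allowed[BiocGenerics::strand(allowed) == "*" &
                         BiocGenerics::width(allowed) >= 300]
    GenomeInfoDb::seqlevels(allowed) <- chroms
    allowed <- allowed[sample(length(allowed))]
    got <- 0
    for (k in seq_along(allowed)) {
      if (got >= target) break
      len_k <- BiocGenerics::width(allowed)[k]
      take <- min(len_k, round(stats::runif(1, 200, 2000)))
      off <- floor(stats::runif(1, 0, len_k - take + 1))
      masks[[length(masks) + 1L]] <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(allowed)[k],
        IRanges::IRanges(GenomicRanges::start(allowed)[k] + off, width = take)
      )
      got <- got + take
    }
  }
  masks <- if (length(masks)) {
    BiocGenerics::sort(do.call(c, masks))
  } else {
    GenomicRanges::GRanges()
  }

  fpkm <- tibble::tibble(
    gene_id = genes$gene_id,
    fpkm = round(stats::rlnorm(nrow(genes), config$fpkm_meanlog,
                               config$fpkm_sdlog), 2)
  )
  out <- list(genome = genome, annotation = annotation, masks = masks,
              fpkm = fpkm, config = config)
  class(out) <- "sim_reference"
  out
}

site_positions <- function(chrseq, base) {
  BiocGenerics::start(Biostrings::matchPattern(base, chrseq))
}

#' Generate synthetic SNVs with planted clusters and ground truth
#'
#' Clustered SNVs: each planted cluster picks an anchor gene with
#' probability proportional to FPKM^coupling, places its center uniformly in
#' the configured window relative to the CDS start (on the gene's own 5'->3'
#' axis), and draws members uniformly among strand-appropriate cytosine
#' sites within the cluster span -- a C->T needs a reference C, a G->A a
#' reference G, so deaminations are only planted where the chosen strand
#' offers a cytosine. Background SNVs fall uniformly on unmasked deamination-
#' eligible sites, with a configurable non-deaminase-like fraction placed at
#' arbitrary unmasked bases. Records are distributed across `n_samples`
#' clones. Deterministic given the configuration.
#'
#' @param reference A [generate_reference()] result.
#' @param config A [simulation_config] (defaults to the reference's).
#' @return A list with `snvs` (an [snv_set]) and `truth` (a tibble with one
#'   row per planted cluster: `cluster_id`, `chrom`, `start`, `end`, `size`,
#'   `gene_id`, `n_nontranscribed` and a `positions` list-column).
#' @export
generate_mutations <- function(reference, config = reference$config) {
  set.seed(config$seed + 1L)
  genome <- reference$genome
  ann <- reference$annotation
  chroms <- names(genome)
  chrom_len <- stats::setNames(Biostrings::width(genome), chroms)
  samples_ids <- sprintf("S%d", seq_len(config$n_samples))

  masked <- reference$masks
  unmask <- function(pos, chr) {
    if (!length(masked) || !length(pos)) return(pos)
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos))
    pos[GenomicRanges::countOverlaps(gr, masked) == 0]
  }
  c_sites <- lapply(chroms, function(ch) unmask(site_positions(genome[[ch]], "C"), ch))
  g_sites <- lapply(chroms, function(ch) unmask(site_positions(genome[[ch]], "G"), ch))
  names(c_sites) <- names(g_sites) <- chroms

  genes <- ann$genes[ann$genes$kind == "protein_coding", , drop = FALSE]
  genes <- dplyr::left_join(genes, reference$fpkm, by = "gene_id")
  if (config$n_clusters > nrow(genes)) {
    stop("more clusters requested than genes available as anchors")
  }
  wts <- genes$fpkm^config$expression_coupling
  anchors <- sample(nrow(genes), config$n_clusters, prob = wts / sum(wts))
  p_nt_eff <- if (config$sub1_mode) config$sub1_p_nt else config$p_nt

  snv_rows <- list()
  truth <- list()
  for (k in seq_len(config$n_clusters)) {
    gene <- genes[anchors[k], ]
    size <- sample(seq(config$cluster_size_range[1], config$cluster_size_range[2]), 1)
    span <- stats::runif(1, config$cluster_span_range[1], config$cluster_span_range[2])
    window <- config$tss_window
    if (config$sub1_mode && stats::runif(1) < 0.5) window <- config$sub1_window
    nt <- stats::runif(size) < p_nt_eff
    mclass <- ifelse(xor(nt, gene$strand == "-"), "CT", "GA")
    placed <- NULL
    for (try in seq_len(20)) {
      center_off <- stats::runif(1, window[1], window[2])
      center <- if (gene$strand == "+") gene$cds_start + center_off else
        gene$cds_end - center_off
      lo <- max(1, round(center - span / 2))
      hi <- min(chrom_len[[gene$chrom]], round(center + span / 2))
      cc <- c_sites[[gene$chrom]]
      gg <- g_sites[[gene$chrom]]
      cand_ct <- cc[cc >= lo & cc <= hi]
      cand_ga <- gg[gg >= lo & gg <= hi]
      if (length(cand_ct) >= sum(mclass == "CT") &&
          length(cand_ga) >= sum(mclass == "GA")) {
        pos <- integer(size)
        pos[mclass == "CT"] <- cand_ct[sample.int(length(cand_ct), sum(mclass == "CT"))]
        pos[mclass == "GA"] <- cand_ga[sample.int(length(cand_ga), sum(mclass == "GA"))]
        placed <- pos
        break
      }
    }
    if (is.null(placed)) {
      stop("could not place cluster ", k, ": no eligible C/G sites in window")
    }
    ord <- order(placed)
    snv_rows[[length(snv_rows) + 1L]] <- tibble::tibble(
      chrom = gene$chrom, pos = placed[ord],
      ref = ifelse(mclass[ord] == "CT", "C", "G"),
      alt = ifelse(mclass[ord] == "CT", "T", "A"),
      sample_id = sample(samples_ids, size, replace = TRUE)
    )
    truth[[length(truth) + 1L]] <- tibble::tibble(
      cluster_id = sprintf("truth_%03d", k),
      chrom = gene$chrom, start = min(placed), end = max(placed),
      size = size, gene_id = gene$gene_id,
      n_nontranscribed = sum(nt),
      positions = list(sort(placed))
    )
  }

  # uniform background over unmasked eligible sites
  unmasked_len <- sum(chrom_len) - sum(BiocGenerics::width(masked))
  n_bg <- stats::rpois(1, config$background_rate * unmasked_len)
  if (n_bg > 0) {
    bg_chrom <- sample(chroms, n_bg, replace = TRUE,
                       prob = chrom_len / sum(chrom_len))
    is_other <- stats::runif(n_bg) < config$other_frac
    bg <- vector("list", n_bg)
    other_alts <- list(A = c("C", "T"), C = c("A", "G"),
                       G = c("C", "T"), T = c("A", "C", "G"))
    for (i in seq_len(n_bg)) {
      ch <- bg_chrom[i]
      if (is_other[i]) {
        pos <- sample(chrom_len[[ch]], 1)
        while (length(masked) &&
               GenomicRanges::countOverlaps(
                 GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos)),
                 masked) > 0) {
          pos <- sample(chrom_len[[ch]], 1)
        }
        ref <- as.character(Biostrings::subseq(genome[[ch]], pos, pos))
        alt <- sample(other_alts[[ref]], 1)
      } else if (stats::runif(1) < 0.5) {
        pos <- c_sites[[ch]][sample.int(length(c_sites[[ch]]), 1)]
        ref <- "C"; alt <- "T"
      } else {
        pos <- g_sites[[ch]][sample.int(length(g_sites[[ch]]), 1)]
        ref <- "G"; alt <- "A"
      }
      bg[[i]] <- tibble::tibble(chrom = ch, pos = as.integer(pos), ref = ref,
                                alt = alt,
                                sample_id = sample(samples_ids, 1))
    }
    bg <- dplyr::bind_rows(bg)
    if (config$sub1_mode && nrow(bg)) {
      # CDS background halved: limited deaminase is spent at gene starts
      in_cds <- GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(bg$chrom, IRanges::IRanges(bg$pos, bg$pos)),
        ann$cds, ignore.strand = TRUE) > 0
      drop <- in_cds & stats::runif(nrow(bg)) < 0.5
      bg <- bg[!drop, , drop = FALSE]
    }
    snv_rows[[length(snv_rows) + 1L]] <- bg
  }

  df <- dplyr::bind_rows(snv_rows)
  snvs <- snv_set(df$chrom, df$pos, df$ref, df$alt, df$sample_id,
                  label = paste0(config$label,
                                 if (config$sub1_mode) "_sub1" else ""))
  list(snvs = snvs, truth = dplyr::bind_rows(truth))
}

#' Generate a full synthetic dataset (reference + mutations)
#'
#' @param config A [simulation_config].
#' @param out_dir Optional directory; when given, writes `genome.fasta`,
#'   `annotation.gff3`, `masks.bed`, `fpkm.tsv`, one `snvs_<sample>.vcf` per
#'   sample, `snvs.tsv` (pooled), and `truth.tsv`.
#' @return A list with `reference`, `snvs`, `truth`.
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  reference <- generate_reference(config)
  mut <- generate_mutations(reference, config)
  out <- list(reference = reference, snvs = mut$snvs, truth = mut$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(reference$genome, file.path(out_dir, "genome.fasta"))
    write_annotation(reference$annotation, file.path(out_dir, "annotation.gff3"))
    if (length(reference$masks)) {
      write_mask(reference$masks, file.path(out_dir, "masks.bed"))
    }
    readr::write_tsv(reference$fpkm, file.path(out_dir, "fpkm.tsv"))
    write_snvs(mut$snvs, file.path(out_dir, "snvs.tsv"), format = "tsv")
    for (sid in unique(mut$snvs$sample_id)) {
      one <- mut$snvs[mut$snvs$sample_id == sid, , drop = FALSE]
      write_snvs(new_snv_set(one), file.path(out_dir, paste0("snvs_", sid, ".vcf")),
                 format = "vcf")
    }
    tr <- mut$truth
    tr$positions <- vapply(tr$positions, paste, character(1), collapse = ",")
    readr::write_tsv(tr, file.path(out_dir, "truth.tsv"))
  }
  out
}

#' Compare detected clusters with planted ground truth
#'
#' A detected cluster matches a truth record when at least `min_frac` of the
#' truth members are among the detected members (positions on the same
#' chromosome). Recall is the fraction of truth records matched by some
#' detected cluster; precision the fraction of detected clusters matching
#' some truth record. A detected cluster covering two or more truth records
#' is flagged as a merge.
#'
#' @param detected A cluster tibble from [detect_clusters()].
#' @param truth A truth tibble from [generate_mutations()].
#' @param min_frac Member-overlap fraction required for a match (default
#'   0.5).
#' @return A list with `precision`, `recall` (NA when undefined),
#'   `n_detected`, `n_truth`, `matches` (per-truth tibble) and `n_merges`.
#' @export
evaluate_detection <- function(detected, truth, min_frac = 0.5) {
  n_det <- nrow(detected)
  n_truth <- nrow(truth)
  det_matched <- rep(FALSE, n_det)
  det_n_truth <- rep(0L, n_det)
  matches <- list()
  for (i in seq_len(n_truth)) {
    tpos <- truth$positions[[i]]
    best <- 0
    best_j <- NA_integer_
    for (j in seq_len(n_det)) {
      if (detected$chrom[j] != truth$chrom[i]) next
      frac <- sum(tpos %in% detected$members[[j]]$pos) / length(tpos)
      if (frac > best) {
        best <- frac
        best_j <- j
      }
      if (frac >= min_frac) {
        det_matched[j] <- TRUE
        det_n_truth[j] <- det_n_truth[j] + 1L
      }
    }
    matches[[i]] <- tibble::tibble(
      cluster_id = truth$cluster_id[i],
      best_fraction = best,
      matched = best >= min_frac,
      detected_id = if (!is.na(best_j)) detected$cluster_id[best_j] else NA_character_
    )
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(cluster_id = character(), best_fraction = numeric(),
                   matched = logical(), detected_id = character())
  list(
    precision = if (n_det) sum(det_matched) / n_det else NA_real_,
    recall = if (n_truth) sum(matches$matched) / n_truth else NA_real_,
    n_detected = n_det, n_truth = n_truth,
    matches = matches, n_merges = sum(det_n_truth >= 2L)
  )
}
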