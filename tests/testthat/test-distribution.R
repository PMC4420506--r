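test_that("deaminated-strand assignment maps class x gene strand correctly", {
  expect_equal(assign_deaminated_strand("CT", "+"), "non_transcribed")
  expect_equal(assign_deaminated_strand("GA", "+"), "transcribed")
  expect_equal(assign_deaminated_strand("CT", "-"), "transcribed")
  expect_equal(assign_deaminated_strand("GA", "-"), "non_transcribed")
  expect_equal(assign_deaminated_strand("OTHER", "+"), "undefined")
  # involution: flipping both the class and the strand preserves the call
  grid <- expand.grid(m = c("CT", "GA"), s = c("+", "-"),
                      stringsAsFactors = FALSE)
  flip_m <- c(CT = "GA", GA = "CT")[grid$m]
  flip_s <- c(`+` = "-", `-` = "+")[grid$s]
  expect_equal(assign_deaminated_strand(grid$m, grid$s),
               assign_deaminated_strand(flip_m, flip_s))
})

test_that("CDS-start density puts mass in the right 5 bp bins", {
  ann <- tiny_annotation()
  # gA is + with cds_start 1101: offsets -100..-1 are positions 1001..1100
  s <- snv_set("chrT", c(1001, 1100, 1101, 1150), "C", "T")
  prof <- density_around_cds_start(s, ann)
  expect_equal(sum(prof$fraction) * nrow(s), 4) # all SNVs inside the window
  frac_at <- function(b) prof$fraction[prof$bin_start == b]
  expect_equal(frac_at(-100), 0.25)  # pos 1001 -> offset -100
  expect_equal(frac_at(-5), 0.25)    # pos 1100 -> offset -1 -> bin [-5, 0)
  expect_equal(frac_at(0), 0.25)     # pos 1101 -> offset 0 (start codon)
  expect_equal(frac_at(45), 0.25)    # pos 1150 -> offset 49 -> bin [45, 50)
  # Crick-strand gene gB (cds_end 6100): the same offsets mirror
  s2 <- snv_set("chrT", c(6101, 6051), "G", "A")
  prof2 <- density_around_cds_start(s2, ann)
  expect_equal(prof2$fraction[prof2$bin_start == -5], 0.5)  # offset -1
  expect_equal(prof2$fraction[prof2$bin_start == 45], 0.5)  # offset 49
})

test_that("density fractions are normalized by the genome-wide SNV total", {
  ann <- tiny_annotation()
  s <- snv_set("chrT", c(1051, 30000), "C", "T")  # one in window, one far away
  prof <- density_around_cds_start(s, ann)
  expect_equal(sum(prof$fraction), 0.5)
  # duplicating every record leaves all fractions unchanged
  s2 <- pool_samples(list(s, snv_set("chrT", c(1051, 30000), "C", "T", "s2")))
  expect_equal(density_around_cds_start(s2, ann)$fraction, prof$fraction)
})

test_that("strand-resolved layers split the CDS-start profile by deaminated strand", {
  ann <- tiny_annotation()
  s <- snv_set("chrT", c(1051, 1052), c("C", "G"), c("T", "A"))  # + gene gA
  prof <- density_around_cds_start(s, ann, strand_layers = TRUE)
  nt <- prof[prof$layer == "non_transcribed", ]
  tr <- prof[prof$layer == "transcribed", ]
  expect_equal(sum(nt$fraction), 0.5)  # the C->T record
  expect_equal(sum(tr$fraction), 0.5)  # the G->A record
})

test_that("TSS tri-panel respects UTR length exclusion and percent binning", {
  ann <- tiny_annotation()
  # gA utr5 1001-1100 (length 100): position 1051 is offset 50 -> bin [50, 60)
  s <- snv_set("chrT", 1051, "C", "T")
  tri <- tss_tripanel_density(s, ann)
  expect_equal(tri$utr5$fraction[tri$utr5$bin_start == 50], 1)
  expect_equal(sum(tri$utr5$fraction), 1)
  # SNV at the TSS itself (first UTR base) -> [0, 10)
  tri2 <- tss_tripanel_density(snv_set("chrT", 1001, "C", "T"), ann)
  expect_equal(tri2$utr5$fraction[tri2$utr5$bin_start == 0], 1)
  # 1 bp upstream of the TSS -> last 5 bp bin of the pre-UTR panel
  tri3 <- tss_tripanel_density(snv_set("chrT", 1000, "C", "T"), ann)
  expect_equal(tri3$pre$fraction[tri3$pre$bin_start == -5], 1)
  expect_equal(sum(tri3$utr5$fraction), 0)
  # gC's 4 bp UTR is below the 10 bp minimum: its SNVs contribute nowhere
  tri4 <- tss_tripanel_density(snv_set("chrT", 8002, "C", "T"), ann)
  expect_equal(sum(tri4$pre$fraction) + sum(tri4$utr5$fraction) +
                 sum(tri4$cds$fraction), 0)
  # Crick gene gE: utr5 5'-end is utr5_end 16000; 15951 sits at offset 49
  tri5 <- tss_tripanel_density(snv_set("chrT", 15951, "G", "A"), ann)
  expect_equal(tri5$utr5$fraction[tri5$utr5$bin_start == 40], 1) # 49% of 100 bp
})

test_that("pre-UTR and UTR panels exclude SNVs hitting another gene's feature", {
  ann <- tiny_annotation()
  # an SNV 1 bp upstream of gD's UTR overlaps no other gene: counted
  tri <- tss_tripanel_density(snv_set("chrT", 14000, "C", "T"), ann)
  expect_equal(sum(tri$pre$fraction), 1)
  # divergent pair: gY (-) sits inside gX's (+) pre-UTR window
  ann2 <- genome_annotation(tibble::tibble(
    gene_id = c("gX", "gY"), chrom = "chrU", strand = c("+", "-"),
    kind = "protein_coding",
    cds_start = c(2101L, 1600L), cds_end = c(3000L, 1800L),
    utr5_start = c(2001L, 1801L), utr5_end = c(2100L, 1900L),
    utr3_start = c(3001L, 1500L), utr3_end = c(3100L, 1599L)
  ))
  # 1850 lies in gX's pre-UTR window (2001-300..2000) but inside gY's body:
  # excluded from gX's pre panel, yet counted in gY's own UTR panel at the
  # 50-60% bin (gY 5'-end is 1900, offset 50 of a 100 bp UTR)
  tri2 <- tss_tripanel_density(snv_set("chrU", 1850, "G", "A"), ann2)
  expect_equal(sum(tri2$pre$fraction), 0)
  expect_equal(tri2$utr5$fraction[tri2$utr5$bin_start == 50], 1)
  # 1950 is between the genes: inside gX's pre-UTR window, no other gene; it
  # is also upstream of gY's 5'-end (pre-UTR window 1901..2200... no: gY pre
  # window is 1901+1..? gY 5'-end 1900, window 1901-2200): counted once in
  # each panel because both windows cover it and neither overlaps a feature
  tri3 <- tss_tripanel_density(snv_set("chrU", 1950, "C", "T"), ann2)
  expect_equal(sum(tri3$pre$fraction), 2)
})

test_that("phi matches the closed-form 2x2 value and the Pearson cross-check", {
  ann <- tiny_annotation()
  # build SNV sets hitting gA (+ strand CDS) and gB (- strand CDS)
  mk <- function(n_ct_plus, n_ga_plus, n_ct_minus, n_ga_minus) {
    pos_plus <- 1101 + seq_len(n_ct_plus + n_ga_plus) # gA CDS
    pos_minus <- 5101 + seq_len(n_ct_minus + n_ga_minus) # gB CDS
    snv_set(
      "chrT", c(pos_plus, pos_minus),
      rep(c("C", "G", "C", "G"), c(n_ct_plus, n_ga_plus, n_ct_minus, n_ga_minus)),
      rep(c("T", "A", "T", "A"), c(n_ct_plus, n_ga_plus, n_ct_minus, n_ga_minus))
    )
  }
  sb <- strand_bias_phi(mk(40, 10, 10, 40), ann, "CDS")
  expect_equal(sb$phi, 0.6)  # (1600-100)/sqrt(50^4)
  expect_equal(sb$test, "chisq")
  expect_lt(sb$p_value, 1e-8)
  expect_equal(strand_bias_phi(mk(25, 25, 25, 25), ann, "CDS")$phi, 0)
  expect_equal(strand_bias_phi(mk(50, 0, 0, 50), ann, "CDS")$phi, 1)
  # phi equals the Pearson correlation of the two binary indicators
  set.seed(31)
  for (rep in 1:10) {
    counts <- sample(3:30, 4, replace = TRUE)
    sb2 <- strand_bias_phi(mk(counts[1], counts[2], counts[3], counts[4]), ann, "CDS")
    x <- rep(c(1, 0, 1, 0), counts)  # is CT
    y <- rep(c(1, 1, 0, 0), counts)  # is + gene
    expect_equal(sb2$phi, stats::cor(x, y), tolerance = 1e-12)
  }
  # small expected counts fall back to Fisher's exact test
  expect_equal(strand_bias_phi(mk(3, 1, 1, 3), ann, "CDS")$test, "fisher")
  # a zero margin leaves phi undefined
  expect_true(is.na(strand_bias_phi(mk(5, 0, 5, 0), ann, "CDS")$phi))
})

test_that("context matrix orients on the deaminated C and normalizes by GC", {
  # genome with four C sites whose +1 neighbours enumerate A, C, G, T and a
  # G site whose window reverse-complements onto a C center
  seqs <- Biostrings::DNAStringSet(c(
    chrC = "AAACAAAAAACCAAAAAACGAAAAAACTAAAAAAGAAAA"
  ))
  # C sites whose +1 neighbours enumerate A (pos 4), C (11), G (19), T (27)
  s <- snv_set("chrC", c(4, 11, 19, 27), "C", "T")
  cm <- context_matrix(s, seqs, halfwidth = 1, gc = 0.38)
  expect_equal(unname(cm$prob["C", "0"]), 1)  # centered on C by construction
  expect_equal(cm$freq[, "1"], c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  # uniform frequencies at gc = 0.38 give p(C)=p(G)=0.31, p(A)=p(T)=0.19
  expect_equal(round(unname(cm$prob[c("C", "G"), "1"]), 2), c(0.31, 0.31))
  expect_equal(round(unname(cm$prob[c("A", "T"), "1"]), 2), c(0.19, 0.19))
  # at gc = 0.5 the normalization is the identity
  cm5 <- context_matrix(s, seqs, halfwidth = 1, gc = 0.5)
  expect_equal(cm5$prob, cm5$freq)
  # a G>A record is reverse-complemented: G at 35 has left neighbour A,
  # so the oriented window's +1 offset shows the complement T
  sga <- snv_set("chrC", 35, "G", "A")
  cmg <- context_matrix(sga, seqs, halfwidth = 1)
  expect_equal(unname(cmg$counts["C", "0"]), 1)
  expect_equal(unname(cmg$counts["T", "1"]), 1)
  # windows running past the contig end are skipped and counted
  edge <- snv_set("chrC", 39, "C", "T")
  cme <- context_matrix(edge, seqs, halfwidth = 3)
  expect_equal(cme$n_skipped, 1)
  expect_equal(cme$n_used, 0)
})

test_that("expression association separates mutated from unmutated genes", {
  # ten genes, the five mutated ones expressed ~10x higher: the exact
  # two-sided rank-sum p for a clean 5 vs 5 separation is 2/252 ~ 0.0079
  starts <- seq(1000L, by = 5000L, length.out = 10L)
  ann <- genome_annotation(tibble::tibble(
    gene_id = sprintf("g%02d", 1:10), chrom = "chrE", strand = "+",
    kind = "protein_coding",
    cds_start = starts, cds_end = starts + 999L
  ))
  s <- snv_set("chrE", rep(starts[1:5], each = 2) + c(10L, 20L), "C", "T")
  fpkm <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    fpkm = c(90, 95, 100, 105, 110, 8, 9, 10, 11, 12)
  )
  ea <- expression_association(s, ann, fpkm)
  expect_equal(ea$median_mutated, 100)
  expect_equal(ea$median_unmutated, 10)
  expect_equal(ea$p_value, 2 / choose(10, 5))
  expect_equal(sum(ea$strata$n_genes), 10)
  expect_equal(ea$strata$n_genes[ea$strata$n_snvs == 2], 5)
  # identical FPKM everywhere: medians equal, p = 1
  fpkm2 <- fpkm
  fpkm2$fpkm <- 50
  ea2 <- expression_association(s, ann, fpkm2)
  expect_equal(ea2$median_mutated, ea2$median_unmutated)
  expect_equal(ea2$p_value, 1)
  # replicate columns are averaged; missing genes are counted
  fpkm3 <- tibble::tibble(gene_id = sprintf("g%02d", 1:3),
                          rep1 = c(90, 100, 10), rep2 = c(110, 90, 10))
  ea3 <- expression_association(s, ann, fpkm3)
  expect_equal(ea3$n_missing_fpkm, 7)
  expect_equal(ea3$genes$fpkm[ea3$genes$gene_id == "g01"], 100)
  expect_error(expression_association(s, ann,
                                      tibble::tibble(gene_id = "zz", fpkm = 1)),
               "no overlap")
})
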