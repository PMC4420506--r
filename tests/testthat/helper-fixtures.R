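# Small hand-built annotation used across tests.
#
# chrT layout (1-based, inclusive):
#   gA (+, protein_coding): utr5 1001-1100, cds 1101-2100, utr3 2101-2200
#   gB (-, protein_coding): utr3 5001-5100, cds 5101-6100, utr5 6101-6200
#   gC (+, protein_coding): utr5 8001-8004 (4 bp, below the 10 bp minimum),
#                           cds 8005-8800, utr3 8801-8900
#   nc1 (+, ncRNA):         12001-12400
#   gD (+) and gE (-) overlap around 15000:
#     gD: utr5 14001-14100, cds 14101-15100, utr3 15101-15200
#     gE: utr3 14901-15000, cds 15001-15900, utr5 15901-16000
tiny_annotation <- function() {
  genome_annotation(tibble::tibble(
    gene_id = c("gA", "gB", "gC", "nc1", "gD", "gE"),
    chrom = "chrT",
    strand = c("+", "-", "+", "+", "+", "-"),
    kind = c("protein_coding", "protein_coding", "protein_coding",
             "ncRNA", "protein_coding", "protein_coding"),
    body_start = c(1001L, 5001L, 8001L, 12001L, 14001L, 14901L),
    body_end = c(2200L, 6200L, 8900L, 12400L, 15200L, 16000L),
    cds_start = c(1101L, 5101L, 8005L, NA, 14101L, 15001L),
    cds_end = c(2100L, 6100L, 8800L, NA, 15100L, 15900L),
    utr5_start = c(1001L, 6101L, 8001L, NA, 14001L, 15901L),
    utr5_end = c(1100L, 6200L, 8004L, NA, 14100L, 16000L),
    utr3_start = c(2101L, 5001L, 8801L, NA, 15101L, 14901L),
    utr3_end = c(2200L, 5100L, 8900L, NA, 15200L, 15000L)
  ))
}

# A small deterministic simulation, fast enough for unit tests.
tiny_sim_config <- function(seed = 7, ...) {
  args <- list(chrom_length = 2e5, n_genes = 60, n_ncrna = 4, n_clusters = 5,
               background_rate = 1e-4, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

scipy_oracle_cases <- function() {
  jsonlite::read_json(test_path("fixtures", "hier_oracle.json"),
                      simplifyVector = TRUE)
}
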