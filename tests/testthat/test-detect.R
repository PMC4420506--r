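mk_members <- function(pos, mclass = "CT", sample_id = "s1", chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = ifelse(mclass == "CT", "C", ifelse(mclass == "GA", "G", "A")),
    alt = ifelse(mclass == "CT", "T", ifelse(mclass == "GA", "A", "G")),
    sample_id = rep_len(sample_id, length(pos)),
    mclass = rep_len(mclass, length(pos))
  )
}

test_that("mask filter removes any cluster touching a masked interval", {
  cl_masked <- mk_members(seq(1000, 1400, by = 100))
  cl_clean <- mk_members(seq(9000, 9400, by = 100))
  masks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1390, 1450))
  res <- filter_clusters(list(cl_masked, cl_clean), masks = masks)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start, 9000)
  expect_equal(unique(res$removed_snvs$reason), "cluster_overlaps_mask")
  expect_equal(nrow(res$removed_snvs), 5)
})

test_that("non-deaminase-like composition filter follows the single-SNV rescue rule", {
  # >1 OTHER member: cluster removed
  bad <- dplyr::bind_rows(mk_members(seq(100, 600, 100)),
                          mk_members(c(350, 450), mclass = "OTHER"))
  # exactly one OTHER carried by one sample: SNV dropped, cluster kept
  rescue <- dplyr::bind_rows(mk_members(seq(5000, 5500, 100)),
                             mk_members(5250, mclass = "OTHER"))
  # one OTHER variant present in two samples (two records): removed as recurrent
  recurrent <- dplyr::bind_rows(
    mk_members(seq(9000, 9500, 100)),
    mk_members(c(9250, 9250), mclass = "OTHER", sample_id = c("s1", "s2"))
  )
  res <- filter_clusters(list(bad, rescue, recurrent),
                         params = cluster_params(min_power = 0))
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$start, 5000)
  expect_equal(res$clusters$size, 6)          # the OTHER member is gone
  expect_equal(res$clusters$n_other, 0)
  expect_equal(sum(res$removed_snvs$reason == "too_many_nondeaminase"), 8)
  expect_equal(sum(res$removed_snvs$reason == "single_sample_nondeaminase_snv"), 1)
  expect_equal(sum(res$removed_snvs$reason == "recurrent_nondeaminase_snv"), 8)
  # without deaminase mode all three clusters pass composition filtering
  res2 <- filter_clusters(list(bad, rescue, recurrent),
                          params = cluster_params(min_power = 0),
                          deaminase_mode = FALSE)
  expect_equal(nrow(res2$clusters), 3)
})

test_that("size and power thresholds are inclusive and restoration is per sample", {
  boundary <- mk_members(seq(0, 400, 100) + 1, sample_id = c("s1", "s2"))
  small <- mk_members(c(700, 720, 740, 760))           # size 4 < 5
  weak <- mk_members(seq(20000, 28000, by = 2000))     # power 5/2000 < 0.05
  res <- filter_clusters(list(boundary, small, weak))
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$power, 0.05)               # exactly at threshold
  expect_equal(res$clusters$size, 5)
  # restored SNVs include all clusters surviving stages (a)-(b), sorted by sample
  expect_equal(nrow(res$restored), 5 + 4 + 5)
  expect_equal(res$restored$sample_id, sort(res$restored$sample_id))
})

test_that("detect_clusters recovers a planted cluster among sparse background", {
  set.seed(41)
  planted <- sort(sample(5000:5400, 20))
  background <- seq(60000, 60000 + 29 * 50000, by = 50000)
  s <- snv_set("chr1", c(planted, background), "C", "T", "s1")
  # extraction + filtering alone recover the planted cluster exactly: the
  # background singletons can never reach the minimum size
  flat <- detect_clusters(s, refine = FALSE)
  expect_equal(nrow(flat), 1)
  expect_equal(flat$size, 20)
  expect_setequal(flat$members[[1]]$pos, planted)
  expect_equal(flat$majority_class, "CT")
  expect_equal(flat$homogeneity, 1)
  # border refinement may split the planted run into denser fragments, but
  # whatever survives is made of planted SNVs only
  refined <- detect_clusters(s)
  for (m in refined$members) expect_true(all(m$pos %in% planted))
})

test_that("detect_clusters handles all-OTHER and empty inputs", {
  s <- snv_set("chr1", seq(100, 1000, 100), "A", "G", "s1")
  expect_equal(nrow(detect_clusters(s)), 0)
  empty <- snv_set(character(), integer(), character(), character())
  expect_equal(nrow(detect_clusters(empty)), 0)
})

test_that("clusters never span chromosomes and output is sorted", {
  pos <- seq(100, 2000, 100)
  s <- pool_samples(list(
    snv_set("chr2", pos, "C", "T", "s1"),
    snv_set("chr1", pos, "G", "A", "s1")
  ))
  clusters <- detect_clusters(s, params = cluster_params(min_power = 0))
  expect_true(all(vapply(clusters$members,
                         function(m) length(unique(m$chrom)) == 1, logical(1))))
  expect_equal(clusters$chrom, sort(clusters$chrom))
  expect_true(all(startsWith(clusters$cluster_id, paste0("cl_", clusters$chrom))))
})

test_that("filtering is monotone in min_size and min_power", {
  set.seed(42)
  member_list <- lapply(1:25, function(i) {
    n <- sample(3:12, 1)
    start <- i * 10000
    mk_members(start + sort(sample(0:600, n)))
  })
  count <- function(min_size, min_power) {
    nrow(filter_clusters(member_list,
                         params = cluster_params(min_size = min_size,
                                                 min_power = min_power))$clusters)
  }
  for (ms in c(3, 5, 8)) {
    expect_gte(count(ms, 0.01), count(ms, 0.05))
    expect_gte(count(ms, 0.05), count(ms, 0.2))
  }
  for (mp in c(0.01, 0.05)) {
    expect_gte(count(3, mp), count(5, mp))
    expect_gte(count(5, mp), count(8, mp))
  }
})

test_that("threshold sweep counts plateau between block scales and shrink with t", {
  blocks <- c(sort(runif(6, 0, 300)), sort(runif(7, 50000, 50300)),
              sort(runif(5, 120000, 120300)))
  s <- snv_set("chr1", round(blocks), "C", "T", "s1")
  sw <- threshold_sweep(s)
  expect_equal(sw$threshold, seq(50, 5000, by = 50))
  # any threshold between the intra-block and inter-block cophenetic scales
  # finds exactly the three planted blocks
  expect_true(all(sw$n_clusters[sw$threshold >= 400] == 3))
  expect_true(all(diff(sw$n_total) <= 0))
  expect_error(threshold_sweep(s, t_min = 0), "t_min")
  # a threshold below every pairwise distance yields no multi-SNV clusters
  far <- snv_set("chr1", c(1, 1e5, 2e5), "C", "T", "s1")
  expect_equal(threshold_sweep(far, t_min = 50, t_max = 100)$n_clusters,
               c(0L, 0L))
})
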