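pileup_row <- function(sample = "s1", pos = 100L, ref = "A",
                       A = 0L, C = 0L, G = 0L, T = 0L) {
  tibble::tibble(
    sample_id = sample, chrom = "chr1", pos = pos, ref = ref,
    count_A = A, count_C = C, count_G = G, count_T = T
  )
}

test_that("candidate p-values match the exact binomial tail oracle", {
  # 90 ref / 10 alt at error 1%
  cand <- detect_candidates(pileup_row(A = 90L, G = 10L), error_rate = 0.01)
  expect_equal(cand$alt, "G")
  expect_equal(cand$aaf, 0.10)
  p_oracle <- oracle_binom_tail(10, 100, 0.01)
  expect_equal(p_oracle, 7.631588e-08, tolerance = 1e-6) # frozen oracle value
  expect_lt(abs(cand$p_value - p_oracle), 1e-12)

  # 45 ref / 5 alt at n = 50
  cand2 <- detect_candidates(pileup_row(A = 45L, G = 5L), error_rate = 0.01)
  p2 <- oracle_binom_tail(5, 50, 0.01)
  expect_equal(p2, 1.4568927e-4, tolerance = 1e-6) # frozen oracle value
  expect_lt(abs(cand2$p_value - p2), 1e-12)

  # random configurations
  set.seed(1)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    k <- sample.int(n, 1)
    e <- runif(1, 0.001, 0.05)
    cand <- detect_candidates(
      pileup_row(A = n - k, G = k),
      error_rate = e
    )
    expect_lt(abs(cand$p_value - oracle_binom_tail(k, n, e)), 1e-12)
  }
})

test_that("no-mismatch, tied and zero-depth pileups give no candidate", {
  expect_equal(nrow(detect_candidates(pileup_row(A = 100L))), 0)
  expect_message(
    out <- detect_candidates(pileup_row(A = 90L, G = 5L, C = 5L)),
    "tied"
  )
  expect_equal(nrow(out), 0)
  expect_equal(nrow(detect_candidates(pileup_row())), 0)
})

test_that("BH adjustment equals the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("FDR and AAF window thresholds apply as specified", {
  cfg <- edit_config()
  cands <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
    ref_count = 1L, alt_count = 1L,
    aaf = c(0.10, 1.00, 0.10, 0.005),
    p_value = 0.001,
    q_value = c(0.04, 0.01, 0.06, 0.01)
  )
  kept <- filter_fdr_aaf(cands, cfg)
  expect_equal(kept$pos, 1L) # q<=0.05 & aaf in [0.01, 1)
})

test_that("germline subtraction removes matched variants and unverifiable sites", {
  cfg <- edit_config(min_dna_depth = 10)
  cands <- tibble::tibble(
    sample_id = c("s1", "s1", "s1"), chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = "A", alt = "G", ref_count = 50L, alt_count = 10L,
    aaf = 0.2, p_value = 1e-6, q_value = 1e-5
  )
  dna <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = 10L, ref = "A", alt = "G",
    genotype = "het", gq = 40L, dna_depth = 30L
  )
  cov <- tibble::tibble(
    sample_id = "s1", chrom = "chr1", pos = c(10L, 20L, 30L),
    dna_depth = c(30L, 30L, 2L)
  )
  kept <- subtract_genomic(cands, dna, cov, cfg)
  expect_equal(kept$pos, 20L) # 10 is a het variant, 30 lacks DNA depth

  # a matching variant in a different sample does not subtract
  dna_other <- dna |> dplyr::mutate(sample_id = "s2")
  kept2 <- subtract_genomic(cands, dna_other, cov |>
    dplyr::mutate(dna_depth = 30L), cfg)
  expect_equal(kept2$pos, c(10L, 20L, 30L))
})

test_that("known-SNP removal is positional and sample-agnostic", {
  cands <- tibble::tibble(
    sample_id = c("s1", "s2", "s1"), chrom = "chr1", pos = c(10L, 10L, 20L),
    alt = c("G", "T", "G")
  )
  expect_equal(nrow(remove_known_snps(cands, tibble::tibble(
    chrom = character(0), pos = integer(0)
  ))), 3)
  kept <- remove_known_snps(cands, tibble::tibble(chrom = "chr1", pos = 10L))
  expect_equal(kept$pos, 20L) # both samples removed at the cataloged position
})

test_that("known-editing overlap fraction counts distinct sites", {
  cands <- tibble::tibble(
    sample_id = c("s1", "s2", "s1", "s1"), chrom = "chr1",
    pos = c(1L, 1L, 2L, 3L)
  )
  # 3 distinct sites; catalog holds 2 of them -> two thirds
  fl <- flag_known_editing(cands, tibble::tibble(chrom = "chr1", pos = c(1L, 2L)))
  expect_equal(fl$overlap_fraction, 2 / 3)
  expect_equal(fl$cands$known_editing, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(
    flag_known_editing(cands, tibble::tibble(chrom = "chr1", pos = 1:3))$overlap_fraction,
    1
  )
  expect_equal(
    flag_known_editing(cands, tibble::tibble(chrom = "chr2", pos = 1:3))$overlap_fraction,
    0
  )
  empty <- cands[0, ]
  expect_true(is.na(flag_known_editing(empty, tibble::tibble(
    chrom = "chr1", pos = 1L
  ))$overlap_fraction))
})

test_that("the filter cascade is order-invariant and equals brute force", {
  cfg <- edit_config()
  cands <- random_candidates(200, seed = 7)
  dna <- tibble::tibble(
    sample_id = sample(c("s1", "s2", "s3"), 40, replace = TRUE),
    chrom = "chr1", pos = sample(cands$pos, 40), ref = "A", alt = "G",
    genotype = "het", gq = 50L, dna_depth = 30L
  )
  cov <- tidyr::crossing(
    sample_id = c("s1", "s2", "s3"),
    tibble::tibble(pos = unique(cands$pos))
  ) |>
    dplyr::mutate(chrom = "chr1", dna_depth = sample(c(2L, 30L),
      dplyr::n(),
      replace = TRUE, prob = c(0.1, 0.9)
    ))
  snps <- tibble::tibble(chrom = "chr1", pos = sample(cands$pos, 30))

  filters <- list(
    fdr_aaf = function(x) filter_fdr_aaf(x, cfg),
    genomic = function(x) subtract_genomic(x, dna, cov, cfg),
    snps = function(x) remove_known_snps(x, snps)
  )
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  results <- lapply(orders, function(o) {
    out <- cands
    for (i in o) out <- filters[[i]](out)
    out |> dplyr::arrange(sample_id, pos)
  })
  for (r in results[-1]) expect_identical(results[[1]], r)

  # brute force: per-row predicate intersection
  keep_fdr <- cands$q_value <= cfg$fdr_threshold &
    cands$aaf >= cfg$aaf_min & cands$aaf < cfg$aaf_max_exclusive
  dkey <- paste(dna$sample_id, dna$pos)
  ckey <- paste(cands$sample_id, cands$pos)
  covkey <- paste(cov$sample_id, cov$pos)
  keep_dna <- !(ckey %in% dkey) & cov$dna_depth[match(ckey, covkey)] >= 10
  keep_snp <- !(cands$pos %in% snps$pos)
  brute <- cands[keep_fdr & keep_dna & keep_snp, ] |>
    dplyr::arrange(sample_id, pos)
  expect_identical(results[[1]], brute)
})

test_that("the caller recovers implanted sites on a reduced synthetic cohort", {
  p <- small_params()
  d <- simulate_dataset(p, seed = 23)
  cfg <- edit_config()
  dna_var <- d$dna_records |>
    dplyr::filter(gt %in% c("0/1", "1/1"), gq >= cfg$gq_min, !is.na(alt)) |>
    dplyr::mutate(genotype = ifelse(gt == "1/1", "hom_alt", "het")) |>
    dplyr::select(sample_id, chrom, pos, ref, alt, genotype, gq, dna_depth)
  dna_cov <- d$dna_records |> dplyr::select(sample_id, chrom, pos, dna_depth)
  called <- call_editing_sites(
    d$pileups, dna_var, dna_cov,
    d$catalogs$known_snps, d$catalogs$known_edits, cfg
  )
  rec <- caller_recovery(
    called$sites, d$truth, d$samples, d$pileups, d$dna_records
  )
  expect_gt(rec$sensitivity_powered, 0.85)
  expect_lt(rec$empirical_fdr, 0.15)
  expect_equal(rec$n_snp_survivors_gq30, 0L)
})
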