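test_that("the same seed reproduces every simulated artefact byte for byte", {
  p <- small_params()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- simulate_dataset(p, seed = 11, out_dir = d1)
  r2 <- simulate_dataset(p, seed = 11, out_dir = d2)
  for (nm in names(r1$files)) {
    expect_equal(
      unname(tools::md5sum(r1$files[[nm]])),
      unname(tools::md5sum(r2$files[[nm]])),
      label = paste("file", nm)
    )
  }
  r3 <- simulate_dataset(p, seed = 12)
  expect_false(identical(
    as.character(r1$ann$genome), as.character(r3$ann$genome)
  ))
})

test_that("annotation counts and degenerate knobs behave", {
  p <- small_params()
  sim <- simulate_genome_annotation(p, seed = 5)
  expect_equal(sum(sim$models$feature == "gene"), p$n_genes)
  expect_true(all(c("+", "-") %in% sim$models$strand))
  # exon-union lengths positive; CDS nested in exons per gene
  cds_ok <- sim$models |>
    dplyr::filter(feature == "CDS") |>
    dplyr::left_join(
      sim$models |>
        dplyr::filter(feature == "gene") |>
        dplyr::select(gene_id, gs = start, ge = end),
      by = "gene_id"
    )
  expect_true(all(cds_ok$start >= cds_ok$gs & cds_ok$end <= cds_ok$ge))

  no_alu <- simulate_genome_annotation(
    small_params(alu_fraction_of_genome = 0), seed = 5
  )
  expect_false(any(no_alu$repeats$family == "Alu"))

  expect_error(
    simulate_genome_annotation(sim_params(genome_length = 30000L), seed = 1),
    "too short"
  )
})

test_that("implanted truth honours placement fractions and disjointness", {
  p <- small_params(frac_edits_in_alu = 1.0)
  ann <- simulate_genome_annotation(p, seed = 8)
  tr <- implant_truth(p, ann, seed = 8)
  alu <- ann$repeats |> dplyr::filter(family == "Alu")
  in_alu <- editscape:::positions_in_intervals(
    tr$edit_sites$chrom, tr$edit_sites$pos, alu
  )
  expect_true(all(in_alu))

  p2 <- small_params(a2i_fraction = 1.0)
  tr2 <- implant_truth(p2, simulate_genome_annotation(p2, seed = 9), seed = 9)
  expect_true(all(tr2$edit_sites$transcript_change == "A>G"))
  minus <- tr2$edit_sites |> dplyr::filter(strand == "-")
  expect_gt(nrow(minus), 0)
  expect_true(all(minus$g_ref == "T" & minus$g_alt == "C"))

  # edit, SNP and background positions never collide
  keys <- c(
    paste(tr$edit_sites$chrom, tr$edit_sites$pos),
    paste(tr$snps$chrom, tr$snps$pos),
    paste(tr$background$chrom, tr$background$pos)
  )
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(tr$edit_sites$true_level > 0 & tr$edit_sites$true_level < 1))
})

test_that("Alu placement of many implanted sites stays in its binomial CI", {
  p <- sim_params(
    genome_length = 400000L, n_genes = 140L,
    n_edit_sites = 625L, case_extra_sites_factor = 1.6
  )
  ann <- simulate_genome_annotation(p, seed = 21)
  tr <- implant_truth(p, ann, seed = 21)
  n <- nrow(tr$edit_sites)
  expect_equal(n, 1000)
  ci <- binom_ci99(0.8, n)
  expect_gt(mean(tr$edit_sites$in_alu), ci[1])
  expect_lt(mean(tr$edit_sites$in_alu), ci[2])
})

test_that("true editing levels follow the configured Beta distribution", {
  p <- sim_params(edit_level_min = 1e-4, edit_level_max = 1 - 1e-4)
  set.seed(31)
  lv <- draw_edit_levels(1000, p)
  ks <- suppressWarnings(stats::ks.test(lv, "pbeta", 2, 6))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free pileups carry no mismatches without implanted truth", {
  p <- small_params(
    n_edit_sites = 0L, n_snps = 0L, n_coupled_genes = 0L,
    seq_error_rate = 0
  )
  ann <- simulate_genome_annotation(p, seed = 4)
  tr <- implant_truth(p, ann, seed = 4)
  expect_equal(nrow(tr$edit_sites), 0)
  pp <- simulate_pileups(tr, sample_sheet(p), p, ann, seed = 4)
  counts <- as.matrix(pp$pileups[paste0("count_", c("A", "C", "G", "T"))])
  ref_idx <- match(pp$pileups$ref, c("A", "C", "G", "T"))
  ref_counts <- counts[cbind(seq_len(nrow(counts)), ref_idx)]
  expect_equal(rowSums(counts), ref_counts) # every read matches the reference
})

test_that("pileups reflect genotype dosage and editing levels", {
  p <- small_params()
  ann <- simulate_genome_annotation(p, seed = 6)
  tr <- implant_truth(p, ann, seed = 6)
  samples <- sample_sheet(p)
  pp <- simulate_pileups(tr, samples, p, ann, seed = 6)

  # het SNPs: DNA 0/1 and RNA AAF near 0.5 on average
  het <- tr$snps |> dplyr::filter(genotype == "het")
  key <- paste(pp$dna_records$chrom, pp$dna_records$pos)
  dna_het <- pp$dna_records[key %in% paste(het$chrom, het$pos), ]
  expect_true(all(dna_het$gt == "0/1"))
  pk <- paste(pp$pileups$chrom, pp$pileups$pos)
  pl_het <- pp$pileups[pk %in% paste(het$chrom, het$pos), ]
  alt_base <- het$alt[match(paste(pl_het$chrom, pl_het$pos), paste(het$chrom, het$pos))]
  alt_n <- as.matrix(pl_het[paste0("count_", c("A", "C", "G", "T"))])[
    cbind(seq_len(nrow(pl_het)), match(alt_base, c("A", "C", "G", "T")))
  ]
  expect_lt(abs(mean(alt_n / pl_het$depth) - 0.5), 0.02)

  # implanted sites: pooled observed AAF tracks the sample-adjusted level
  st <- draw_sample_truth(samples, tr, p, seed = 6)
  ed <- tr$edit_sites |> dplyr::filter(!group_specific)
  pl_ed <- pp$pileups[pk %in% paste(ed$chrom, ed$pos), ]
  i <- match(paste(pl_ed$chrom, pl_ed$pos), paste(ed$chrom, ed$pos))
  m <- st$m_edit[match(pl_ed$sample_id, st$sample_id)]
  expected <- pmin(ed$true_level[i] * m, 0.98)
  alt_n <- as.matrix(pl_ed[paste0("count_", c("A", "C", "G", "T"))])[
    cbind(seq_len(nrow(pl_ed)), match(ed$g_alt[i], c("A", "C", "G", "T")))
  ]
  obs <- alt_n / pl_ed$depth
  expect_lt(abs(mean(obs - expected)), 0.01)
})

test_that("count matrix is reproducible and respects the null", {
  p <- small_params()
  dt <- make_de_truth(n_genes = 200, n_de = 0, seed = 2)
  samples <- de_sample_sheet(4, 4)
  c1 <- simulate_counts(dt$truth, samples, p, dt$models, seed = 13)
  c2 <- simulate_counts(dt$truth, samples, p, dt$models, seed = 13)
  expect_identical(c1, c2)

  # no implanted effect: after removing library-size factors, group means
  # should not shift systematically
  m <- as.matrix(c1[-1])
  m <- sweep(m, 2, colSums(m) / mean(colSums(m)), "/")
  lfc <- log2((rowMeans(m[, 1:4]) + 0.5) / (rowMeans(m[, 5:8]) + 0.5))
  expect_lt(abs(mean(lfc)), 0.1)
})

test_that("vanishing dispersion approaches the Poisson limit", {
  p <- small_params(nb_dispersion = 1e-9)
  dt <- make_de_truth(n_genes = 150, n_de = 0, seed = 3)
  samples <- de_sample_sheet(20, 20)
  cnt <- simulate_counts(dt$truth, samples, p, dt$models, seed = 14)
  m <- as.matrix(cnt[-1])
  # remove per-sample library factors before computing moments
  m <- sweep(m, 2, colMeans(m) / mean(colMeans(m)), "/")
  ratio <- apply(m, 1, var) / rowMeans(m)
  # Poisson limit: variance over mean concentrates near 1
  expect_lt(abs(median(ratio) - 1), 0.25)
})

test_that("every emitted file parses through the package readers cleanly", {
  d <- withr::local_tempdir()
  r <- simulate_dataset(small_params(), seed = 17, out_dir = d)
  f <- r$files
  expect_no_warning({
    read_gene_models(f$gtf, essential_list = f$essential)
    read_repeats(f$repeats)
    read_site_pileups(f$pileups)
    read_dna_genotypes(f$dna_vcf)
    read_dna_coverage(f$dna_vcf)
    read_site_catalog(f$known_snps)
    read_site_catalog(f$known_edits)
    read_sample_sheet(f$samples)
    read_count_matrix(f$counts)
  })
})

test_that("case samples carry the configured excess of implanted sites", {
  p <- small_params()
  tr <- implant_truth(p, simulate_genome_annotation(p, seed = 19), seed = 19)
  st <- draw_sample_truth(sample_sheet(p), tr, p, seed = 19)
  ratio <- mean(st$n_implanted[st$group == "case"]) /
    mean(st$n_implanted[st$group == "control"])
  expect_equal(ratio, p$case_extra_sites_factor, tolerance = 0.02)
})
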