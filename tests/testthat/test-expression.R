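test_that("FPKM follows its defining formula and scaling invariance", {
  counts <- tibble::tibble(
    gene_id = c("g1", "g2"),
    s1 = c(100L, 999900L)
  )
  lengths <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(1000L, 500L))
  f <- compute_fpkm(counts, lengths)
  expect_equal(f$s1[1], 100) # 100 / (1 kb * 1e6/1e6)

  counts2 <- tibble::tibble(
    gene_id = c("g1", "g2"), s1 = c(250L, 1999750L)
  )
  lengths2 <- tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(2500L, 100L))
  expect_equal(compute_fpkm(counts2, lengths2)$s1[1], 50) # 250/(2.5 * 2)

  expect_equal(compute_fpkm(
    tibble::tibble(gene_id = c("g1", "g2"), s1 = c(0L, 50L)),
    tibble::tibble(gene_id = c("g1", "g2"), length_bp = c(700L, 900L))
  )$s1[1], 0)

  # uniform scaling of one sample's counts leaves its FPKM unchanged
  set.seed(3)
  cnt <- tibble::tibble(
    gene_id = paste0("g", 1:50),
    s1 = rpois(50, 200), s2 = rpois(50, 300)
  )
  len <- tibble::tibble(gene_id = cnt$gene_id, length_bp = sample(500:3000, 50))
  f1 <- compute_fpkm(cnt, len)
  f2 <- compute_fpkm(cnt |> dplyr::mutate(s2 = s2 * 7L), len)
  expect_equal(f1$s2, f2$s2, tolerance = 1e-12)

  expect_error(
    compute_fpkm(
      tibble::tibble(gene_id = "g1", s1 = 0L),
      tibble::tibble(gene_id = "g1", length_bp = 100L)
    ),
    "zero library"
  )
})

test_that("size factors equal the hand median-of-ratios computation", {
  cnt <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    s1 = c(10L, 20L, 30L, 40L), s2 = c(10L, 20L, 30L, 40L)
  )
  expect_equal(unname(size_factors(cnt)), c(1, 1))

  cnt2 <- cnt |> dplyr::mutate(s2 = s1 * 2L)
  sf <- size_factors(cnt2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  toy <- tibble::tibble(
    gene_id = c("a", "b", "c"), s1 = c(4L, 9L, 25L), s2 = c(1L, 1L, 1L)
  )
  ref <- exp(rowMeans(log(cbind(c(4, 9, 25), c(1, 1, 1)))))
  want <- c(
    median(c(4, 9, 25) / ref),
    median(c(1, 1, 1) / ref)
  )
  expect_equal(unname(size_factors(toy)), want)

  all_zero_somewhere <- tibble::tibble(
    gene_id = c("a", "b"), s1 = c(0L, 3L), s2 = c(5L, 0L)
  )
  expect_error(size_factors(all_zero_somewhere), "pseudocount")
})

test_that("NB Wald fold changes and null behaviour are sane", {
  # 60 stable genes plus one quadrupled gene: lfc close to 2
  set.seed(11)
  base <- rpois(60, 400)
  cnt <- tibble::tibble(gene_id = paste0("g", 1:61)) |>
    dplyr::bind_cols(purrr::map_dfc(1:6, function(i) {
      v <- c(base + rpois(60, 5), if (i <= 3) 1600L else 400L)
      tibble::tibble(!!paste0("s", i) := as.integer(v))
    }))
  samples <- de_sample_sheet(3, 3) |>
    dplyr::mutate(sample_id = paste0("s", 1:6))
  de <- nb_wald_de(cnt, samples, c("group", "case", "control"))
  expect_equal(de$log2fc[de$gene_id == "g61"], 2, tolerance = 0.1)
  expect_lt(max(abs(de$log2fc[de$gene_id != "g61"])), 0.5)

  # global null: BH keeps the significant fraction near zero
  p <- small_params()
  dt <- make_de_truth(n_genes = 400, n_de = 0, seed = 5)
  cnull <- simulate_counts(dt$truth, de_sample_sheet(5, 5), p, dt$models, seed = 6)
  den <- nb_wald_de(cnull, de_sample_sheet(5, 5), c("group", "case", "control"))
  frac_padj <- mean(den$padj <= 0.05)
  expect_lte(frac_padj, 0.05 + 2 * sqrt(0.05 * 0.95 / nrow(den)))
  expect_equal(sum(den$significant), 0)
})

test_that("implanted fold changes are recovered with controlled FDR", {
  p <- small_params()
  dt <- make_de_truth(n_genes = 400, n_de = 20, log2fc = 2, seed = 7)
  cnt <- simulate_counts(dt$truth, de_sample_sheet(5, 5), p, dt$models, seed = 8)
  de <- nb_wald_de(cnt, de_sample_sheet(5, 5), c("group", "case", "control"))
  rec <- de_recovery(de, dt$truth)
  expect_gte(rec$sensitivity, 0.8)
  expect_lte(rec$empirical_fdr, 0.1)
  expect_gte(rec$sign_recovery, 0.95)
})

test_that("NB Wald direction agrees with DESeq2 on a shared matrix", {
  skip_if_not_installed("DESeq2")
  p <- small_params()
  dt <- make_de_truth(n_genes = 150, n_de = 15, log2fc = 2, seed = 9)
  samples <- de_sample_sheet(4, 4)
  cnt <- simulate_counts(dt$truth, samples, p, dt$models, seed = 10)
  de <- nb_wald_de(cnt, samples, c("group", "case", "control"))

  m <- as.matrix(cnt[-1])
  rownames(m) <- cnt$gene_id
  cd <- S4Vectors::DataFrame(group = factor(samples$group,
    levels = c("control", "case")
  ))
  dds <- DESeq2::DESeqDataSetFromMatrix(m, cd, ~group)
  res <- suppressMessages(DESeq2::results(DESeq2::DESeq(dds, quiet = TRUE)))
  shared <- intersect(de$gene_id, rownames(res))
  a <- de$log2fc[match(shared, de$gene_id)]
  b <- res$log2FoldChange[match(shared, rownames(res))]
  expect_gt(cor(a, b, use = "complete.obs"), 0.9)
  true_ids <- dt$truth$de_genes$gene_id
  expect_equal(
    sign(a[shared %in% true_ids]),
    sign(b[shared %in% true_ids])
  )
})

test_that("PLS-DA separates shifted groups and not permuted labels", {
  set.seed(21)
  n_feat <- 100
  samples <- de_sample_sheet(8, 8)
  shift <- c(rep(2, n_feat / 2), rep(0, n_feat / 2))
  x <- sapply(seq_len(16), function(i) {
    rnorm(n_feat, mean = if (i <= 8) shift else 0, sd = 1)
  })
  fpkm <- tibble::tibble(gene_id = paste0("g", 1:n_feat)) |>
    dplyr::bind_cols(as.data.frame(2^x) |> stats::setNames(samples$sample_id))
  fit <- pls_da(fpkm, samples)
  sc <- fit$scores
  case_rng <- range(sc$comp1[sc$class == "case"])
  ctrl_rng <- range(sc$comp1[sc$class == "control"])
  expect_true(case_rng[2] < ctrl_rng[1] || ctrl_rng[2] < case_rng[1])

  sep_stat <- function(scores) {
    s <- split(scores$comp1, scores$class)
    abs(mean(s[[1]]) - mean(s[[2]])) / sd(scores$comp1)
  }
  obs <- sep_stat(sc)
  perm_stats <- vapply(1:20, function(i) {
    ss <- samples
    ss$group <- sample(ss$group)
    sep_stat(pls_da(fpkm, ss)$scores)
  }, numeric(1))
  expect_gt(obs, max(perm_stats))
})

test_that("PLS-DA degenerate inputs error or truncate", {
  samples <- de_sample_sheet(2, 2)
  const <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    s1 = 1, s2 = 1, s3 = 1, s4 = 1
  ) |> stats::setNames(c("gene_id", samples$sample_id))
  expect_error(pls_da(const, samples), "constant")

  set.seed(31)
  small <- tibble::tibble(gene_id = paste0("g", 1:10)) |>
    dplyr::bind_cols(as.data.frame(matrix(rexp(40), 10, 4)) |>
      stats::setNames(samples$sample_id))
  expect_message(fit <- pls_da(small, samples, n_components = 10), "truncated")
  expect_lte(fit$n_components, 3)
})

test_that("tidy, glance and autoplot methods work on fitted objects", {
  p <- small_params()
  dt <- make_de_truth(n_genes = 80, n_de = 8, seed = 13)
  samples <- de_sample_sheet(3, 3)
  cnt <- simulate_counts(dt$truth, samples, p, dt$models, seed = 13)
  de <- nb_wald_de(cnt, samples, c("group", "case", "control"))
  td <- generics::tidy(de)
  expect_s3_class(td, "tbl_df")
  expect_false(is.unsorted(td$padj, na.rm = TRUE))
  gl <- generics::glance(de)
  expect_equal(gl$n_genes, nrow(de))
  expect_s3_class(ggplot2::autoplot(de), "ggplot")

  fpkm <- compute_fpkm(cnt, gene_lengths(dt$models))
  fit <- pls_da(fpkm, samples)
  expect_s3_class(generics::tidy(fit), "tbl_df")
  expect_equal(generics::glance(fit)$n_components, 2)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
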