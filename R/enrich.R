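#' Hypergeometric over-representation of gene sets
#'
#' For each term, with `N` universe genes, `K` term members, `n` query
#' genes and `k` hits, the p-value is the hypergeometric upper tail
#' `P(X >= k)`; BH adjustment runs across all tested terms. Query genes
#' outside the universe are dropped with a warning.
#'
#' @param query_genes character vector of genes of interest.
#' @param catalog long-form tibble: `term_id`, `term_name`, `gene_id`.
#' @param universe character vector of all annotated genes (default: all
#'   genes in the catalog).
#' @param cfg an [edit_config()] object (supplies `enrich_padj_max`).
#' @return tibble: `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`,
#'   `padj`, `enriched`; empty query gives an empty result.
#' @export
hypergeom_enrich <- function(query_genes, catalog,
                             universe = unique(catalog$gene_id),
                             cfg = edit_config()) {
  assert_columns(catalog, c("term_id", "gene_id"), "gene-set catalog")
  if (!"term_name" %in% names(catalog)) catalog$term_name <- catalog$term_id
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped", length(outside)))
    query_genes <- intersect(query_genes, universe)
  }
  if (length(query_genes) == 0) {
    return(tibble(
      term_id = character(0), term_name = character(0),
      k = integer(0), K = integer(0), n = integer(0), N = integer(0),
      p = numeric(0), padj = numeric(0), enriched = logical(0)
    ))
  }
  catalog <- catalog |> filter(.data$gene_id %in% universe)
  N <- length(universe)
  n <- length(query_genes)
  res <- catalog |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(
      K = n_distinct(.data$gene_id),
      k = n_distinct(intersect(.data$gene_id, query_genes)),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE)
    )
  res$padj <- bh_adjust(res$p)
  res$enriched <- res$padj < cfg$enrich_padj_max
  res |> arrange(.data$p, .data$term_id)
}

#' Condition-specific edited-gene sets
#'
#' Builds the distinct edited-gene set of every group x tissue condition
#' (a gene counts as edited in a condition when it carries a called site in
#' at least one of its samples), then all pairwise set differences and
#' intersections, in deterministic order.
#'
#' @param sites called/annotated site tibble with `gene_id`.
#' @param samples sample sheet tibble.
#' @return list with `condition_sets` (condition, gene_id),
#'   `pairwise` (set_a, set_b, n_a, n_b, n_intersection, n_only_a,
#'   n_only_b) and `specific_genes` (comparison, gene_id: genes edited in
#'   set_a but not set_b).
#' @export
specific_edited_sets <- function(sites, samples) {
  validate_sample_sheet(samples)
  cond <- sites |>
    filter(!is.na(.data$gene_id)) |>
    left_join(samples |> select("sample_id", "group", "tissue"),
      by = "sample_id"
    ) |>
    mutate(condition = paste(.data$group, .data$tissue, sep = "_")) |>
    distinct(.data$condition, .data$gene_id) |>
    arrange(.data$condition, .data$gene_id)
  conds <- sort(unique(paste(samples$group, samples$tissue, sep = "_")))
  sets <- lapply(conds, function(cn) cond$gene_id[cond$condition == cn])
  names(sets) <- conds
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(pr) {
    a <- sets[[pr[1]]]
    b <- sets[[pr[2]]]
    tibble(
      set_a = pr[1], set_b = pr[2],
      n_a = length(a), n_b = length(b),
      n_intersection = length(intersect(a, b)),
      n_only_a = length(setdiff(a, b)),
      n_only_b = length(setdiff(b, a))
    )
  }) |> bind_rows()
  specific <- purrr::map(pairs, function(pr) {
    bind_rows(
      tibble(
        comparison = paste0(pr[1], "_not_", pr[2]),
        gene_id = sort(setdiff(sets[[pr[1]]], sets[[pr[2]]]))
      ),
      tibble(
        comparison = paste0(pr[2], "_not_", pr[1]),
        gene_id = sort(setdiff(sets[[pr[2]]], sets[[pr[1]]]))
      )
    )
  }) |> bind_rows()
  list(condition_sets = cond, pairwise = pairwise, specific_genes = specific)
}

perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) {
    return(perm_cache[[key]])
  }
  pm <- if (n == 1) {
    matrix(1L, 1, 1)
  } else {
    prev <- all_permutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(rep(i, nrow(prev)), matrix(rest[prev], nrow(prev)))
    }))
  }
  perm_cache[[key]] <- pm
  pm
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Rho is the Pearson correlation of mid-ranks (tie-corrected). The
#' two-sided p-value comes from full enumeration of rank permutations for
#' small samples (`n <= exact_max`) and from the t approximation
#' `t = r sqrt((n-2)/(1-r^2))` otherwise. NA pairs are dropped pairwise;
#' zero variance in either vector yields `r = NA`.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_max largest n for exact permutation enumeration.
#' @return one-row tibble: `r`, `p`, `n_pairs`, `method`.
#' @export
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
spearman_cor <- function(x, y, exact_max = 9L) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) {
    return(tibble(r = NA_real_, p = NA_real_, n_pairs = n, method = "none"))
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    inform("zero variance: Spearman correlation undefined")
    return(tibble(r = NA_real_, p = NA_real_, n_pairs = n, method = "degenerate"))
  }
  r <- cor(rx, ry)
  if (n <= exact_max) {
    pm <- all_permutations(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    stats <- matrix(ryc[pm], nrow = nrow(pm)) %*% rxc / denom
    p <- mean(abs(stats) >= abs(r) - 1e-12)
    return(tibble(r = r, p = p, n_pairs = n, method = "exact_permutation"))
  }
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  tibble(r = r, p = min(p, 1), n_pairs = n, method = "t_approximation")
}

#' Correlation of ADAR-like expression with editing-site counts
#'
#' Spearman correlation, across samples, of summed ADAR-family FPKM
#' against the number of called editing sites.
#'
#' @param fpkm FPKM tibble.
#' @param sites called site tibble.
#' @param adar_gene_ids character vector of ADAR-family gene ids.
#' @param samples sample sheet tibble.
#' @return one-row tibble: `label`, `r`, `p`, `n_pairs`, `method`.
#' @export
adar_site_correlation <- function(fpkm, sites, adar_gene_ids, samples) {
  validate_sample_sheet(samples)
  if (nrow(samples) < 3) {
    return(tibble(
      label = "ADAR_vs_site_count", r = NA_real_, p = NA_real_,
      n_pairs = nrow(samples), method = "none"
    ))
  }
  m <- counts_to_matrix(fpkm)
  adar_expr <- colSums(m[intersect(adar_gene_ids, rownames(m)), , drop = FALSE])
  n_sites <- sites |>
    count(.data$sample_id, name = "n_sites")
  tb <- samples |>
    select("sample_id") |>
    mutate(
      adar_fpkm = adar_expr[match(.data$sample_id, names(adar_expr))],
      n_sites = n_sites$n_sites[match(.data$sample_id, n_sites$sample_id)]
    ) |>
    mutate(n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites))
  res <- spearman_cor(tb$adar_fpkm, tb$n_sites)
  bind_cols(tibble(label = "ADAR_vs_site_count"), res)
}

#' Per-gene correlation of editing level with expression
#'
#' For each gene, the per-sample editing level is the mean (or maximum)
#' level over that gene's called sites in the sample; samples without any
#' called site in the gene are uninformative and dropped pairwise. Genes
#' with at least `min_samples` informative samples are tested by Spearman
#' correlation against their FPKM, with BH adjustment across genes
#' alongside the raw p-values.
#'
#' @param sites called/annotated site tibble (`gene_id`, `editing_level`).
#' @param fpkm FPKM tibble.
#' @param samples sample sheet tibble.
#' @param min_samples minimum informative samples per gene (default 3).
#' @param aggregate `"mean"` (default) or `"max"` site-level aggregation.
#' @return tibble: `gene_id`, `r`, `p`, `padj`, `n_pairs`, `method`.
#' @export
editing_expression_correlation <- function(sites, fpkm, samples,
                                           min_samples = 3L,
                                           aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  agg_fun <- if (aggregate == "mean") mean else max
  m <- counts_to_matrix(fpkm)
  lvl <- sites |>
    filter(!is.na(.data$gene_id)) |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(level = agg_fun(.data$editing_level), .groups = "drop")
  genes <- lvl |>
    count(.data$gene_id) |>
    filter(.data$n >= min_samples) |>
    pull("gene_id")
  genes <- intersect(genes, rownames(m))
  res <- purrr::map(sort(genes), function(g) {
    gl <- lvl |> filter(.data$gene_id == g)
    expr <- m[g, match(gl$sample_id, colnames(m))]
    bind_cols(tibble(gene_id = g), spearman_cor(gl$level, expr))
  }) |> bind_rows()
  if (nrow(res) == 0) {
    return(tibble(
      gene_id = character(0), r = numeric(0), p = numeric(0),
      padj = numeric(0), n_pairs = integer(0), method = character(0)
    ))
  }
  res$padj <- bh_adjust(res$p)
  res |> select("gene_id", "r", "p", "padj", "n_pairs", "method")
}
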