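#' Per-group summaries of annotated editing sites
#'
#' Computes per-sample site counts and distinct edited-gene counts, then
#' averages within each group x tissue condition, alongside pooled type,
#' chromosome, region and repeat-class count tables.
#'
#' @param sites annotated site tibble.
#' @param samples sample sheet tibble.
#' @return list of tibbles: `per_sample`, `group_summary`,
#'   `per_type_counts`, `per_chrom_counts`, `region_counts`, `alu_counts`.
#' @export
summarize_groups <- function(sites, samples) {
  validate_sample_sheet(samples)
  if (nrow(samples) == 0) {
    abort("every group x tissue condition needs at least one sample")
  }
  per_sample <- samples |>
    left_join(
      sites |>
        group_by(.data$sample_id) |>
        summarise(
          n_sites = n(),
          n_edited_genes = n_distinct(.data$gene_id[!is.na(.data$gene_id)]),
          .groups = "drop"
        ),
      by = "sample_id"
    ) |>
    mutate(
      n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites),
      n_edited_genes = ifelse(is.na(.data$n_edited_genes), 0L, .data$n_edited_genes)
    )
  group_summary <- per_sample |>
    group_by(.data$group, .data$tissue) |>
    summarise(
      n_samples = n(),
      n_sites_mean = mean(.data$n_sites),
      n_edited_genes_mean = mean(.data$n_edited_genes),
      .groups = "drop"
    )
  by_cond <- sites |>
    left_join(samples |> select("sample_id", "group", "tissue"), by = "sample_id")
  per_type_counts <- by_cond |>
    count(.data$group, .data$tissue, .data$transcript_change, .data$edit_class,
      name = "n_sites"
    )
  per_chrom_counts <- by_cond |>
    count(.data$group, .data$tissue, .data$chrom, name = "n_sites")
  region_counts <- by_cond |>
    count(.data$group, .data$tissue, .data$region, name = "n_sites")
  alu_counts <- by_cond |>
    count(.data$group, .data$tissue, .data$repeat_class, name = "n_sites")
  list(
    per_sample = per_sample,
    group_summary = group_summary,
    per_type_counts = per_type_counts,
    per_chrom_counts = per_chrom_counts,
    region_counts = region_counts,
    alu_counts = alu_counts
  )
}

#' Rank-based comparison of per-sample quantities between groups
#'
#' Two groups give a two-sided Wilcoxon rank-sum (Mann-Whitney) test, exact
#' for small tie-free samples, normal approximation with tie correction
#' otherwise; three or more groups dispatch to Kruskal-Wallis. Identical
#' group value multisets are degenerate and return p = 1.
#'
#' @param values numeric vector of per-sample values.
#' @param groups group label per value (2 or more levels).
#' @return one-row tibble: `statistic_name`, `statistic`, `p_value`,
#'   `n_per_group`, `degenerate`.
#' @export
compare_counts <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  split_v <- split(values, factor(groups, levels = lev))
  sizes <- paste(vapply(split_v, length, integer(1)), collapse = ",")
  if (length(lev) < 2) abort("need at least 2 groups")
  if (length(lev) == 2) {
    a <- split_v[[1]]
    b <- split_v[[2]]
    if (length(a) < 2 || length(b) < 2) abort("need >= 2 samples per group")
    if (identical(sort(a), sort(b))) {
      return(tibble(
        statistic_name = "wilcoxon", statistic = NA_real_, p_value = 1,
        n_per_group = sizes, degenerate = TRUE
      ))
    }
    wt <- suppressWarnings(wilcox.test(a, b, exact = (length(a) + length(b)) <= 10))
    return(tibble(
      statistic_name = "wilcoxon", statistic = unname(wt$statistic),
      p_value = wt$p.value, n_per_group = sizes, degenerate = FALSE
    ))
  }
  kt <- kruskal.test(values, factor(groups))
  tibble(
    statistic_name = "kruskal_wallis", statistic = unname(kt$statistic),
    p_value = kt$p.value, n_per_group = sizes, degenerate = FALSE
  )
}

#' Compare two proportions from a 2x2 count table
#'
#' Pearson chi-squared without continuity correction (df = 1); when any
#' expected cell falls below 5 the test switches to Fisher's exact test
#' (reported via the statistic name).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return one-row tibble: `statistic_name`, `statistic`, `p_value`.
#' @export
compare_proportions <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("2x2 table has a zero margin")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    ft <- fisher.test(table)
    return(tibble(
      statistic_name = "fisher_f", statistic = unname(ft$estimate),
      p_value = ft$p.value
    ))
  }
  ct <- chisq.test(table, correct = FALSE)
  tibble(
    statistic_name = "chi2", statistic = unname(ct$statistic),
    p_value = ct$p.value
  )
}

#' Synonymous versus nonsynonymous editing per sample
#'
#' Counts synonymous and nonsynonymous edited CDS sites per sample
#' (stop-loss/stop-gain count as nonsynonymous) and tests, within each
#' group x tissue condition, whether nonsynonymous editing exceeds
#' synonymous editing by a one-sided paired Wilcoxon signed-rank test
#' across samples.
#'
#' @param sites annotated site tibble (needs `coding_effect`).
#' @param samples sample sheet tibble.
#' @return list with `per_sample` counts and `tests` (one row per
#'   condition; NA p-value when no CDS sites).
#' @export
syn_nonsyn_analysis <- function(sites, samples) {
  validate_sample_sheet(samples)
  cds <- sites |>
    filter(.data$coding_effect %in%
      c("synonymous", "nonsynonymous", "stop_loss", "stop_gain"))
  per_sample <- samples |>
    left_join(
      cds |>
        group_by(.data$sample_id) |>
        summarise(
          n_syn = sum(.data$coding_effect == "synonymous"),
          n_nonsyn = sum(.data$coding_effect != "synonymous"),
          .groups = "drop"
        ),
      by = "sample_id"
    ) |>
    mutate(across(c("n_syn", "n_nonsyn"), ~ ifelse(is.na(.x), 0L, .x)))
  tests <- per_sample |>
    group_by(.data$group, .data$tissue) |>
    summarise(
      n_samples = n(),
      p_value = if (sum(.data$n_syn + .data$n_nonsyn) == 0) {
        NA_real_
      } else {
        suppressWarnings(wilcox.test(.data$n_nonsyn, .data$n_syn,
          paired = TRUE, alternative = "greater",
          exact = n() <= 20
        )$p.value)
      },
      .groups = "drop"
    )
  list(per_sample = per_sample, tests = tests)
}

#' Edited-gene counts and editing levels by gene essentiality
#'
#' Counts distinct edited essential and nonessential genes, tests the
#' edited-gene essentiality proportion against the background gene-set
#' proportion (chi-squared / Fisher on the 2x2 of edited vs not-edited by
#' essential vs not), and compares per-gene mean editing levels between
#' essential and nonessential nonsynonymously edited genes by rank-sum.
#'
#' @param sites annotated site tibble.
#' @param models gene-model tibble with `essential` flags.
#' @return list with `counts` (one row), `proportion_test`, `level_test`.
#' @export
ess_noness_analysis <- function(sites, models) {
  genes <- models |>
    filter(.data$feature == "gene") |>
    distinct(.data$gene_id, .data$essential)
  edited <- sites |>
    filter(!is.na(.data$gene_id)) |>
    distinct(.data$gene_id) |>
    left_join(genes, by = "gene_id")
  counts <- tibble(
    n_ess_edited = sum(edited$essential, na.rm = TRUE),
    n_noness_edited = sum(!edited$essential, na.rm = TRUE),
    n_ess_background = sum(genes$essential),
    n_noness_background = sum(!genes$essential)
  )
  if (counts$n_ess_background == 0 || nrow(edited) == 0) {
    return(list(counts = counts, proportion_test = NULL, level_test = NULL))
  }
  tab <- matrix(
    c(
      counts$n_ess_edited, counts$n_noness_edited,
      counts$n_ess_background - counts$n_ess_edited,
      counts$n_noness_background - counts$n_noness_edited
    ),
    nrow = 2, byrow = TRUE
  )
  prop_test <- if (any(tab < 0) || any(rowSums(tab) == 0) ||
    any(colSums(tab) == 0)) {
    NULL
  } else {
    compare_proportions(tab)
  }

  ns_genes <- sites |>
    filter(
      .data$coding_effect %in% c("nonsynonymous", "stop_loss", "stop_gain"),
      !is.na(.data$gene_id)
    ) |>
    group_by(.data$gene_id) |>
    summarise(mean_level = mean(.data$editing_level), .groups = "drop") |>
    left_join(genes, by = "gene_id")
  level_test <- NULL
  if (sum(ns_genes$essential) >= 2 && sum(!ns_genes$essential) >= 2) {
    level_test <- compare_counts(
      ns_genes$mean_level,
      ifelse(ns_genes$essential, "essential", "nonessential")
    )
  }
  list(counts = counts, proportion_test = prop_test, level_test = level_test)
}

#' Alu / non-Alu repeat fractions of called sites
#'
#' @param sites annotated site tibble (needs `repeat_class`).
#' @param samples sample sheet tibble.
#' @return list with `per_sample` and `per_condition` fraction tibbles
#'   (NA fractions for samples without sites).
#' @export
alu_proportion <- function(sites, samples) {
  validate_sample_sheet(samples)
  frac <- function(df) {
    tibble(
      n_sites = nrow(df),
      frac_alu = ifelse(nrow(df) == 0, NA_real_,
        mean(df$repeat_class == "Alu")
      ),
      frac_non_alu_repeat = ifelse(nrow(df) == 0, NA_real_,
        mean(df$repeat_class == "repetitive_non_Alu")
      ),
      frac_nonrepetitive = ifelse(nrow(df) == 0, NA_real_,
        mean(df$repeat_class == "nonrepetitive")
      )
    )
  }
  per_sample <- samples |>
    select("sample_id", "group", "tissue") |>
    rowwise() |>
    mutate(frac(sites[sites$sample_id == .data$sample_id, ])) |>
    ungroup()
  per_condition <- sites |>
    left_join(samples |> select("sample_id", "group", "tissue"),
      by = "sample_id"
    ) |>
    group_by(.data$group, .data$tissue) |>
    summarise(
      n_sites = n(),
      frac_alu = mean(.data$repeat_class == "Alu"),
      frac_non_alu_repeat = mean(.data$repeat_class == "repetitive_non_Alu"),
      frac_nonrepetitive = mean(.data$repeat_class == "nonrepetitive"),
      .groups = "drop"
    )
  list(per_sample = per_sample, per_condition = per_condition)
}
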