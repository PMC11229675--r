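#' Detect candidate editing sites from pileups
#'
#' For every pileup record with at least one mismatching read, the
#' alternative base is the non-reference base with the highest count (ties
#' give no candidate and are reported); the p-value is the upper tail of
#' `Binomial(alt_count; n = ref_count + alt_count, p = error_rate)`, i.e.
#' the probability of seeing at least this many mismatching reads from
#' sequencing error alone.
#'
#' @param pileups pileup tibble from [read_site_pileups()] or
#'   [simulate_pileups()].
#' @param error_rate assumed per-base error rate in (0, 1).
#' @param min_depth minimum site depth; shallower sites are skipped.
#' @return candidate tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `aaf`, `p_value`.
#' @export
#' @examples
#' p <- tibble::tibble(
#'   sample_id = "s1", chrom = "chr1", pos = 100L, ref = "A",
#'   count_A = 90L, count_C = 0L, count_G = 10L, count_T = 0L
#' )
#' detect_candidates(p, error_rate = 0.01)
detect_candidates <- function(pileups, error_rate = 0.01, min_depth = 0L) {
  assert_fraction(error_rate, "error_rate")
  if (error_rate <= 0 || error_rate >= 1) {
    abort("error_rate must be strictly inside (0, 1)")
  }
  assert_columns(
    pileups,
    c("sample_id", "chrom", "pos", "ref", paste0("count_", BASES)),
    "pileups"
  )
  counts <- as.matrix(pileups[paste0("count_", BASES)])
  colnames(counts) <- BASES
  depth <- rowSums(counts)
  ref_idx <- match(pileups$ref, BASES)
  ref_count <- counts[cbind(seq_len(nrow(counts)), ref_idx)]
  alt_counts <- counts
  alt_counts[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  alt_max <- apply(alt_counts, 1, max)
  n_max <- rowSums(alt_counts == alt_max)
  tied <- alt_max >= 1 & n_max > 1
  if (any(tied)) {
    inform(sprintf(
      "%d site(s) with tied alternative bases: no candidate emitted",
      sum(tied)
    ))
  }
  keep <- depth >= min_depth & depth > 0 & alt_max >= 1 & !tied
  if (!any(keep)) {
    return(tibble(
      sample_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), ref_count = integer(0),
      alt_count = integer(0), aaf = numeric(0), p_value = numeric(0)
    ))
  }
  alt_base <- BASES[apply(alt_counts[keep, , drop = FALSE], 1, which.max)]
  rc <- as.integer(ref_count[keep])
  ac <- as.integer(alt_max[keep])
  n <- rc + ac
  tibble(
    sample_id = pileups$sample_id[keep],
    chrom = pileups$chrom[keep],
    pos = pileups$pos[keep],
    ref = pileups$ref[keep],
    alt = alt_base,
    ref_count = rc,
    alt_count = ac,
    aaf = ac / n,
    p_value = pbinom(ac - 1, size = n, prob = error_rate, lower.tail = FALSE)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment, order-preserving with the input:
#' `q_i = min over ranks j >= rank(i) of p_(j) * m / j`, capped at 1.
#'
#' @param p_values numeric vector of p-values in \\[0, 1\\].
#' @return adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Attach BH-adjusted q-values to candidates
#'
#' By default adjustment is performed within each sample's candidate list
#' (each sample is its own multiple-testing family); `scope = "pooled"`
#' adjusts across the whole cohort instead.
#'
#' @param cands candidate tibble from [detect_candidates()].
#' @param scope `"per_sample"` or `"pooled"`.
#' @return `cands` with a `q_value` column.
#' @export
add_fdr <- function(cands, scope = c("per_sample", "pooled")) {
  scope <- match.arg(scope)
  if (scope == "pooled") {
    cands$q_value <- bh_adjust(cands$p_value)
    return(cands)
  }
  cands |>
    group_by(.data$sample_id) |>
    mutate(q_value = bh_adjust(.data$p_value)) |>
    ungroup()
}

#' Filter candidates by FDR and allele-frequency window
#'
#' Retains candidates with `q_value <= fdr_threshold` and
#' `aaf_min <= aaf < aaf_max_exclusive`. Fully alternative sites (AAF = 1)
#' are genomic signals, not editing, and are excluded by the default window.
#'
#' @param cands candidate tibble with `q_value` populated (see [add_fdr()]).
#' @param cfg an [edit_config()] object.
#' @return filtered candidate tibble.
#' @export
filter_fdr_aaf <- function(cands, cfg = edit_config()) {
  assert_columns(cands, c("q_value", "aaf"), "candidates")
  cands |>
    filter(
      .data$q_value <= cfg$fdr_threshold,
      .data$aaf >= cfg$aaf_min,
      .data$aaf < cfg$aaf_max_exclusive
    )
}

#' Subtract germline variation using matched DNA genotypes
#'
#' A candidate is removed when the same sample carries a passing DNA variant
#' with the same alternative allele at that position (the mismatch is
#' genomic, not an editing event), and also when that sample's DNA depth at
#' the position is missing or below `min_dna_depth` — without hom-ref DNA
#' evidence the candidate is unverifiable and is dropped conservatively.
#'
#' @param cands candidate tibble.
#' @param dna variant genotypes from [read_dna_genotypes()] (already GQ-
#'   filtered).
#' @param dna_coverage per-sample DNA depths from [read_dna_coverage()];
#'   `NULL` skips the coverage requirement.
#' @param cfg an [edit_config()] object.
#' @return filtered candidate tibble.
#' @export
subtract_genomic <- function(cands, dna, dna_coverage = NULL,
                             cfg = edit_config()) {
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$alt, sep = "\r")
  drop_var <- key(cands) %in% key(dna)
  drop_cov <- rep(FALSE, nrow(cands))
  if (!is.null(dna_coverage)) {
    ck <- paste(cands$sample_id, cands$chrom, cands$pos, sep = "\r")
    vk <- paste(dna_coverage$sample_id, dna_coverage$chrom, dna_coverage$pos,
      sep = "\r"
    )
    depth <- dna_coverage$dna_depth[match(ck, vk)]
    drop_cov <- is.na(depth) | depth < cfg$min_dna_depth
  }
  cands[!(drop_var | drop_cov), , drop = FALSE]
}

#' Remove candidates at known SNP positions
#'
#' Any candidate at a cataloged SNP position is removed regardless of its
#' allele, in every sample.
#'
#' @param cands candidate tibble.
#' @param snp_catalog tibble with `chrom` and `pos` (1-based) columns.
#' @return filtered candidate tibble.
#' @export
remove_known_snps <- function(cands, snp_catalog) {
  if (is.null(snp_catalog) || nrow(snp_catalog) == 0) {
    return(cands)
  }
  ck <- paste(cands$chrom, cands$pos, sep = "\r")
  sk <- paste(snp_catalog$chrom, snp_catalog$pos, sep = "\r")
  cands[!(ck %in% sk), , drop = FALSE]
}

#' Flag candidates present in a known-editing catalog
#'
#' @param cands candidate tibble.
#' @param known_edits catalog tibble with `chrom` and `pos`.
#' @return list with `cands` (with a `known_editing` column) and
#'   `overlap_fraction`: distinct flagged sites over distinct called sites
#'   (NA when the call set is empty).
#' @export
flag_known_editing <- function(cands, known_edits) {
  kk <- if (is.null(known_edits) || nrow(known_edits) == 0) {
    character(0)
  } else {
    paste(known_edits$chrom, known_edits$pos, sep = "\r")
  }
  ck <- paste(cands$chrom, cands$pos, sep = "\r")
  cands$known_editing <- ck %in% kk
  distinct_sites <- unique(ck)
  overlap <- if (length(distinct_sites) == 0) {
    NA_real_
  } else {
    length(unique(ck[cands$known_editing])) / length(distinct_sites)
  }
  list(cands = cands, overlap_fraction = overlap)
}

#' Full editing-site calling cascade
#'
#' Runs candidate detection, BH FDR control, AAF windowing, matched-DNA
#' germline subtraction, known-SNP removal and known-editing flagging in
#' one call. The three filters are pure predicate intersections, so their
#' order does not affect the final set.
#'
#' @param pileups pileup tibble.
#' @param dna GQ-filtered DNA variant genotypes.
#' @param dna_coverage per-sample DNA depth tibble (or `NULL`).
#' @param snp_catalog known-SNP positions (or `NULL`).
#' @param known_edits known-editing catalog (or `NULL`).
#' @param cfg an [edit_config()] object.
#' @return list with `sites` (called tibble, `editing_level = aaf`) and
#'   `known_overlap_fraction`.
#' @export
call_editing_sites <- function(pileups, dna, dna_coverage = NULL,
                               snp_catalog = NULL, known_edits = NULL,
                               cfg = edit_config()) {
  cands <- detect_candidates(pileups,
    error_rate = cfg$seq_error_rate,
    min_depth = cfg$min_rna_depth
  )
  cands <- add_fdr(cands, scope = cfg$bh_scope)
  cands <- filter_fdr_aaf(cands, cfg)
  cands <- subtract_genomic(cands, dna, dna_coverage, cfg)
  cands <- remove_known_snps(cands, snp_catalog)
  fl <- flag_known_editing(cands, known_edits)
  sites <- fl$cands
  sites$editing_level <- sites$aaf
  list(sites = sites, known_overlap_fraction = fl$overlap_fraction)
}

#' Recovery of implanted truth by the caller
#'
#' Compares called sites with the implanted ground truth per sample:
#' sensitivity overall and within the well-powered stratum (true level at
#' least `level_min`, observed RNA depth at least `depth_min`), the
#' empirical false discovery rate (called sample-site pairs that were not
#' implanted edits), and the number of surviving implanted SNPs whose
#' same-sample DNA genotype passed GQ.
#'
#' @param sites called site tibble.
#' @param truth an `edit_truth` object.
#' @param samples sample sheet tibble.
#' @param pileups the pileups the caller saw (for observed depth).
#' @param dna_records long DNA record tibble (for SNP genotype quality).
#' @param level_min,depth_min stratum bounds for the powered sensitivity.
#' @return one-row tibble: `sensitivity`, `sensitivity_powered`,
#'   `empirical_fdr`, `n_snp_survivors_gq30`, `n_called`, `n_true`.
#' @export
caller_recovery <- function(sites, truth, samples, pileups,
                            dna_records = NULL,
                            level_min = 0.05, depth_min = 30) {
  validate_sample_sheet(samples)
  expected <- tidyr::crossing(
    samples |> select("sample_id", "group"),
    truth$edit_sites |>
      select("chrom", "pos", "true_level", "group_specific")
  ) |>
    filter(!.data$group_specific | .data$group == "case")
  pk <- paste(pileups$sample_id, pileups$chrom, pileups$pos, sep = "\r")
  expected$obs_depth <- pileups$depth[match(
    paste(expected$sample_id, expected$chrom, expected$pos, sep = "\r"), pk
  )]
  called_key <- paste(sites$sample_id, sites$chrom, sites$pos, sep = "\r")
  expected$called <- paste(expected$sample_id, expected$chrom, expected$pos,
    sep = "\r"
  ) %in% called_key

  powered <- expected |>
    filter(.data$true_level >= level_min, .data$obs_depth >= depth_min)
  true_key <- paste(expected$sample_id, expected$chrom, expected$pos, sep = "\r")
  fp <- !(called_key %in% true_key)

  n_snp_surv <- 0L
  if (!is.null(dna_records) && nrow(sites) > 0) {
    snp_rec <- dna_records |>
      filter(.data$gt %in% c("0/1", "1/0"), .data$gq >= 30)
    sk <- paste(snp_rec$sample_id, snp_rec$chrom, snp_rec$pos, sep = "\r")
    n_snp_surv <- sum(called_key %in% sk)
  }
  tibble(
    sensitivity = mean(expected$called),
    sensitivity_powered = mean(powered$called),
    empirical_fdr = if (nrow(sites) == 0) NA_real_ else mean(fp),
    n_snp_survivors_gq30 = n_snp_surv,
    n_called = nrow(sites),
    n_true = nrow(expected)
  )
}
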