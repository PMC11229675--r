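#' Pipeline configuration
#'
#' Thresholds used across the calling, differential-expression and enrichment
#' stages. Defaults follow common practice for RNA-editing surveys of matched
#' DNA/RNA cohorts: candidate sites are kept when their Benjamini-Hochberg
#' false-discovery rate is at most `fdr_threshold`, their alternative allele
#' frequency (AAF) lies in `[aaf_min, aaf_max_exclusive)`, the same sample's
#' DNA shows at least `min_dna_depth` reads of genotype evidence, and DNA
#' genotypes used for germline subtraction pass `gq_min`.
#'
#' @param fdr_threshold maximum BH-adjusted p-value for a candidate site.
#' @param aaf_min minimum alternative allele frequency (inclusive).
#' @param aaf_max_exclusive maximum AAF (exclusive); 1 excludes fully
#'   alternative sites, which are genomic rather than editing signals.
#' @param gq_min minimum genotype quality for a DNA genotype to count.
#' @param qual_min minimum VCF site QUAL for a DNA record to count.
#' @param seq_error_rate per-base sequencing error rate used by the
#'   per-site binomial test.
#' @param min_rna_depth minimum RNA depth for a site to be testable.
#' @param min_dna_depth minimum same-sample DNA depth required to verify a
#'   candidate as non-genomic; less coverage drops the candidate.
#' @param de_padj_max,de_abs_log2fc_min significance thresholds for
#'   differential expression.
#' @param enrich_padj_max adjusted-p cutoff for enriched gene-set terms.
#' @param bh_scope `"per_sample"` (default) adjusts p-values within each
#'   sample's candidate list; `"pooled"` adjusts across the whole cohort.
#' @param rng_seed master seed for all randomised stages.
#' @return a list of class `edit_config`.
#' @export
#' @examples
#' cfg <- edit_config(fdr_threshold = 0.05)
#' cfg$aaf_min
edit_config <- function(fdr_threshold = 0.05,
                        aaf_min = 0.01,
                        aaf_max_exclusive = 1.0,
                        gq_min = 30L,
                        qual_min = 2,
                        seq_error_rate = 0.01,
                        min_rna_depth = 10L,
                        min_dna_depth = 10L,
                        de_padj_max = 0.05,
                        de_abs_log2fc_min = 1.0,
                        enrich_padj_max = 0.05,
                        bh_scope = c("per_sample", "pooled"),
                        rng_seed = 1L) {
  assert_fraction(fdr_threshold, "fdr_threshold")
  assert_fraction(aaf_min, "aaf_min")
  assert_fraction(aaf_max_exclusive, "aaf_max_exclusive")
  assert_fraction(seq_error_rate, "seq_error_rate")
  assert_fraction(de_padj_max, "de_padj_max")
  assert_fraction(enrich_padj_max, "enrich_padj_max")
  if (!(aaf_min > 0 && aaf_min < aaf_max_exclusive && aaf_max_exclusive <= 1)) {
    abort("need 0 < aaf_min < aaf_max_exclusive <= 1")
  }
  stopifnot(gq_min >= 0, min_rna_depth >= 0, min_dna_depth >= 0)
  structure(
    list(
      fdr_threshold = fdr_threshold,
      aaf_min = aaf_min,
      aaf_max_exclusive = aaf_max_exclusive,
      gq_min = as.integer(gq_min),
      qual_min = qual_min,
      seq_error_rate = seq_error_rate,
      min_rna_depth = as.integer(min_rna_depth),
      min_dna_depth = as.integer(min_dna_depth),
      de_padj_max = de_padj_max,
      de_abs_log2fc_min = de_abs_log2fc_min,
      enrich_padj_max = enrich_padj_max,
      bh_scope = match.arg(bh_scope),
      rng_seed = as.integer(rng_seed)
    ),
    class = "edit_config"
  )
}

#' Synthetic-cohort simulation parameters
#'
#' Parameters of the synthetic matched DNA/RNA cohort: a compact two-
#' chromosome genome tiled with stranded genes, Alu and non-Alu repeats,
#' implanted A-to-I-dominated editing sites enriched in Alu elements,
#' germline SNPs, negative-binomial expression counts with implanted
#' differentially expressed genes, an ADAR-like gene whose expression tracks
#' per-sample editing-site counts, and genes whose expression co-varies
#' monotonically with their own editing level.
#'
#' The defaults mirror the cohort structure the generator emulates: five
#' case and three control subjects, each contributing one subcutaneous and
#' one abdominal adipose sample; cases carry about `case_extra_sites_factor`
#' times as many editing sites as controls; roughly 80% of sites fall in Alu
#' elements and 70% are A-to-I in transcript orientation; about half of the
#' implanted sites are also present in the bundled known-editing catalog.
#'
#' @param n_case_subjects,n_control_subjects subjects per group (each gives
#'   two samples, one per tissue).
#' @param genome_length total genome size in bp across two chromosomes.
#' @param n_genes number of genes tiling the genome on alternating strands.
#' @param ncrna_fraction fraction of genes emitted without CDS (noncoding).
#' @param essential_fraction fraction of genes flagged essential.
#' @param alu_fraction_of_genome fraction of genome covered by Alu repeats.
#' @param other_repeat_fraction fraction covered by non-Alu repeats.
#' @param n_edit_sites number of shared implanted editing sites (present in
#'   every sample).
#' @param case_extra_sites_factor case/control ratio of expected per-sample
#'   implanted site counts (case-specific sites make up the excess).
#' @param frac_edits_in_alu fraction of implanted sites placed inside Alu.
#' @param a2i_fraction fraction of implanted sites that are A-to-I in
#'   transcript orientation.
#' @param known_edit_overlap fraction of implanted sites also written into
#'   the known-editing catalog.
#' @param case_specific_gene_fraction fraction of genes reserved to carry
#'   only case-specific sites, so case-only edited gene sets (the Venn-style
#'   set algebra) are non-trivial.
#' @param case_specific_in_reserved fraction of case-specific sites placed
#'   inside the reserved genes (the rest land anywhere).
#' @param n_snps number of implanted germline SNP positions.
#' @param known_snp_overlap fraction of implanted SNPs present in the known-
#'   SNP catalog (the rest must be caught by DNA-genotype subtraction).
#' @param n_background_sites extra non-edited pileup positions per sample.
#' @param mean_rna_depth,mean_dna_depth Poisson means of per-site coverage.
#' @param seq_error_rate per-base sequencing error rate.
#' @param level_shape1,level_shape2 Beta parameters of true editing levels.
#' @param edit_level_min,edit_level_max clipping bounds for true levels.
#' @param sample_propensity_range per-sample multiplicative range of editing
#'   propensity (drives sample-to-sample editing-level variation).
#' @param low_gq_fraction fraction of DNA genotype records emitted with
#'   genotype quality below 30 (unverifiable germline evidence).
#' @param n_de_genes,de_log2fc implanted differentially expressed genes and
#'   their absolute log2 fold change (half up, half down in cases).
#' @param n_coupled_genes genes whose expression is made co-monotone with
#'   their own editing level.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param mean_counts log-normal location of per-gene baseline mean counts.
#' @return a list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_genes = 40, genome_length = 120000)
#' p$n_edit_sites
sim_params <- function(n_case_subjects = 5L,
                       n_control_subjects = 3L,
                       genome_length = 220000L,
                       n_genes = 80L,
                       ncrna_fraction = 0.1,
                       essential_fraction = 0.2,
                       alu_fraction_of_genome = 0.25,
                       other_repeat_fraction = 0.08,
                       n_edit_sites = 250L,
                       case_extra_sites_factor = 1.6,
                       frac_edits_in_alu = 0.8,
                       a2i_fraction = 0.7,
                       known_edit_overlap = 0.5,
                       case_specific_gene_fraction = 0.3,
                       case_specific_in_reserved = 0.7,
                       n_snps = 150L,
                       known_snp_overlap = 0.5,
                       n_background_sites = 400L,
                       mean_rna_depth = 60,
                       mean_dna_depth = 30,
                       seq_error_rate = 0.01,
                       level_shape1 = 2,
                       level_shape2 = 6,
                       edit_level_min = 0.01,
                       edit_level_max = 0.95,
                       sample_propensity_range = c(0.6, 1.4),
                       low_gq_fraction = 0.01,
                       n_de_genes = 8L,
                       de_log2fc = 2.0,
                       n_coupled_genes = 8L,
                       nb_dispersion = 0.05,
                       mean_counts = 250) {
  for (nm in c(
    "ncrna_fraction", "essential_fraction", "alu_fraction_of_genome",
    "other_repeat_fraction", "frac_edits_in_alu", "a2i_fraction",
    "known_edit_overlap", "known_snp_overlap", "seq_error_rate",
    "low_gq_fraction", "case_specific_gene_fraction", "case_specific_in_reserved"
  )) {
    assert_fraction(get(nm), nm)
  }
  if (n_case_subjects < 2 || n_control_subjects < 2) {
    abort("need at least 2 subjects per group for testability")
  }
  if (case_extra_sites_factor < 1) {
    abort("case_extra_sites_factor must be >= 1")
  }
  p <- list(
    n_case_subjects = as.integer(n_case_subjects),
    n_control_subjects = as.integer(n_control_subjects),
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    ncrna_fraction = ncrna_fraction,
    essential_fraction = essential_fraction,
    alu_fraction_of_genome = alu_fraction_of_genome,
    other_repeat_fraction = other_repeat_fraction,
    n_edit_sites = as.integer(n_edit_sites),
    case_extra_sites_factor = case_extra_sites_factor,
    frac_edits_in_alu = frac_edits_in_alu,
    a2i_fraction = a2i_fraction,
    known_edit_overlap = known_edit_overlap,
    case_specific_gene_fraction = case_specific_gene_fraction,
    case_specific_in_reserved = case_specific_in_reserved,
    n_snps = as.integer(n_snps),
    known_snp_overlap = known_snp_overlap,
    n_background_sites = as.integer(n_background_sites),
    mean_rna_depth = mean_rna_depth,
    mean_dna_depth = mean_dna_depth,
    seq_error_rate = seq_error_rate,
    level_shape1 = level_shape1,
    level_shape2 = level_shape2,
    edit_level_min = edit_level_min,
    edit_level_max = edit_level_max,
    sample_propensity_range = sample_propensity_range,
    low_gq_fraction = low_gq_fraction,
    n_de_genes = as.integer(n_de_genes),
    de_log2fc = de_log2fc,
    n_coupled_genes = as.integer(n_coupled_genes),
    nb_dispersion = nb_dispersion,
    mean_counts = mean_counts
  )
  structure(p, class = "sim_params")
}

#' Sample sheet for the synthetic cohort
#'
#' One row per sample: each subject contributes one subcutaneous and one
#' abdominal sample; group is constant within subject.
#'
#' @param params a [sim_params()] object.
#' @return tibble with columns `sample_id`, `subject_id`, `group`, `tissue`.
#' @export
#' @examples
#' sample_sheet(sim_params())
sample_sheet <- function(params = sim_params()) {
  subjects <- tibble(
    subject_id = c(
      sprintf("case%02d", seq_len(params$n_case_subjects)),
      sprintf("ctrl%02d", seq_len(params$n_control_subjects))
    ),
    group = rep(
      c("case", "control"),
      c(params$n_case_subjects, params$n_control_subjects)
    )
  )
  tidyr::crossing(subjects, tissue = c("subcutaneous", "abdominal")) |>
    mutate(sample_id = paste(.data$subject_id, substr(.data$tissue, 1, 3),
      sep = "_"
    )) |>
    select("sample_id", "subject_id", "group", "tissue") |>
    arrange(.data$sample_id)
}

validate_sample_sheet <- function(samples) {
  assert_columns(samples, c("sample_id", "subject_id", "group", "tissue"),
    what = "sample sheet"
  )
  if (anyDuplicated(samples$sample_id) > 0) {
    abort("sample_id values must be unique")
  }
  dup <- samples |>
    count(.data$subject_id, .data$tissue) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("each subject may contribute at most one sample per tissue")
  }
  grp <- samples |>
    distinct(.data$subject_id, .data$group) |>
    count(.data$subject_id) |>
    filter(.data$n > 1)
  if (nrow(grp) > 0) abort("group must be constant within subject")
  invisible(samples)
}
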