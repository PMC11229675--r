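#' Run the full synthetic-study pipeline
#'
#' Simulates the study inputs to disk, reads every file back through the
#' package's own readers (file-based stage contracts), then runs calling,
#' annotation, editing statistics, differential expression (case vs control
#' within each tissue plus subcutaneous vs abdominal within cases),
#' over-representation of condition-specific edited genes, and the
#' editing-expression integration analyses. Writes the eight report tables
#' plus a truth-recovery table and returns everything with a deterministic
#' run manifest.
#'
#' @param params a [sim_params()] object.
#' @param cfg an [edit_config()] object.
#' @param seed master seed (defaults to `cfg$rng_seed`).
#' @param out_dir output directory; inputs land in `out_dir/inputs`,
#'   report tables in `out_dir/report`.
#' @return list of class `edit_run`: stage outputs, `recovery`, `manifest`
#'   and `manifest_hash`.
#' @export
run_pipeline <- function(params = sim_params(), cfg = edit_config(),
                         seed = cfg$rng_seed, out_dir = tempfile("editscape_run")) {
  input_dir <- file.path(out_dir, "inputs")
  report_dir <- file.path(out_dir, "report")
  sim <- simulate_dataset(params, seed, out_dir = input_dir)
  f <- sim$files

  # stage contracts are files on disk: read everything back
  models <- read_gene_models(f$gtf, essential_list = f$essential)
  repeats <- read_repeats(f$repeats)
  genome <- Biostrings::readDNAStringSet(f$genome)
  names(genome) <- sub(" .*", "", names(genome))
  pileups <- read_site_pileups(f$pileups)
  dna <- read_dna_genotypes(f$dna_vcf, gq_min = cfg$gq_min, qual_min = cfg$qual_min)
  dna_cov <- read_dna_coverage(f$dna_vcf)
  snp_catalog <- read_site_catalog(f$known_snps)
  known_edits <- read_site_catalog(f$known_edits)
  samples <- read_sample_sheet(f$samples)
  counts <- read_count_matrix(f$counts)
  genesets <- readr::read_tsv(f$genesets, show_col_types = FALSE, progress = FALSE)

  called <- call_editing_sites(pileups, dna, dna_cov, snp_catalog, known_edits, cfg)
  sites <- annotate_sites(called$sites, models, repeats, genome)

  summaries <- summarize_groups(sites, samples)
  alu <- alu_proportion(sites, samples)
  synnon <- syn_nonsyn_analysis(sites, samples)
  essnon <- ess_noness_analysis(sites, models)
  site_count_test <- compare_counts(
    summaries$per_sample$n_sites,
    summaries$per_sample$group
  )

  lengths <- gene_lengths(models)
  fpkm <- compute_fpkm(counts, lengths)
  de_tables <- list(
    case_vs_control_subcutaneous = run_contrast(
      counts, samples, "subcutaneous", c("group", "case", "control"), cfg
    ),
    case_vs_control_abdominal = run_contrast(
      counts, samples, "abdominal", c("group", "case", "control"), cfg
    ),
    sub_vs_abd_in_case = {
      ss <- samples |> filter(.data$group == "case")
      de <- nb_wald_de(counts |> select("gene_id", all_of(ss$sample_id)),
        ss,
        contrast = c("tissue", "subcutaneous", "abdominal"), cfg = cfg
      )
      as_tibble(de)
    }
  )
  de_results <- bind_rows(purrr::imap(
    de_tables,
    function(tb, nm) bind_cols(tibble(contrast = nm), tb)
  ))

  spec_sets <- specific_edited_sets(sites, samples)
  query <- spec_sets$specific_genes |>
    filter(.data$comparison == "case_subcutaneous_not_control_subcutaneous") |>
    pull("gene_id")
  enrichment <- hypergeom_enrich(query, genesets,
    universe = unique(models$gene_id), cfg = cfg
  )

  adar_cor <- adar_site_correlation(fpkm, sites, sim$truth$adar_genes, samples)
  ee_cor <- editing_expression_correlation(sites, fpkm, samples)
  correlations <- bind_rows(
    adar_cor |> mutate(gene_id = NA_character_, padj = NA_real_),
    ee_cor |> mutate(label = "editing_vs_expression")
  ) |> select("label", "gene_id", "r", "p", "padj", "n_pairs", "method")

  recovery <- bind_cols(
    caller_recovery(sites, sim$truth, samples, pileups, sim$dna_records),
    tibble(known_overlap_fraction = called$known_overlap_fraction)
  )

  report <- list(
    called_sites = sites,
    per_type_counts = summaries$per_type_counts,
    per_chrom_counts = summaries$per_chrom_counts,
    region_counts = summaries$region_counts,
    de_results = de_results,
    enrichment_results = enrichment,
    correlations = correlations,
    set_specific_genes = spec_sets$specific_genes
  )
  manifest <- write_report_tables(report, report_dir)
  manifest <- bind_rows(
    manifest,
    write_report_tables(list(recovery = recovery), report_dir)
  )
  cfg_hash <- rlang::hash(list(unclass(cfg), unclass(params), seed))
  manifest_hash <- rlang::hash(list(
    cfg_hash,
    manifest |> mutate(file = basename(.data$file)),
    purrr::map(report, \(tb) as.data.frame(tb))
  ))

  structure(
    list(
      params = params, cfg = cfg, seed = seed,
      files = f, samples = samples, truth = sim$truth,
      sites = sites, known_overlap_fraction = called$known_overlap_fraction,
      summaries = summaries, alu = alu, syn_nonsyn = synnon,
      ess_noness = essnon, site_count_test = site_count_test,
      fpkm = fpkm, de = de_tables, enrichment = enrichment,
      correlations = correlations, spec_sets = spec_sets,
      recovery = recovery, manifest = manifest,
      manifest_hash = manifest_hash, out_dir = out_dir
    ),
    class = "edit_run"
  )
}

run_contrast <- function(counts, samples, tissue, contrast, cfg) {
  ss <- samples |> filter(.data$tissue == !!tissue)
  de <- nb_wald_de(counts |> select("gene_id", all_of(ss$sample_id)),
    ss,
    contrast = contrast, cfg = cfg
  )
  as_tibble(de)
}

#' @export
print.edit_run <- function(x, ...) {
  cat("editscape pipeline run\n")
  cat(sprintf("  seed: %s  samples: %d\n", x$seed, nrow(x$samples)))
  cat(sprintf(
    "  called sites: %d (known-catalog overlap %.2f)\n",
    nrow(x$sites), x$known_overlap_fraction
  ))
  cat(sprintf(
    "  powered sensitivity %.3f, empirical FDR %.3f\n",
    x$recovery$sensitivity_powered, x$recovery$empirical_fdr
  ))
  cat(sprintf("  report tables: %d (out_dir: %s)\n", nrow(x$manifest), x$out_dir))
  invisible(x)
}
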