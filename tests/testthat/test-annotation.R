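test_that("sites are assigned to genes and regions by precedence", {
  models <- tiny_models()
  sites <- tibble::tibble(
    chrom = "chrT",
    pos = c(115L, 125L, 50L, 105L, 157L, 310L, 225L, 255L)
  )
  out <- assign_gene_region(sites, models)
  expect_equal(out$gene_id, c("gp", "gp", NA, "gp", "gp", "gn", "gm", "gm"))
  expect_equal(out$region, c(
    "exonic_cds", "intronic", "intergenic", "UTR5", "UTR3",
    "ncRNA_or_noncoding", "exonic_cds", "UTR5"
  ))
  # partition: exactly one region label each, from the closed vocabulary
  expect_true(all(out$region %in% c(
    "exonic_cds", "UTR3", "UTR5", "ncRNA_or_noncoding", "intronic", "intergenic"
  )))
})

test_that("overlapping genes resolve to the longest, deterministically", {
  models <- dplyr::bind_rows(
    tiny_models(),
    tibble::tibble(
      gene_id = "gz", chrom = "chrT", strand = "+",
      feature = c("gene", "exon"), start = c(110L, 110L), end = c(130L, 130L),
      biotype = "ncRNA", essential = FALSE, recoding_eligible = FALSE
    )
  )
  sites <- tibble::tibble(chrom = "chrT", pos = 115L)
  expect_message(out <- assign_gene_region(sites, models), "multiple genes")
  expect_equal(out$gene_id, "gp") # gp spans 60 bp, gz only 21
})

test_that("editing types are classified in transcript orientation", {
  sites <- tibble::tibble(
    ref = c("A", "T", "G", "C", "A"),
    alt = c("G", "C", "A", "A", "G"),
    gene_strand = c("+", "-", "-", "+", NA)
  )
  out <- classify_edit_type(sites)
  expect_equal(out$transcript_change, c("A>G", "A>G", "C>T", "C>A", "A>G"))
  expect_equal(out$edit_class, c("A-to-I", "A-to-I", "C-to-U", "other", "A-to-I"))
  expect_equal(out$strand_resolved, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("complementing strand and alleles together leaves the type fixed", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  for (ref in bases) {
    for (alt in setdiff(bases, ref)) {
      a <- classify_edit_type(tibble::tibble(
        ref = ref, alt = alt, gene_strand = "+"
      ))
      b <- classify_edit_type(tibble::tibble(
        ref = unname(comp[ref]), alt = unname(comp[alt]), gene_strand = "-"
      ))
      expect_equal(a$transcript_change, b$transcript_change)
      expect_equal(a$edit_class, b$edit_class)
    }
  }
})

test_that("coding effects match the exhaustive 576-case codon oracle", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  pad5 <- strrep("C", 10)
  for (codon in codons) {
    genome <- Biostrings::DNAStringSet(paste0(pad5, codon, strrep("C", 10)))
    names(genome) <- "chrX"
    models <- tibble::tibble(
      gene_id = "g1", chrom = "chrX", strand = "+",
      feature = c("gene", "exon", "CDS"),
      start = c(11L, 11L, 11L), end = c(13L, 13L, 13L),
      biotype = "protein_coding", essential = FALSE, recoding_eligible = TRUE
    )
    cases <- tidyr::crossing(off = 0:2, alt = bases) |>
      dplyr::mutate(refb = substring(codon, off + 1, off + 1)) |>
      dplyr::filter(alt != refb)
    sites <- tibble::tibble(
      chrom = "chrX", pos = 11L + cases$off, alt = cases$alt,
      gene_id = "g1", region = "exonic_cds"
    )
    got <- coding_effect(sites, models, genome)$coding_effect
    want <- mapply(oracle_coding_effect, codon, cases$off + 1, cases$alt)
    expect_equal(got, unname(want), label = paste("codon", codon))
  }
})

test_that("minus-strand codons are rebuilt via reverse complement", {
  skip_if_not_installed("seqinr")
  bases <- c("A", "C", "G", "T")
  set.seed(5)
  for (i in 1:20) {
    codon <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(codon)))
    genome <- Biostrings::DNAStringSet(paste0(strrep("C", 10), rc, strrep("C", 10)))
    names(genome) <- "chrX"
    models <- tibble::tibble(
      gene_id = "g1", chrom = "chrX", strand = "-",
      feature = c("gene", "exon", "CDS"),
      start = c(11L, 11L, 11L), end = c(13L, 13L, 13L),
      biotype = "protein_coding", essential = FALSE, recoding_eligible = TRUE
    )
    # genomic position 13 is transcript position 1 on the minus strand
    off <- sample(0:2, 1)
    t_ref <- substring(codon, off + 1, off + 1)
    t_alt <- sample(setdiff(bases, t_ref), 1)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    sites <- tibble::tibble(
      chrom = "chrX", pos = 13L - off, alt = unname(comp[t_alt]),
      gene_id = "g1", region = "exonic_cds"
    )
    got <- coding_effect(sites, models, genome)$coding_effect
    expect_equal(got, oracle_coding_effect(codon, off + 1, t_alt))
  }
})

test_that("stop-codon recoding gives stop_loss, and edge codons bail out", {
  genome <- Biostrings::DNAStringSet(paste0(strrep("C", 10), "TAG", strrep("C", 10)))
  names(genome) <- "chrX"
  models <- tibble::tibble(
    gene_id = "g1", chrom = "chrX", strand = "+",
    feature = c("gene", "exon", "CDS"),
    start = c(11L, 11L, 11L), end = c(13L, 13L, 13L),
    biotype = "protein_coding", essential = FALSE, recoding_eligible = TRUE
  )
  # TAG -> TGG: stop becomes Trp
  sites <- tibble::tibble(
    chrom = "chrX", pos = 12L, alt = "G", gene_id = "g1", region = "exonic_cds"
  )
  expect_equal(coding_effect(sites, models, genome)$coding_effect, "stop_loss")

  # recoding-ineligible gene stays not_applicable
  models2 <- models |> dplyr::mutate(recoding_eligible = FALSE)
  expect_equal(
    coding_effect(sites, models2, genome)$coding_effect,
    "not_applicable"
  )
})

test_that("repeat classes follow Alu > other repeat > nonrepetitive", {
  repeats <- tiny_repeats()
  sites <- tibble::tibble(
    chrom = "chrT", pos = c(110L, 310L, 50L, 130L, 131L)
  )
  out <- classify_repeat(sites, repeats)
  expect_equal(out$repeat_class, c(
    "Alu", "repetitive_non_Alu", "nonrepetitive", "Alu", "nonrepetitive"
  ))
  # Alu wins when intervals of both families cover a position
  both <- dplyr::bind_rows(
    repeats,
    tibble::tibble(chrom = "chrT", start = 100L, end = 130L, family = "L1")
  )
  expect_equal(
    classify_repeat(tibble::tibble(chrom = "chrT", pos = 110L), both)$repeat_class,
    "Alu"
  )
})

test_that("annotate_sites produces one coherent record per called site", {
  d <- simulate_dataset(small_params(), seed = 29)
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
  ann <- annotate_sites(called$sites, d$ann$models, d$ann$repeats, d$ann$genome)
  expect_equal(nrow(ann), nrow(called$sites))
  expect_false(any(is.na(ann$region)))
  expect_false(any(is.na(ann$repeat_class)))
  expect_equal(ann$editing_level, ann$aaf)
  # implanted site types must be reproduced exactly in transcript space
  tr_key <- paste(d$truth$edit_sites$chrom, d$truth$edit_sites$pos)
  hit <- match(paste(ann$chrom, ann$pos), tr_key)
  ok <- !is.na(hit)
  expect_gt(sum(ok), 0)
  expect_equal(
    ann$transcript_change[ok],
    d$truth$edit_sites$transcript_change[hit[ok]]
  )
})
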