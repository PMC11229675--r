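# Shared fixtures, built in code at test time.

# reduced cohort for fast simulation-backed tests
small_params <- function(...) {
  args <- utils::modifyList(
    list(
      genome_length = 90000L, n_genes = 30L,
      n_edit_sites = 90L, n_snps = 40L, n_background_sites = 120L,
      n_coupled_genes = 4L, n_de_genes = 4L
    ),
    list(...)
  )
  do.call(sim_params, args)
}

# one plus-strand and one minus-strand coding gene with fully known
# structure, plus a noncoding gene, on a deterministic genome
tiny_models <- function() {
  dplyr::bind_rows(
    # gp: + strand, span 101-160; exons 101-120 (UTR5 101-110, CDS 111-120),
    #     131-140 (CDS), 151-160 (CDS 151-152, UTR3 153-160); CDS len 22? no:
    #     CDS pieces 10 + 10 + 2 = 22 -> not divisible; use CDS 151-154 (4)
    #     -> 24 bases, divisible by 3.
    tibble::tibble(
      gene_id = "gp", chrom = "chrT", strand = "+",
      feature = c("gene", "exon", "exon", "exon", "CDS", "CDS", "CDS", "UTR5", "UTR3"),
      start = c(101L, 101L, 131L, 151L, 111L, 131L, 151L, 101L, 155L),
      end = c(160L, 120L, 140L, 160L, 120L, 140L, 154L, 110L, 160L),
      biotype = "protein_coding", essential = FALSE, recoding_eligible = TRUE
    ),
    # gm: - strand, span 201-260, mirrored layout
    tibble::tibble(
      gene_id = "gm", chrom = "chrT", strand = "-",
      feature = c("gene", "exon", "exon", "exon", "CDS", "CDS", "CDS", "UTR3", "UTR5"),
      start = c(201L, 201L, 221L, 241L, 207L, 221L, 241L, 201L, 251L),
      end = c(260L, 210L, 230L, 260L, 210L, 230L, 250L, 206L, 260L),
      biotype = "protein_coding", essential = TRUE, recoding_eligible = TRUE
    ),
    tibble::tibble(
      gene_id = "gn", chrom = "chrT", strand = "+",
      feature = c("gene", "exon"),
      start = c(301L, 301L), end = c(340L, 340L),
      biotype = "ncRNA", essential = FALSE, recoding_eligible = FALSE
    )
  )
}

tiny_genome <- function() {
  set.seed(42)
  g <- Biostrings::DNAStringSet(paste(sample(c("A", "C", "G", "T"), 400,
    replace = TRUE
  ), collapse = ""))
  names(g) <- "chrT"
  g
}

tiny_repeats <- function() {
  tibble::tibble(
    chrom = "chrT",
    start = c(100L, 300L), # 0-based half-open
    end = c(130L, 320L),
    family = c("Alu", "L1")
  )
}

# random candidate table for filter-semantics tests
random_candidates <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sample(c("s1", "s2", "s3"), n, replace = TRUE),
    chrom = "chr1",
    pos = sample.int(5000, n),
    ref = "A", alt = "G",
    ref_count = 50L, alt_count = 5L,
    aaf = runif(n),
    p_value = runif(n)^2,
    q_value = runif(n) * 0.12
  ) |> dplyr::distinct(.data$sample_id, .data$pos, .keep_all = TRUE)
}
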