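REGION_LEVELS <- c(
  "exonic_cds", "UTR3", "UTR5", "ncRNA_or_noncoding", "intronic", "intergenic"
)

#' Assign called sites to genes and genic regions
#'
#' Each site is assigned to the unique overlapping gene; when several genes
#' overlap, the longest overlapping gene wins, then lexicographic gene id
#' (deterministic, reported via message). The region label follows the
#' precedence CDS > UTR3 > UTR5 > noncoding exon > intron; sites outside
#' all genes are intergenic with no gene id.
#'
#' @param sites tibble with `chrom` and `pos` (1-based).
#' @param models gene-model tibble from [read_gene_models()].
#' @return `sites` with `gene_id`, `gene_strand` and `region` columns.
#' @export
assign_gene_region <- function(sites, models) {
  genes <- models |> filter(.data$feature == "gene")
  qu <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  su <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(qu, su)
  ht <- tibble(
    site = S4Vectors::queryHits(hits),
    gene_idx = S4Vectors::subjectHits(hits)
  ) |>
    mutate(
      gene_id = genes$gene_id[.data$gene_idx],
      gene_strand = genes$strand[.data$gene_idx],
      span = genes$end[.data$gene_idx] - genes$start[.data$gene_idx] + 1L
    )
  n_multi <- ht |>
    count(.data$site) |>
    filter(.data$n > 1) |>
    nrow()
  if (n_multi > 0) {
    inform(sprintf(
      "%d site(s) overlap multiple genes; longest gene kept", n_multi
    ))
  }
  pick <- ht |>
    arrange(.data$site, desc(.data$span), .data$gene_id) |>
    distinct(.data$site, .keep_all = TRUE)
  sites$gene_id <- NA_character_
  sites$gene_strand <- NA_character_
  sites$gene_id[pick$site] <- pick$gene_id
  sites$gene_strand[pick$site] <- pick$gene_strand

  sites$region <- "intergenic"
  genic <- which(!is.na(sites$gene_id))
  if (length(genic) > 0) {
    feat <- models |> filter(.data$feature != "gene")
    biot <- models |>
      filter(.data$feature == "gene") |>
      distinct(.data$gene_id, .data$biotype)
    fq <- GenomicRanges::GRanges(
      sites$chrom[genic],
      IRanges::IRanges(sites$pos[genic], sites$pos[genic])
    )
    fs <- GenomicRanges::GRanges(feat$chrom, IRanges::IRanges(feat$start, feat$end))
    fh <- GenomicRanges::findOverlaps(fq, fs)
    ft <- tibble(
      site = genic[S4Vectors::queryHits(fh)],
      gene_id = feat$gene_id[S4Vectors::subjectHits(fh)],
      feature = feat$feature[S4Vectors::subjectHits(fh)]
    ) |>
      filter(.data$gene_id == sites$gene_id[.data$site])
    ft <- ft |>
      left_join(biot, by = "gene_id") |>
      mutate(region = case_when(
        .data$feature == "CDS" ~ "exonic_cds",
        .data$feature == "UTR3" ~ "UTR3",
        .data$feature == "UTR5" ~ "UTR5",
        .data$feature == "exon" & .data$biotype != "protein_coding" ~
          "ncRNA_or_noncoding",
        TRUE ~ NA_character_
      )) |>
      filter(!is.na(.data$region)) |>
      mutate(prec = match(.data$region, REGION_LEVELS)) |>
      arrange(.data$site, .data$prec) |>
      distinct(.data$site, .keep_all = TRUE)
    sites$region[genic] <- "intronic"
    sites$region[ft$site] <- ft$region
  }
  sites
}

#' Classify editing type in transcript orientation
#'
#' Genomic ref/alt are complemented into transcript space for minus-strand
#' genes: an A/G mismatch on a plus-strand gene and a T/C mismatch on a
#' minus-strand gene are both A>G in the transcript, i.e. A-to-I editing.
#' Sites without a resolved strand (intergenic) keep the genomic change;
#' their class is assigned from the genomic change when it maps to a named
#' class, but flagged as strand-unresolved.
#'
#' @param sites tibble with `ref`, `alt` (genomic) and `gene_strand`
#'   (`"+"`, `"-"` or NA).
#' @return `sites` with `transcript_change`, `edit_class` and
#'   `strand_resolved` columns.
#' @export
classify_edit_type <- function(sites) {
  assert_columns(sites, c("ref", "alt", "gene_strand"), "sites")
  minus <- !is.na(sites$gene_strand) & sites$gene_strand == "-"
  t_ref <- ifelse(minus, complement_base(sites$ref), sites$ref)
  t_alt <- ifelse(minus, complement_base(sites$alt), sites$alt)
  change <- paste0(t_ref, ">", t_alt)
  class_map <- c(
    "A>G" = "A-to-I", "C>T" = "C-to-U", "T>C" = "U-to-C", "G>A" = "G-to-A"
  )
  cls <- unname(class_map[change])
  resolved <- !is.na(sites$gene_strand)
  cls[is.na(cls) & resolved] <- "other"
  cls[is.na(cls) & !resolved] <- "unresolved"
  sites$transcript_change <- change
  sites$edit_class <- cls
  sites$strand_resolved <- resolved
  sites
}

#' Synonymous/nonsynonymous consequence of edited CDS sites
#'
#' Rebuilds the codon containing each CDS site from the gene's CDS in
#' transcript orientation, substitutes the edited base and translates with
#' the standard genetic code. Stop codons map to `stop_loss` (stop becomes
#' an amino acid) or `stop_gain` (amino acid becomes stop). Sites outside
#' CDS, in recoding-ineligible genes, or in partial codons get
#' `not_applicable`.
#'
#' @param sites tibble with `chrom`, `pos`, `alt`, `gene_id`, `region`.
#' @param models gene-model tibble.
#' @param genome a [Biostrings::DNAStringSet] (chromosome sequences).
#' @return `sites` with a `coding_effect` column.
#' @export
coding_effect <- function(sites, models, genome) {
  sites$coding_effect <- "not_applicable"
  idx <- which(sites$region == "exonic_cds" & !is.na(sites$gene_id))
  if (length(idx) == 0) {
    return(sites)
  }
  elig <- models |>
    filter(.data$feature == "gene") |>
    distinct(.data$gene_id, .data$recoding_eligible)
  chrom_seq <- as.character(genome)
  code <- Biostrings::GENETIC_CODE

  for (g in unique(sites$gene_id[idx])) {
    ok <- elig$recoding_eligible[match(g, elig$gene_id)]
    if (is.na(ok) || !ok) next
    cds <- models |>
      filter(.data$gene_id == g, .data$feature == "CDS") |>
      arrange(.data$start)
    if (nrow(cds) == 0) next
    strand <- cds$strand[1]
    chrom <- cds$chrom[1]
    pieces <- substring(chrom_seq[[chrom]], cds$start, cds$end)
    cds_seq <- paste(pieces, collapse = "")
    # genomic coordinates of each CDS base, 5'->3' in transcript space
    gpos <- unlist(purrr::map2(cds$start, cds$end, seq.int))
    if (strand == "-") {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)
      ))
      gpos <- rev(gpos)
    }
    here <- idx[sites$gene_id[idx] == g]
    for (i in here) {
      ti <- match(sites$pos[i], gpos)
      if (is.na(ti)) next
      codon_i <- (ti - 1) %/% 3
      cstart <- codon_i * 3 + 1
      if (cstart + 2 > nchar(cds_seq)) {
        inform(sprintf("site %s:%d in partial codon; not_applicable",
          sites$chrom[i], sites$pos[i]
        ))
        next
      }
      codon <- substring(cds_seq, cstart, cstart + 2)
      off <- ti - cstart + 1
      t_alt <- if (strand == "-") complement_base(sites$alt[i]) else sites$alt[i]
      edited <- codon
      substr(edited, off, off) <- t_alt
      aa_ref <- code[[codon]]
      aa_alt <- code[[edited]]
      sites$coding_effect[i] <- if (aa_ref == aa_alt) {
        "synonymous"
      } else if (aa_ref == "*") {
        "stop_loss"
      } else if (aa_alt == "*") {
        "stop_gain"
      } else {
        "nonsynonymous"
      }
    }
  }
  sites
}

#' Repeat-class label for called sites
#'
#' `Alu` when the position falls in any Alu interval (Alu wins ties),
#' `repetitive_non_Alu` when only in another repeat family, else
#' `nonrepetitive`. BED intervals are 0-based half-open, so a 1-based
#' position `pos` overlaps `[s, e)` iff `s < pos <= e`.
#'
#' @param sites tibble with `chrom`, `pos`.
#' @param repeats repeat tibble from [read_repeats()].
#' @return `sites` with a `repeat_class` column.
#' @export
classify_repeat <- function(sites, repeats) {
  in_alu <- positions_in_intervals(
    sites$chrom, sites$pos,
    repeats |> filter(.data$family == "Alu")
  )
  in_other <- positions_in_intervals(
    sites$chrom, sites$pos,
    repeats |> filter(.data$family != "Alu")
  )
  sites$repeat_class <- ifelse(in_alu, "Alu",
    ifelse(in_other, "repetitive_non_Alu", "nonrepetitive")
  )
  sites
}

#' Annotate called editing sites
#'
#' Runs gene/region assignment, strand-aware type classification,
#' synonymous/nonsynonymous recoding and repeat classification, and sets
#' `editing_level` to the site's AAF.
#'
#' @param sites called site tibble from [call_editing_sites()].
#' @param models gene-model tibble.
#' @param repeats repeat tibble.
#' @param genome chromosome sequences ([Biostrings::DNAStringSet]).
#' @return fully annotated site tibble.
#' @export
annotate_sites <- function(sites, models, repeats, genome) {
  sites <- assign_gene_region(sites, models)
  sites <- classify_edit_type(sites)
  sites <- coding_effect(sites, models, genome)
  sites <- classify_repeat(sites, repeats)
  if (!"editing_level" %in% names(sites) && "aaf" %in% names(sites)) {
    sites$editing_level <- sites$aaf
  }
  sites
}
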