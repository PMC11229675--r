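#' Read gene models from a GTF file
#'
#' Parses gene/exon/CDS (and, when present, UTR) features into a tidy
#' gene-model table. UTRs absent from the GTF are derived as exon minus CDS,
#' split into 5' and 3' parts by transcript orientation. Genes whose total
#' CDS length is not divisible by 3 are flagged recoding-ineligible with a
#' warning.
#'
#' Coordinates are 1-based inclusive throughout (GTF convention).
#'
#' @param gtf_path path to a GTF (GTF2.2 dialect) file.
#' @param essential_list optional path to a TSV whose first column holds the
#'   gene ids of essential genes; all other genes are flagged nonessential.
#' @return tibble with one row per feature interval: `gene_id`, `chrom`,
#'   `strand`, `feature` (gene/exon/CDS/UTR5/UTR3), `start`, `end`,
#'   `biotype`, `essential`, `recoding_eligible`.
#' @export
read_gene_models <- function(gtf_path, essential_list = NULL) {
  check_gtf_lines(gtf_path)
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  tb <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  tb$feature[tb$feature %in% c("five_prime_utr", "5UTR")] <- "UTR5"
  tb$feature[tb$feature %in% c("three_prime_utr", "3UTR")] <- "UTR3"
  tb <- tb |> filter(.data$feature %in% c("gene", "exon", "CDS", "UTR5", "UTR3"))

  per_gene <- split(tb, tb$gene_id)
  out <- purrr::map(per_gene, derive_gene_model)
  models <- bind_rows(out)

  bad <- models |>
    filter(.data$feature == "CDS") |>
    group_by(.data$gene_id) |>
    summarise(cds_len = sum(.data$end - .data$start + 1), .groups = "drop") |>
    filter(.data$cds_len %% 3 != 0)
  models$recoding_eligible <- models$biotype == "protein_coding" &
    !(models$gene_id %in% bad$gene_id)
  if (nrow(bad) > 0) {
    warn(sprintf(
      "CDS length not divisible by 3 for %d gene(s) (%s); flagged recoding-ineligible",
      nrow(bad), paste(utils::head(bad$gene_id, 3), collapse = ", ")
    ))
  }

  ess <- character(0)
  if (!is.null(essential_list)) {
    ess_tb <- readr::read_tsv(essential_list,
      show_col_types = FALSE,
      progress = FALSE
    )
    if (nrow(ess_tb) > 0) ess <- as.character(ess_tb[[1]])
  }
  models$essential <- models$gene_id %in% ess
  models |>
    arrange(.data$chrom, .data$start, .data$gene_id) |>
    as_tibble()
}

check_gtf_lines <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1
  if (any(nfield != 9)) {
    bad_line <- which(body)[which(nfield != 9)[1]]
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields", bad_line))
  }
  invisible(TRUE)
}

# expand one gene's raw GTF rows into the canonical feature table,
# deriving UTRs from exon \ CDS when the file does not carry them.
derive_gene_model <- function(g) {
  gene_row <- g[g$feature == "gene", , drop = FALSE]
  if (nrow(gene_row) == 0) {
    gene_row <- g[1, , drop = FALSE]
    gene_row$feature <- "gene"
    gene_row$start <- min(g$start)
    gene_row$end <- max(g$end)
  }
  exons <- g[g$feature == "exon", , drop = FALSE]
  cds <- g[g$feature == "CDS", , drop = FALSE]
  utrs <- g[g$feature %in% c("UTR5", "UTR3"), , drop = FALSE]
  biotype <- if (nrow(cds) > 0) "protein_coding" else "ncRNA"

  if (nrow(utrs) == 0 && nrow(cds) > 0 && nrow(exons) > 0) {
    ex <- IRanges::IRanges(exons$start, exons$end)
    cd <- IRanges::IRanges(cds$start, cds$end)
    left <- IRanges::setdiff(ex, cd)
    if (length(left) > 0) {
      lt <- tibble(
        gene_id = gene_row$gene_id[1], chrom = gene_row$chrom[1],
        strand = gene_row$strand[1], feature = NA_character_,
        start = IRanges::start(left), end = IRanges::end(left)
      )
      cds_lo <- min(cds$start)
      cds_hi <- max(cds$end)
      upstream <- lt$end < cds_lo
      downstream <- lt$start > cds_hi
      if (gene_row$strand[1] == "+") {
        lt$feature <- ifelse(upstream, "UTR5", ifelse(downstream, "UTR3", NA))
      } else {
        lt$feature <- ifelse(upstream, "UTR3", ifelse(downstream, "UTR5", NA))
      }
      utrs <- lt[!is.na(lt$feature), , drop = FALSE]
    }
  }
  res <- bind_rows(
    gene_row[, c("gene_id", "chrom", "strand", "feature", "start", "end")],
    exons[, c("gene_id", "chrom", "strand", "feature", "start", "end")],
    cds[, c("gene_id", "chrom", "strand", "feature", "start", "end")],
    utrs[, c("gene_id", "chrom", "strand", "feature", "start", "end")]
  )
  res$biotype <- biotype
  res
}

#' Write gene models to GTF
#'
#' Emits gene, exon and CDS rows (UTRs are derivable and therefore not
#' written), matching what [read_gene_models()] consumes.
#'
#' @param models gene-model tibble as produced by [read_gene_models()] or the
#'   simulator.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  keep <- models |> filter(.data$feature %in% c("gene", "exon", "CDS"))
  gr <- GenomicRanges::GRanges(
    seqnames = keep$chrom,
    ranges = IRanges::IRanges(keep$start, keep$end),
    strand = keep$strand
  )
  gr$source <- "editscape"
  gr$type <- keep$feature
  gr$gene_id <- keep$gene_id
  gr$transcript_id <- ifelse(keep$feature == "gene", NA_character_,
    paste0(keep$gene_id, ".t1")
  )
  gr$phase <- cds_phase(keep)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# GTF phase per CDS row: bases to skip before the first complete codon,
# accumulated along transcript orientation.
cds_phase <- function(feat) {
  phase <- rep(NA_integer_, nrow(feat))
  idx <- which(feat$feature == "CDS")
  for (g in unique(feat$gene_id[idx])) {
    gi <- idx[feat$gene_id[idx] == g]
    ord <- if (feat$strand[gi[1]] == "-") {
      gi[order(feat$start[gi], decreasing = TRUE)]
    } else {
      gi[order(feat$start[gi])]
    }
    len <- feat$end[ord] - feat$start[ord] + 1L
    before <- c(0L, cumsum(len)[-length(len)])
    phase[ord] <- (3L - before %% 3L) %% 3L
  }
  phase
}

#' Read site-level RNA pileups
#'
#' @param tsv_path TSV with header columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref` (A/C/G/T) and `count_A`, `count_C`, `count_G`,
#'   `count_T`. Rows with a reference base outside A/C/G/T are rejected with
#'   a message; a duplicated (sample, chrom, pos) key is an error.
#' @return tibble keyed by (sample_id, chrom, pos) with a `depth` column
#'   equal to the sum of the four base counts.
#' @export
read_site_pileups <- function(tsv_path) {
  tb <- readr::read_tsv(tsv_path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      sample_id = "c", chrom = "c", pos = "i", ref = "c",
      count_A = "i", count_C = "i", count_G = "i", count_T = "i"
    )
  )
  assert_columns(tb, c(
    "sample_id", "chrom", "pos", "ref",
    "count_A", "count_C", "count_G", "count_T"
  ), "pileup table")
  bad_ref <- !(tb$ref %in% BASES)
  if (any(bad_ref)) {
    inform(sprintf(
      "rejected %d pileup record(s) with reference base outside A/C/G/T",
      sum(bad_ref)
    ))
    tb <- tb[!bad_ref, , drop = FALSE]
  }
  if (anyDuplicated(tb[c("sample_id", "chrom", "pos")]) > 0) {
    abort("duplicate (sample_id, chrom, pos) key in pileup table")
  }
  counts <- as.matrix(tb[paste0("count_", BASES)])
  if (any(counts < 0)) abort("negative base count in pileup table")
  tb$depth <- as.integer(rowSums(counts))
  tb
}

#' Write site pileups to TSV
#' @param pileups pileup tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_pileups <- function(pileups, path) {
  pileups |>
    select(
      "sample_id", "chrom", "pos", "ref",
      "count_A", "count_C", "count_G", "count_T"
    ) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' Read variant DNA genotypes from a VCF
#'
#' Returns only variant genotypes (het or hom-alt) that pass the genotype-
#' quality and site-quality filters; genotypes with missing GQ are treated
#' as failing and reported via a message.
#'
#' @param vcf_path VCF 4.x file with per-sample `GT`, `GQ` and `DP` fields.
#' @param gq_min minimum genotype quality (default 30).
#' @param qual_min minimum site QUAL (default 2).
#' @return tibble: `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `genotype` (`het`/`hom_alt`), `gq`, `dna_depth`.
#' @export
read_dna_genotypes <- function(vcf_path, gq_min = 30L, qual_min = 2) {
  long <- vcf_long(vcf_path)
  n_missing_gq <- sum(long$variant & is.na(long$gq))
  if (n_missing_gq > 0) {
    inform(sprintf(
      "%d variant genotype(s) with missing GQ treated as failing the filter",
      n_missing_gq
    ))
  }
  long |>
    filter(
      .data$variant,
      !is.na(.data$gq), .data$gq >= gq_min,
      is.na(.data$qual) | .data$qual >= qual_min
    ) |>
    mutate(genotype = ifelse(.data$hom, "hom_alt", "het")) |>
    select(
      "sample_id", "chrom", "pos", "ref", "alt",
      "genotype", "gq", "dna_depth"
    )
}

#' Read per-sample DNA depth at every VCF record
#'
#' Germline subtraction needs hom-ref coverage evidence as well as variant
#' calls, so the simulator emits a record (possibly `0/0`) for every assayed
#' site; this reader recovers the per-sample depth at each of them.
#'
#' @inheritParams read_dna_genotypes
#' @return tibble: `sample_id`, `chrom`, `pos`, `dna_depth`.
#' @export
read_dna_coverage <- function(vcf_path) {
  vcf_long(vcf_path) |> select("sample_id", "chrom", "pos", "dna_depth")
}

vcf_long <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF drops dims
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, nrow = 1, dimnames = list(NULL, names(x))) else x
  }
  gt <- as_mat(vcfR::extract.gt(v, element = "GT"))
  gq <- suppressWarnings(as_mat(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)))
  dp <- suppressWarnings(as_mat(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)))
  samples <- colnames(gt)
  base <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = ifelse(is.na(fix$ALT) | fix$ALT == ".", NA_character_, fix$ALT),
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
  long <- purrr::map(samples, function(s) {
    tb <- base
    tb$sample_id <- s
    tb$gt <- gsub("\\|", "/", gt[, s])
    tb$gq <- gq[, s]
    tb$dna_depth <- as.integer(dp[, s])
    tb
  }) |> bind_rows()
  long$variant <- long$gt %in% c("0/1", "1/0", "1/1") & !is.na(long$alt)
  long$hom <- long$gt == "1/1"
  long
}

#' Write per-sample DNA genotypes to a multi-sample VCF
#'
#' Emits a VCF 4.2 file with `GT:GQ:DP` per-sample fields, one record per
#' assayed site (hom-ref sites carry `ALT=.`). Output is readable by
#' [read_dna_genotypes()] and [read_dna_coverage()].
#'
#' @param records tibble with `chrom`, `pos`, `ref`, `alt` (NA for hom-ref
#'   sites), `qual` and one list of per-sample fields via columns
#'   `sample_id`, `gt`, `gq`, `dna_depth` (long form: one row per
#'   sample x site).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dna_vcf <- function(records, path) {
  assert_columns(records, c(
    "chrom", "pos", "ref", "alt", "qual",
    "sample_id", "gt", "gq", "dna_depth"
  ), "VCF record table")
  samples <- sort(unique(records$sample_id))
  site <- records |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$qual) |>
    arrange(.data$chrom, .data$pos)
  if (anyDuplicated(site[c("chrom", "pos")]) > 0) {
    abort("conflicting site definitions for one (chrom, pos) in VCF records")
  }
  wide <- records |>
    mutate(field = sprintf("%s:%s:%d", .data$gt, .data$gq, .data$dna_depth)) |>
    select("chrom", "pos", "sample_id", "field") |>
    pivot_wider(names_from = "sample_id", values_from = "field") |>
    arrange(.data$chrom, .data$pos)
  for (s in samples) {
    if (!s %in% names(wide)) wide[[s]] <- "./.:.:."
    wide[[s]][is.na(wide[[s]])] <- "./.:.:."
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=editscape",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  body <- paste(
    site$chrom, site$pos, ".", site$ref,
    ifelse(is.na(site$alt), ".", site$alt),
    site$qual, "PASS", ".", "GT:GQ:DP",
    sep = "\t"
  )
  sample_block <- do.call(paste, c(unname(as.list(wide[samples])), sep = "\t"))
  readr::write_lines(c(header, paste(body, sample_block, sep = "\t")), path)
  invisible(path)
}

#' Read repeat regions from BED
#'
#' BED intervals are 0-based half-open; a 1-based position `pos` overlaps
#' interval `[s, e)` iff `s < pos <= e`.
#'
#' @param bed_path BED file whose name column carries the repeat family
#'   (e.g. `Alu`, `L1`).
#' @return tibble: `chrom`, `start` (0-based), `end` (exclusive), `family`.
#' @export
read_repeats <- function(bed_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    family = if (is.null(gr$name)) "repeat" else as.character(gr$name)
  )
}

#' Write repeat regions to BED
#' @param repeats tibble with 0-based half-open `start`/`end` and `family`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeats_bed <- function(repeats, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = repeats$chrom,
    ranges = IRanges::IRanges(repeats$start + 1L, repeats$end),
    name = repeats$family
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a position catalog (known SNPs or known editing sites)
#'
#' @param path TSV with at least `chrom` and `pos` (1-based) columns;
#'   known-editing catalogs additionally carry `ref` and `alt`.
#' @return tibble of catalog records.
#' @export
read_site_catalog <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tb, c("chrom", "pos"), "site catalog")
  tb$pos <- as.integer(tb$pos)
  tb
}

#' Write a position catalog to TSV
#' @param catalog tibble with `chrom`, `pos`, and optional further columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path, progress = FALSE)
  invisible(path)
}

#' Read a gene count matrix
#' @param path TSV with first column `gene_id` and one column per sample.
#' @return tibble (genes x samples).
#' @export
read_count_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tb, "gene_id", "count matrix")
  tb
}

#' Write a gene count matrix
#' @param counts tibble with `gene_id` plus sample columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#' @param path TSV with `sample_id`, `subject_id`, `group`, `tissue`.
#' @return validated tibble.
#' @export
read_sample_sheet <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(tb)
  tb
}

#' Write report tables and a run manifest
#'
#' Writes each element of `results` as `<name>.tsv` under `out_dir` and
#' returns a manifest of files and row counts. Rerunning with identical
#' inputs reproduces the files byte-identically.
#'
#' @param results named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return tibble manifest: `table`, `file`, `n_rows`.
#' @export
write_report_tables <- function(results, out_dir) {
  stopifnot(is.list(results), !is.null(names(results)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  rows <- purrr::imap(results, function(tb, nm) {
    stopifnot(is.data.frame(tb))
    file <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tb, file, progress = FALSE)
    tibble(table = nm, file = file, n_rows = nrow(tb))
  })
  bind_rows(rows)
}
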