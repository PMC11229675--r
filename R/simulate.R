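#' Simulate a toy genome with gene, repeat and essentiality annotation
#'
#' Builds a two-chromosome random genome tiled with stranded genes (a fixed
#' three-exon structure with UTR5/CDS/UTR3 for coding genes; exon-only
#' noncoding genes), places non-overlapping Alu and non-Alu repeat intervals,
#' and flags a fraction of genes as essential. All downstream structure
#' (editing sites, SNPs, expression) is implanted on top of this scaffold.
#'
#' @param params a [sim_params()] object.
#' @param seed integer master seed; the same seed reproduces the genome
#'   byte-identically.
#' @return list with `genome` (a [Biostrings::DNAStringSet]), `models`
#'   (gene-model tibble as in [read_gene_models()]) and `repeats`
#'   (0-based half-open repeat tibble).
#' @export
simulate_genome_annotation <- function(params = sim_params(), seed = 1L) {
  with_substream(seed, "genome", {
    chrom_len <- c(
      chr1 = round(params$genome_length * 0.6),
      chr2 = params$genome_length - round(params$genome_length * 0.6)
    )
    n_genes_chrom <- c(
      chr1 = round(params$n_genes * 0.6),
      chr2 = params$n_genes - round(params$n_genes * 0.6)
    )
    gene_len <- 1800L
    for (ch in names(chrom_len)) {
      if (n_genes_chrom[[ch]] > 0 &&
        chrom_len[[ch]] / n_genes_chrom[[ch]] < gene_len + 100) {
        abort("genome too short for n_genes: enlarge genome_length or reduce n_genes")
      }
    }
    seqs <- lapply(chrom_len, function(L) {
      paste(sample(BASES, L, replace = TRUE), collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(chrom_len)

    models <- simulate_gene_layout(chrom_len, n_genes_chrom, gene_len, params)
    repeats <- simulate_repeat_layout(chrom_len, params)
    list(genome = genome, models = models, repeats = repeats)
  })
}

# Fixed gene architecture, 0-based offsets relative to gene start (+ strand):
#   exon1 [0,300) = UTR5 [0,150) + CDS [150,300)
#   exon2 [700,1000) = CDS
#   exon3 [1400,1800) = CDS [1400,1550) + UTR3 [1550,1800)
# Minus-strand genes mirror the layout within the gene span.
gene_architecture <- function(strand) {
  rel <- list(
    exon = rbind(c(0, 299), c(700, 999), c(1400, 1799)),
    CDS = rbind(c(150, 299), c(700, 999), c(1400, 1549)),
    UTR5 = rbind(c(0, 149)),
    UTR3 = rbind(c(1550, 1799))
  )
  if (strand == "-") {
    rel <- lapply(rel, function(m) {
      r <- cbind(1799 - m[, 2], 1799 - m[, 1])
      r[order(r[, 1]), , drop = FALSE]
    })
  }
  rel
}

simulate_gene_layout <- function(chrom_len, n_genes_chrom, gene_len, params) {
  rows <- list()
  gi <- 0L
  n_total <- sum(n_genes_chrom)
  ncrna_ids <- sample.int(n_total, round(params$ncrna_fraction * n_total))
  essential_ids <- sample.int(n_total, round(params$essential_fraction * n_total))
  for (ch in names(chrom_len)) {
    ng <- n_genes_chrom[[ch]]
    if (ng == 0) next
    slot <- floor(chrom_len[[ch]] / ng)
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      gene_id <- sprintf("g%03d", gi)
      strand <- if (gi %% 2 == 1) "+" else "-"
      s <- (k - 1L) * slot + sample.int(slot - gene_len - 10L, 1)
      coding <- !(gi %in% ncrna_ids)
      rel <- gene_architecture(strand)
      feats <- list(tibble(
        gene_id = gene_id, chrom = ch, strand = strand, feature = "gene",
        start = s + 1L, end = s + gene_len,
        biotype = if (coding) "protein_coding" else "ncRNA"
      ))
      use <- if (coding) c("exon", "CDS", "UTR5", "UTR3") else "exon"
      for (f in use) {
        m <- rel[[f]]
        feats[[length(feats) + 1]] <- tibble(
          gene_id = gene_id, chrom = ch, strand = strand, feature = f,
          start = s + m[, 1] + 1L, end = s + m[, 2] + 1L,
          biotype = if (coding) "protein_coding" else "ncRNA"
        )
      }
      rows[[gi]] <- bind_rows(feats)
    }
  }
  models <- bind_rows(rows)
  gene_ids <- unique(models$gene_id)
  models$essential <- models$gene_id %in% gene_ids[essential_ids]
  models$recoding_eligible <- models$biotype == "protein_coding"
  models
}

simulate_repeat_layout <- function(chrom_len, params) {
  place_family <- function(ch, L, n, len_range, family, occupied) {
    if (n <= 0) {
      return(list(tb = NULL, occupied = occupied))
    }
    out <- list()
    tries <- 0L
    while (length(out) < n && tries < n * 60L) {
      tries <- tries + 1L
      w <- sample(seq(len_range[1], len_range[2]), 1)
      s0 <- sample.int(L - w, 1) - 1L
      iv <- IRanges::IRanges(s0 + 1L, s0 + w)
      if (length(occupied) == 0 ||
        sum(IRanges::countOverlaps(iv, occupied)) == 0) {
        occupied <- c(occupied, iv)
        out[[length(out) + 1]] <- tibble(
          chrom = ch, start = s0, end = s0 + w, family = family
        )
      }
    }
    list(tb = bind_rows(out), occupied = occupied)
  }
  res <- list()
  for (ch in names(chrom_len)) {
    L <- chrom_len[[ch]]
    n_alu <- round(params$alu_fraction_of_genome * L / 300)
    n_other <- round(params$other_repeat_fraction * L / 300)
    occ <- IRanges::IRanges()
    a <- place_family(ch, L, n_alu, c(280, 320), "Alu", occ)
    b <- place_family(ch, L, n_other, c(150, 450),
      sample(c("L1", "MIR"), 1),
      occupied = a$occupied
    )
    res[[ch]] <- bind_rows(a$tb, b$tb)
  }
  bind_rows(res) |> arrange(.data$chrom, .data$start)
}

# per-base table of genic positions with strand-oriented transcript base
# and repeat membership; the implant planner samples from this.
genic_position_table <- function(ann) {
  genes <- ann$models |> filter(.data$feature == "gene")
  chars <- lapply(as.character(ann$genome), function(s) strsplit(s, "")[[1]])
  n_per <- genes$end - genes$start + 1L
  tb <- tibble(
    gene_id = rep(genes$gene_id, n_per),
    chrom = rep(genes$chrom, n_per),
    strand = rep(genes$strand, n_per),
    pos = unlist(purrr::map2(genes$start, genes$end, seq.int))
  )
  tb$base <- NA_character_
  for (ch in unique(tb$chrom)) {
    idx <- tb$chrom == ch
    tb$base[idx] <- chars[[ch]][tb$pos[idx]]
  }
  tb$tbase <- ifelse(tb$strand == "+", tb$base, complement_base(tb$base))
  alu <- ann$repeats |> filter(.data$family == "Alu")
  other <- ann$repeats |> filter(.data$family != "Alu")
  tb$in_alu <- positions_in_intervals(tb$chrom, tb$pos, alu)
  tb$in_other_repeat <- positions_in_intervals(tb$chrom, tb$pos, other)
  tb
}

# 1-based positions against 0-based half-open intervals: s < pos <= e
positions_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end)
  )
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Draw true editing levels
#'
#' Editing levels follow a Beta distribution (right-skewed, mean
#' `shape1/(shape1+shape2)`) clipped to `[edit_level_min, edit_level_max]`.
#'
#' @param n number of levels to draw.
#' @param params a [sim_params()] object.
#' @return numeric vector in (0, 1).
#' @export
draw_edit_levels <- function(n, params = sim_params()) {
  pmin(
    pmax(rbeta(n, params$level_shape1, params$level_shape2), params$edit_level_min),
    params$edit_level_max
  )
}

#' Implant ground-truth editing sites, SNPs and expression structure
#'
#' Chooses genic positions for the implanted editing sites (A-to-I dominated
#' in transcript orientation, Alu-enriched, with case-specific extras so the
#' expected case/control per-sample site-count ratio equals
#' `case_extra_sites_factor`), disjoint germline SNP positions, the
#' differentially expressed gene set, coupled genes (expression co-monotone
#' with editing level; each is guaranteed at least three shared sites) and
#' an ADAR-like gene.
#'
#' @param params a [sim_params()] object.
#' @param ann annotation list from [simulate_genome_annotation()].
#' @param seed integer master seed (same seed, same truth).
#' @return list of class `edit_truth`: `edit_sites`, `snps`, `de_genes`,
#'   `coupled_genes`, `adar_genes`.
#' @export
implant_truth <- function(params, ann, seed = 1L) {
  with_substream(seed, "truth", {
    pos_tbl <- genic_position_table(ann)
    n_shared <- params$n_edit_sites
    n_extra <- as.integer(round((params$case_extra_sites_factor - 1) * n_shared))
    n_total <- n_shared + n_extra

    type_levels <- c("A>G", "T>C", "C>T", "G>A", "A>C")
    rem <- 1 - params$a2i_fraction
    probs <- c(
      params$a2i_fraction,
      rem * c(0.5, 0.25, 0.15, 0.10)
    )
    type <- sample(type_levels, n_total, replace = TRUE, prob = probs)
    in_alu <- runif(n_total) < params$frac_edits_in_alu

    all_genes <- ann$models |>
      filter(.data$feature == "gene") |>
      pull("gene_id")
    coding_genes <- ann$models |>
      filter(.data$feature == "gene", .data$biotype == "protein_coding") |>
      pull("gene_id")
    n_coupled <- min(params$n_coupled_genes, length(coding_genes))
    # coupled genes host guaranteed shared sites: draw them from genes with
    # real Alu content so their sites respect the Alu placement fractions
    alu_rich <- pos_tbl |>
      filter(.data$in_alu) |>
      count(.data$gene_id) |>
      filter(.data$n >= 50) |>
      pull("gene_id")
    coupled_pool <- intersect(coding_genes, alu_rich)
    if (length(coupled_pool) < n_coupled) coupled_pool <- coding_genes
    coupled <- sample(coupled_pool, n_coupled)
    # genes reserved for case-specific editing only, so case-only edited
    # gene sets (the Venn-style analysis) are non-trivial
    reserved <- sample(
      setdiff(all_genes, coupled),
      round(params$case_specific_gene_fraction * length(all_genes))
    )
    forced_gene <- rep(NA_character_, n_total)
    if (n_coupled > 0) {
      k <- 3L * n_coupled
      if (k > n_shared) abort("n_edit_sites too small for coupled-gene allocation")
      forced_gene[seq_len(k)] <- rep(coupled, each = 3L)
    }
    is_extra <- c(rep(FALSE, n_shared), rep(TRUE, n_extra))
    pool_lab <- ifelse(!is_extra, "shared",
      ifelse(runif(n_total) < params$case_specific_in_reserved,
        "reserved", "any"
      )
    )

    chosen <- integer(n_total)
    used <- rep(FALSE, nrow(pos_tbl))
    t_ref <- substr(type, 1, 1)
    pos_reserved <- pos_tbl$gene_id %in% reserved
    # forced rows one by one (few); prefer the drawn Alu flag, fall back
    for (i in which(!is.na(forced_gene))) {
      pool <- which(pos_tbl$gene_id == forced_gene[i] &
        pos_tbl$tbase == t_ref[i] & pos_tbl$in_alu == in_alu[i] & !used)
      if (length(pool) == 0) {
        pool <- which(pos_tbl$gene_id == forced_gene[i] &
          pos_tbl$tbase == t_ref[i] & !used)
      }
      if (length(pool) == 0) abort("no eligible position in coupled gene")
      chosen[i] <- if (length(pool) == 1) pool else sample(pool, 1)
      used[chosen[i]] <- TRUE
    }
    free <- which(is.na(forced_gene))
    for (lab in c("shared", "reserved", "any")) {
      pool_ok <- switch(lab,
        shared = !pos_reserved,
        reserved = pos_reserved,
        any = rep(TRUE, nrow(pos_tbl))
      )
      for (r in BASES) {
        for (a in c(TRUE, FALSE)) {
          rows <- free[t_ref[free] == r & in_alu[free] == a &
            pool_lab[free] == lab]
          if (length(rows) == 0) next
          pool <- which(pos_tbl$tbase == r & pos_tbl$in_alu == a &
            pool_ok & !used)
          if (length(pool) < length(rows)) {
            pool <- union(pool, which(pos_tbl$tbase == r & pool_ok & !used))
          }
          if (length(pool) < length(rows)) {
            pool <- union(pool, which(pos_tbl$tbase == r & !used))
          }
          if (length(pool) < length(rows)) {
            abort("not enough eligible genic positions")
          }
          take <- if (length(pool) == 1) pool else sample(pool, length(rows))
          chosen[rows] <- take
          used[take] <- TRUE
        }
      }
    }

    picked <- pos_tbl[chosen, ]
    t_alt <- substr(type, 3, 3)
    edit_sites <- tibble(
      chrom = picked$chrom,
      pos = picked$pos,
      gene_id = picked$gene_id,
      strand = picked$strand,
      transcript_change = type,
      g_ref = picked$base,
      g_alt = as.character(ifelse(picked$strand == "+", t_alt,
        complement_base(t_alt)
      )),
      in_alu = picked$in_alu,
      true_level = draw_edit_levels(n_total, params),
      group_specific = c(rep(FALSE, n_shared), rep(TRUE, n_extra))
    ) |> arrange(.data$chrom, .data$pos)

    snps <- implant_snps(params, ann, edit_sites)
    background <- sample_free_positions(
      params$n_background_sites, ann,
      c(
        paste(edit_sites$chrom, edit_sites$pos),
        paste(snps$chrom, snps$pos)
      )
    )

    pool_de <- setdiff(coding_genes, coupled)
    adar <- sample(pool_de, 1)
    pool_de <- setdiff(pool_de, adar)
    n_de <- min(params$n_de_genes, length(pool_de))
    de_ids <- sample(pool_de, n_de)
    de_genes <- tibble(
      gene_id = de_ids,
      true_log2fc = rep_len(c(1, -1), n_de) * params$de_log2fc
    )

    structure(
      list(
        edit_sites = edit_sites, snps = snps, background = background,
        de_genes = de_genes, coupled_genes = coupled, adar_genes = adar
      ),
      class = "edit_truth"
    )
  })
}

# sample n genome positions (with reference base) avoiding taken keys
sample_free_positions <- function(n, ann, taken) {
  if (n <= 0) {
    return(tibble(chrom = character(0), pos = integer(0), ref = character(0)))
  }
  chrom_len <- Biostrings::width(ann$genome)
  names(chrom_len) <- names(ann$genome)
  chars <- lapply(as.character(ann$genome), function(s) strsplit(s, "")[[1]])
  out <- list()
  need <- n
  while (need > 0) {
    ch <- sample(names(chrom_len), need, replace = TRUE,
      prob = chrom_len / sum(chrom_len)
    )
    p <- vapply(ch, function(c2) sample.int(chrom_len[[c2]], 1), integer(1))
    cand <- tibble(chrom = ch, pos = as.integer(p)) |>
      distinct() |>
      filter(!paste(.data$chrom, .data$pos) %in% taken)
    out[[length(out) + 1]] <- cand
    taken <- c(taken, paste(cand$chrom, cand$pos))
    need <- n - sum(vapply(out, nrow, integer(1)))
  }
  res <- bind_rows(out) |> utils::head(n)
  res$ref <- NA_character_
  for (ch in unique(res$chrom)) {
    idx <- res$chrom == ch
    res$ref[idx] <- chars[[ch]][res$pos[idx]]
  }
  res |> arrange(.data$chrom, .data$pos)
}

implant_snps <- function(params, ann, edit_sites) {
  taken <- paste(edit_sites$chrom, edit_sites$pos)
  snps <- sample_free_positions(params$n_snps, ann, taken)
  snps$alt <- vapply(snps$ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  snps$genotype <- sample(c("het", "hom_alt"), nrow(snps),
    replace = TRUE, prob = c(0.6, 0.4)
  )
  snps
}

#' Build known-SNP and known-editing catalogs from the implanted truth
#'
#' A configurable fraction of implanted editing sites (default half) is
#' copied into the known-editing catalog alongside decoy entries, so the
#' expected catalog-overlap fraction of called sites is controllable.
#' Likewise a fraction of implanted SNP positions enters the known-SNP
#' catalog; the remainder must be caught by matched-DNA subtraction.
#'
#' @param truth an `edit_truth` object from [implant_truth()].
#' @param ann annotation list from [simulate_genome_annotation()].
#' @param params a [sim_params()] object.
#' @param seed integer master seed.
#' @param n_decoys decoy entries per catalog.
#' @return list with `known_edits` and `known_snps` tibbles.
#' @export
build_catalogs <- function(truth, ann, params, seed = 1L, n_decoys = 200L) {
  with_substream(seed, "catalogs", {
    pos_tbl <- genic_position_table(ann)
    taken <- paste(truth$edit_sites$chrom, truth$edit_sites$pos)
    taken <- c(taken, paste(truth$snps$chrom, truth$snps$pos))

    in_cat <- runif(nrow(truth$edit_sites)) < params$known_edit_overlap
    decoy_pool <- pos_tbl |>
      filter(.data$tbase == "A", !paste(.data$chrom, .data$pos) %in% taken)
    decoys <- decoy_pool[sample.int(nrow(decoy_pool), min(n_decoys, nrow(decoy_pool))), ]
    # a known-editing database covers plausible sites genome-wide at the
    # configured rate, whether or not this cohort edits them: the assayed
    # background panel enters the catalog at the same rate
    in_cat_bg <- runif(nrow(truth$background)) < params$known_edit_overlap
    canonical_alt <- c(A = "G", T = "C", C = "T", G = "A")
    known_edits <- bind_rows(
      truth$edit_sites[in_cat, ] |>
        transmute(.data$chrom, .data$pos,
          ref = .data$g_ref, alt = .data$g_alt, strand = .data$strand
        ),
      truth$background[in_cat_bg, ] |>
        transmute(.data$chrom, .data$pos,
          ref = .data$ref, alt = unname(canonical_alt[.data$ref]),
          strand = "."
        ),
      decoys |>
        transmute(.data$chrom, .data$pos,
          ref = .data$base,
          alt = ifelse(.data$strand == "+", "G", "C"), strand = .data$strand
        )
    ) |> arrange(.data$chrom, .data$pos)

    snp_in_cat <- runif(nrow(truth$snps)) < params$known_snp_overlap
    chrom_len <- Biostrings::width(ann$genome)
    names(chrom_len) <- names(ann$genome)
    dch <- sample(names(chrom_len), n_decoys, replace = TRUE)
    dpos <- vapply(dch, function(c2) sample.int(chrom_len[[c2]], 1), integer(1))
    snp_decoys <- tibble(chrom = dch, pos = as.integer(dpos)) |>
      filter(!paste(.data$chrom, .data$pos) %in% taken) |>
      distinct()
    known_snps <- bind_rows(
      truth$snps[snp_in_cat, c("chrom", "pos")],
      snp_decoys
    ) |>
      distinct() |>
      arrange(.data$chrom, .data$pos)
    list(known_edits = known_edits, known_snps = known_snps)
  })
}

#' Per-sample latent editing state
#'
#' Draws each sample's editing propensity multiplier (uniform over
#' `sample_propensity_range`) and tabulates its implanted site count
#' (shared sites plus, for case samples, the case-specific extras). Both
#' the pileup and the count simulators consume this table, which is what
#' couples ADAR-like expression and coupled-gene expression to editing.
#'
#' @param samples sample sheet tibble.
#' @param truth an `edit_truth` object.
#' @param params a [sim_params()] object.
#' @param seed integer master seed.
#' @return tibble: `sample_id`, `group`, `tissue`, `m_edit`, `n_implanted`.
#' @export
draw_sample_truth <- function(samples, truth, params, seed = 1L) {
  with_substream(seed, "sample-truth", {
    validate_sample_sheet(samples)
    n_shared <- sum(!truth$edit_sites$group_specific)
    n_extra <- sum(truth$edit_sites$group_specific)
    samples |>
      arrange(.data$sample_id) |>
      mutate(
        m_edit = runif(
          n(), params$sample_propensity_range[1],
          params$sample_propensity_range[2]
        ),
        n_implanted = n_shared + ifelse(.data$group == "case", n_extra, 0L)
      ) |>
      select("sample_id", "group", "tissue", "m_edit", "n_implanted")
  })
}

#' Simulate RNA site pileups and matched DNA genotypes
#'
#' Emits one pileup record per sample per site of the assayed universe
#' (implanted editing sites, implanted SNPs, and a random non-edited
#' background panel). At editing sites the alternative read count is
#' binomial in the sample-adjusted true editing level while DNA stays
#' hom-ref; at SNPs both DNA genotype and RNA allele fraction reflect the
#' genotype dosage; elsewhere only sequencing error produces mismatches.
#' Depths are Poisson. DNA genotype records (including hom-ref, so the
#' caller can verify coverage) carry GT:GQ:DP; a small fraction of variant
#' records get genotype quality below 30.
#'
#' @param truth an `edit_truth` object.
#' @param samples sample sheet tibble.
#' @param params a [sim_params()] object.
#' @param ann annotation list (needed for background-site reference bases).
#' @param seed integer master seed.
#' @return list with `pileups` (tibble) and `dna_records` (long tibble for
#'   [write_dna_vcf()]).
#' @export
simulate_pileups <- function(truth, samples, params, ann, seed = 1L) {
  st <- draw_sample_truth(samples, truth, params, seed)
  with_substream(seed, "pileups", {
    uni <- bind_rows(
      truth$edit_sites |>
        transmute(.data$chrom, .data$pos,
          ref = .data$g_ref, alt = .data$g_alt,
          kind = "edit", level = .data$true_level,
          group_specific = .data$group_specific, dosage = NA_real_
        ),
      truth$snps |>
        transmute(.data$chrom, .data$pos, .data$ref, .data$alt,
          kind = "snp", level = NA_real_, group_specific = FALSE,
          dosage = ifelse(.data$genotype == "het", 0.5, 1.0)
        )
    )
    bg <- truth$background |> mutate(
      alt = NA_character_, kind = "background", level = NA_real_,
      group_specific = FALSE, dosage = NA_real_
    )
    uni <- bind_rows(uni, bg) |> arrange(.data$chrom, .data$pos)

    e <- params$seq_error_rate
    snp_genotype <- truth$snps$genotype[match(
      paste(uni$chrom, uni$pos),
      paste(truth$snps$chrom, truth$snps$pos)
    )]

    pile <- list()
    dna <- list()
    for (i in seq_len(nrow(st))) {
      s <- st$sample_id[i]
      is_case <- st$group[i] == "case"
      m <- st$m_edit[i]
      f <- rep(0, nrow(uni))
      is_edit <- uni$kind == "edit" & (!uni$group_specific | is_case)
      f[is_edit] <- pmin(uni$level[is_edit] * m, 0.98)
      is_snp <- uni$kind == "snp"
      f[is_snp] <- uni$dosage[is_snp]

      depth <- rpois(nrow(uni), params$mean_rna_depth)
      cm <- sample_base_counts(depth, uni$ref, uni$alt, f, e)
      pile[[s]] <- tibble(
        sample_id = s, chrom = uni$chrom, pos = uni$pos, ref = uni$ref,
        count_A = cm[, "A"], count_C = cm[, "C"],
        count_G = cm[, "G"], count_T = cm[, "T"]
      )

      dna_depth <- rpois(nrow(uni), params$mean_dna_depth)
      gt <- rep("0/0", nrow(uni))
      gt[is_snp] <- ifelse(snp_genotype[is_snp] == "het", "0/1", "1/1")
      gq <- rep(99L, nrow(uni))
      low <- is_snp & runif(nrow(uni)) < params$low_gq_fraction
      gq[low] <- sample(5:29, sum(low), replace = TRUE)
      dna[[s]] <- tibble(
        chrom = uni$chrom, pos = uni$pos, ref = uni$ref,
        alt = ifelse(uni$kind == "snp", uni$alt, NA_character_),
        qual = 100, sample_id = s, gt = gt, gq = gq, dna_depth = dna_depth
      )
    }
    list(
      pileups = bind_rows(pile) |>
        mutate(depth = .data$count_A + .data$count_C + .data$count_G + .data$count_T),
      dna_records = bind_rows(dna)
    )
  })
}

# exact multinomial read counts over A/C/G/T via sequential binomial
# splitting (vectorised over sites): alt fraction f, error rate e spread
# uniformly over the three wrong bases.
sample_base_counts <- function(depth, ref, alt, f, e) {
  n <- length(depth)
  p <- matrix(0, n, 4, dimnames = list(NULL, BASES))
  for (b in BASES) {
    p_ref <- ifelse(ref == b, 1 - e, e / 3)
    p_alt <- ifelse(!is.na(alt) & alt == b, 1 - e, e / 3)
    p[, b] <- (1 - f) * p_ref + ifelse(is.na(alt), 0, f) * p_alt
  }
  # when alt is NA, f is 0 by construction; renormalise defensively
  p <- p / rowSums(p)
  out <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  rem_n <- depth
  rem_p <- rep(1, n)
  for (j in 1:3) {
    pj <- pmin(pmax(p[, j] / rem_p, 0), 1)
    pj[rem_p <= 0] <- 0
    out[, j] <- rbinom(n, rem_n, pj)
    rem_n <- rem_n - out[, j]
    rem_p <- rem_p - p[, j]
  }
  out[, 4] <- rem_n
  out
}

#' Simulate a negative-binomial gene count matrix
#'
#' Counts are NB-distributed around per-gene log-normal baseline means with
#' per-sample library-size factors. Implanted differentially expressed genes
#' have case means shifted by `2^true_log2fc`; the ADAR-like gene's mean is
#' proportional to the sample's implanted editing-site count; coupled genes'
#' means increase monotonically with the sample's editing propensity, so
#' editing level and expression co-vary.
#'
#' @param truth an `edit_truth` object (or minimal truth from
#'   [make_de_truth()]).
#' @param samples sample sheet tibble.
#' @param params a [sim_params()] object.
#' @param models gene-model tibble (supplies gene ids and exonic lengths).
#' @param seed integer master seed.
#' @return tibble: `gene_id` plus one integer column per sample.
#' @export
simulate_counts <- function(truth, samples, params, models, seed = 1L) {
  st <- draw_sample_truth(samples, truth, params, seed)
  with_substream(seed, "counts", {
    genes <- gene_lengths(models)
    ng <- nrow(genes)
    base_mean <- rlnorm(ng, meanlog = log(params$mean_counts), sdlog = 0.8)
    lib <- runif(nrow(st), 0.7, 1.3)

    lfc <- setNames(rep(0, ng), genes$gene_id)
    if (nrow(truth$de_genes) > 0) {
      lfc[truth$de_genes$gene_id] <- truth$de_genes$true_log2fc
    }
    mean_sites <- mean(st$n_implanted)
    mu <- matrix(0, ng, nrow(st), dimnames = list(genes$gene_id, st$sample_id))
    for (i in seq_len(nrow(st))) {
      m <- setNames(base_mean * lib[i], genes$gene_id)
      if (st$group[i] == "case") m <- m * 2^lfc
      if (length(truth$adar_genes) > 0 && mean_sites > 0) {
        m[truth$adar_genes] <- m[truth$adar_genes] *
          (st$n_implanted[i] / mean_sites)
      }
      if (length(truth$coupled_genes) > 0) {
        m[truth$coupled_genes] <- m[truth$coupled_genes] * st$m_edit[i]^2
      }
      mu[, i] <- m
    }
    cnt <- if (params$nb_dispersion <= 0) {
      matrix(rpois(length(mu), lambda = mu), nrow = ng)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion),
        nrow = ng
      )
    }
    dimnames(cnt) <- dimnames(mu)
    bind_cols(tibble(gene_id = genes$gene_id), as_tibble(cnt))
  })
}

#' Exonic gene lengths from a gene-model table
#' @param models gene-model tibble.
#' @return tibble: `gene_id`, `length_bp` (union of exons).
#' @export
gene_lengths <- function(models) {
  ex <- models |> filter(.data$feature == "exon")
  if (nrow(ex) == 0) ex <- models |> filter(.data$feature == "gene")
  ex |>
    group_by(.data$gene_id) |>
    summarise(
      length_bp = {
        iv <- IRanges::reduce(IRanges::IRanges(.data$start, .data$end))
        sum(IRanges::width(iv))
      },
      .groups = "drop"
    )
}

#' Minimal ground truth for expression-only simulations
#'
#' Builds a gene universe and an implanted differential-expression truth
#' without any editing structure, for benchmarking the NB Wald test on its
#' own.
#'
#' @param n_genes genes in the matrix.
#' @param n_de implanted differentially expressed genes.
#' @param log2fc absolute implanted log2 fold change (half up, half down).
#' @param seed integer seed.
#' @param gene_length_bp constant exonic length used for FPKM.
#' @return list with `truth` (class `edit_truth`) and `models`.
#' @export
make_de_truth <- function(n_genes = 1000L, n_de = 50L, log2fc = 2,
                          seed = 1L, gene_length_bp = 1500L) {
  with_substream(seed, "de-truth", {
    ids <- sprintf("g%04d", seq_len(n_genes))
    de_ids <- sample(ids, n_de)
    truth <- structure(
      list(
        edit_sites = tibble(
          chrom = character(0), pos = integer(0), gene_id = character(0),
          strand = character(0), transcript_change = character(0),
          g_ref = character(0), g_alt = character(0), in_alu = logical(0),
          true_level = numeric(0), group_specific = logical(0)
        ),
        snps = tibble(
          chrom = character(0), pos = integer(0), ref = character(0),
          alt = character(0), genotype = character(0)
        ),
        background = tibble(
          chrom = character(0), pos = integer(0), ref = character(0)
        ),
        de_genes = tibble(
          gene_id = de_ids,
          true_log2fc = rep_len(c(1, -1), n_de) * log2fc
        ),
        coupled_genes = character(0),
        adar_genes = character(0)
      ),
      class = "edit_truth"
    )
    models <- tibble(
      gene_id = rep(ids, each = 2),
      chrom = "chr1", strand = "+",
      feature = rep(c("gene", "exon"), n_genes),
      start = 1L, end = gene_length_bp,
      biotype = "protein_coding", essential = FALSE, recoding_eligible = TRUE
    )
    list(truth = truth, models = models)
  })
}

#' Two-group sample sheet without tissue pairing
#'
#' Convenience sheet for expression-only simulations (one tissue).
#'
#' @param n_case,n_control samples per group.
#' @return sample sheet tibble.
#' @export
de_sample_sheet <- function(n_case = 5L, n_control = 5L) {
  tibble(
    sample_id = c(
      sprintf("case%02d_sub", seq_len(n_case)),
      sprintf("ctrl%02d_sub", seq_len(n_control))
    ),
    subject_id = c(
      sprintf("case%02d", seq_len(n_case)),
      sprintf("ctrl%02d", seq_len(n_control))
    ),
    group = rep(c("case", "control"), c(n_case, n_control)),
    tissue = "subcutaneous"
  )
}

#' Synthetic gene-set catalog with planted terms
#'
#' Builds decoy terms of random genes plus planted terms drawn mostly from
#' a given gene set (e.g. genes carrying case-specific editing), so that
#' over-representation analysis has a recoverable positive control.
#'
#' @param gene_ids universe of gene ids.
#' @param planted_genes genes to concentrate in the planted terms.
#' @param n_terms number of decoy terms.
#' @param n_planted number of planted terms.
#' @param seed integer seed.
#' @return tibble: `term_id`, `term_name`, `gene_id` (long form).
#' @export
make_geneset_catalog <- function(gene_ids, planted_genes = character(0),
                                 n_terms = 50L, n_planted = 2L, seed = 1L) {
  with_substream(seed, "genesets", {
    out <- list()
    for (k in seq_len(n_terms)) {
      size <- sample(10:min(40, length(gene_ids)), 1)
      out[[k]] <- tibble(
        term_id = sprintf("TERM%03d", k),
        term_name = sprintf("decoy process %03d", k),
        gene_id = sample(gene_ids, size)
      )
    }
    if (length(planted_genes) >= 5) {
      for (k in seq_len(n_planted)) {
        core <- sample(planted_genes, min(12, length(planted_genes)))
        pad <- sample(setdiff(gene_ids, core), 4)
        out[[n_terms + k]] <- tibble(
          term_id = sprintf("PLANT%02d", k),
          term_name = sprintf("immune-like planted process %02d", k),
          gene_id = c(core, pad)
        )
      }
    }
    bind_rows(out) |> distinct()
  })
}

#' Simulate the full synthetic study
#'
#' Runs genome/annotation simulation, truth implantation, catalog
#' construction, pileup/DNA simulation and count simulation with one master
#' seed; optionally writes every input file (FASTA, GTF, BED, VCF, TSVs)
#' plus a `truth/` subfolder to `out_dir`.
#'
#' @param params a [sim_params()] object.
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return list with `ann`, `truth`, `catalogs`, `samples`, `sample_truth`,
#'   `pileups`, `dna_records`, `counts`, `genesets` and (when written)
#'   `files`.
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1L, out_dir = NULL) {
  ann <- simulate_genome_annotation(params, seed)
  truth <- implant_truth(params, ann, seed)
  catalogs <- build_catalogs(truth, ann, params, seed)
  samples <- sample_sheet(params)
  st <- draw_sample_truth(samples, truth, params, seed)
  pp <- simulate_pileups(truth, samples, params, ann, seed)
  counts <- simulate_counts(truth, samples, params, ann$models, seed)
  spec_genes <- setdiff(
    unique(truth$edit_sites$gene_id[truth$edit_sites$group_specific]),
    unique(truth$edit_sites$gene_id[!truth$edit_sites$group_specific])
  )
  genesets <- make_geneset_catalog(
    unique(ann$models$gene_id),
    planted_genes = spec_genes, seed = seed
  )
  res <- list(
    ann = ann, truth = truth, catalogs = catalogs, samples = samples,
    sample_truth = st, pileups = pp$pileups, dna_records = pp$dna_records,
    counts = counts, genesets = genesets
  )
  if (!is.null(out_dir)) {
    res$files <- write_dataset(res, out_dir)
  }
  res
}

write_dataset <- function(res, out_dir) {
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE, recursive = TRUE)
  f <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "genes.gtf"),
    repeats = file.path(out_dir, "repeats.bed"),
    known_snps = file.path(out_dir, "known_snps.tsv"),
    known_edits = file.path(out_dir, "known_edits.tsv"),
    essential = file.path(out_dir, "essential_genes.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    pileups = file.path(out_dir, "rna_pileups.tsv"),
    dna_vcf = file.path(out_dir, "dna_genotypes.vcf"),
    counts = file.path(out_dir, "gene_counts.tsv"),
    genesets = file.path(out_dir, "genesets.tsv")
  )
  Biostrings::writeXStringSet(res$ann$genome, f$genome)
  write_gene_models_gtf(res$ann$models, f$gtf)
  write_repeats_bed(res$ann$repeats, f$repeats)
  write_site_catalog(res$catalogs$known_snps, f$known_snps)
  write_site_catalog(res$catalogs$known_edits, f$known_edits)
  ess <- res$ann$models |>
    filter(.data$feature == "gene", .data$essential) |>
    select("gene_id")
  readr::write_tsv(ess, f$essential, progress = FALSE)
  readr::write_tsv(res$samples, f$samples, progress = FALSE)
  write_site_pileups(res$pileups, f$pileups)
  write_dna_vcf(res$dna_records, f$dna_vcf)
  write_count_matrix(res$counts, f$counts)
  readr::write_tsv(res$genesets, f$genesets, progress = FALSE)
  readr::write_tsv(res$truth$edit_sites,
    file.path(out_dir, "truth", "edit_sites.tsv"),
    progress = FALSE
  )
  readr::write_tsv(res$truth$snps, file.path(out_dir, "truth", "snps.tsv"),
    progress = FALSE
  )
  readr::write_tsv(res$truth$de_genes,
    file.path(out_dir, "truth", "de_genes.tsv"),
    progress = FALSE
  )
  readr::write_tsv(res$sample_truth,
    file.path(out_dir, "truth", "sample_truth.tsv"),
    progress = FALSE
  )
  f
}
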