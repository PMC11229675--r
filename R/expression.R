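counts_to_matrix <- function(counts) {
  assert_columns(counts, "gene_id", "count matrix")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' FPKM expression values
#'
#' `fpkm[g, s] = counts[g, s] / (length_kb[g] * total_counts[s] / 1e6)`:
#' fragments per kilobase of exonic gene length per million assigned
#' fragments. FPKM is invariant to uniform scaling of one sample's counts
#' because the library total rescales with it.
#'
#' @param counts count tibble (`gene_id` + sample columns).
#' @param lengths tibble from [gene_lengths()] (`gene_id`, `length_bp`).
#' @return tibble of the same shape with FPKM values.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 100L)
#' compute_fpkm(counts, tibble::tibble(gene_id = "g1", length_bp = 1000L))
compute_fpkm <- function(counts, lengths) {
  m <- counts_to_matrix(counts)
  len <- lengths$length_bp[match(rownames(m), lengths$gene_id)]
  if (any(is.na(len)) || any(len <= 0)) {
    abort("every gene needs a positive exonic length")
  }
  lib <- colSums(m)
  if (any(lib == 0)) abort("zero library size in count matrix")
  f <- sweep(m, 1, len / 1000, "/")
  f <- sweep(f, 2, lib / 1e6, "/")
  bind_cols(tibble(gene_id = rownames(m)), as_tibble(f))
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: per sample, the median ratio of its counts to
#' the geometric-mean pseudo-reference, computed over genes with nonzero
#' counts in every sample.
#'
#' @param counts count tibble.
#' @return named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    abort("no gene with nonzero counts in all samples; consider a pseudocount")
  }
  ref <- exp(rowMeans(log(m[allpos, , drop = FALSE])))
  apply(m[allpos, , drop = FALSE], 2, function(col) median(col / ref))
}

# moment dispersion with mild shrinkage toward the cohort trend and a floor
estimate_dispersions <- function(norm, group_idx, floor = 1e-8, prior_n = 4) {
  per_group <- lapply(group_idx, function(ix) {
    mu <- rowMeans(norm[, ix, drop = FALSE])
    v <- apply(norm[, ix, drop = FALSE], 1, var)
    list(mu = mu, v = v, n = length(ix))
  })
  # pooled within-group moments
  mu_bar <- rowMeans(do.call(cbind, lapply(per_group, `[[`, "mu")))
  v_bar <- rowMeans(do.call(cbind, lapply(per_group, `[[`, "v")))
  raw <- (v_bar - mu_bar) / mu_bar^2
  raw[!is.finite(raw)] <- floor
  raw <- pmax(raw, floor)
  trend <- median(raw[mu_bar > quantile(mu_bar, 0.25)])
  if (!is.finite(trend)) trend <- median(raw)
  n_eff <- sum(vapply(per_group, `[[`, numeric(1), "n")) - 2
  disp <- (n_eff * raw + prior_n * trend) / (n_eff + prior_n)
  pmax(disp, floor)
}

#' Negative-binomial Wald differential expression
#'
#' A transparent moments-based NB test: size-factor normalisation
#' (median-of-ratios), per-gene method-of-moments dispersion with shrinkage
#' toward the cohort trend (floor 1e-8), log2 fold change of group means
#' with a stabilising pseudocount, a delta-method Wald standard error from
#' the NB variance function, two-sided normal p-values and BH adjustment.
#' Significance requires both `padj <= de_padj_max` and
#' `|log2fc| >= de_abs_log2fc_min`.
#'
#' @param counts count tibble.
#' @param samples sample sheet tibble.
#' @param contrast length-3 character: metadata column, numerator level,
#'   denominator level, e.g. `c("group", "case", "control")`.
#' @param cfg an [edit_config()] object.
#' @param pseudocount added to normalised group means before the log ratio.
#' @return tibble of class `edit_de`: `gene_id`, `base_mean`, `log2fc`,
#'   `se`, `wald_p`, `padj`, `significant` (all-zero genes are excluded).
#' @export
nb_wald_de <- function(counts, samples, contrast = c("group", "case", "control"),
                       cfg = edit_config(), pseudocount = 0.5) {
  stopifnot(length(contrast) == 3)
  assert_columns(samples, c("sample_id", contrast[1]), "sample sheet")
  m <- counts_to_matrix(counts)
  keep_samples <- samples$sample_id[samples[[contrast[1]]] %in% contrast[2:3]]
  m <- m[, intersect(colnames(m), keep_samples), drop = FALSE]
  lvl <- samples[[contrast[1]]][match(colnames(m), samples$sample_id)]
  ixA <- which(lvl == contrast[2])
  ixB <- which(lvl == contrast[3])
  if (length(ixA) < 2 || length(ixB) < 2) {
    abort("need at least 2 samples per contrast level")
  }
  nonzero <- rowSums(m) > 0
  if (any(!nonzero)) {
    inform(sprintf("%d all-zero gene(s) excluded", sum(!nonzero)))
  }
  m <- m[nonzero, , drop = FALSE]
  sf <- size_factors(bind_cols(
    tibble(gene_id = rownames(m)),
    as_tibble(m)
  ))
  norm <- sweep(m, 2, sf, "/")
  disp <- estimate_dispersions(norm, list(ixA, ixB))
  mA <- rowMeans(norm[, ixA, drop = FALSE])
  mB <- rowMeans(norm[, ixB, drop = FALSE])
  lfc <- log2((mA + pseudocount) / (mB + pseudocount))
  vA <- (mA + disp * mA^2) / length(ixA)
  vB <- (mB + disp * mB^2) / length(ixB)
  se <- sqrt((vA / (mA + pseudocount)^2 + vB / (mB + pseudocount)^2)) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  padj <- bh_adjust(p)
  out <- tibble(
    gene_id = rownames(m),
    base_mean = unname((mA + mB) / 2),
    log2fc = unname(lfc),
    se = unname(se),
    wald_p = unname(p),
    padj = unname(padj),
    significant = unname(padj <= cfg$de_padj_max &
      abs(lfc) >= cfg$de_abs_log2fc_min)
  )
  class(out) <- c("edit_de", class(out))
  attr(out, "contrast") <- contrast
  out
}

#' Recovery of implanted differential expression
#'
#' @param de an `edit_de` result.
#' @param truth an `edit_truth` object with `de_genes`.
#' @return one-row tibble: `sensitivity`, `empirical_fdr`,
#'   `sign_recovery` (fraction of detected true genes with the implanted
#'   fold-change sign), `n_significant`.
#' @export
de_recovery <- function(de, truth) {
  true_ids <- truth$de_genes$gene_id
  sig <- de |> filter(.data$significant)
  hits <- sig |> filter(.data$gene_id %in% true_ids)
  signs <- truth$de_genes$true_log2fc[match(hits$gene_id, true_ids)]
  tibble(
    sensitivity = if (length(true_ids) == 0) NA_real_ else {
      mean(true_ids %in% sig$gene_id)
    },
    empirical_fdr = if (nrow(sig) == 0) 0 else {
      mean(!sig$gene_id %in% true_ids)
    },
    sign_recovery = if (nrow(hits) == 0) NA_real_ else {
      mean(sign(hits$log2fc) == sign(signs))
    },
    n_significant = nrow(sig)
  )
}

#' PLS-DA by NIPALS
#'
#' Supervised projection of log-scale expression onto components that
#' separate labelled groups: NIPALS partial least squares against a
#' one-hot (dummy-coded) class response. Features are log2(FPKM + 1)
#' transformed and mean-centred; constant feature matrices are an error;
#' requesting more components than the matrix rank truncates with a
#' message.
#'
#' @param fpkm FPKM tibble (`gene_id` + sample columns).
#' @param samples sample sheet tibble.
#' @param class_col metadata column holding the class labels.
#' @param n_components components to extract (default 2).
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @return object of class `edit_plsda`: `scores` tibble, `loadings`
#'   matrix, `explained_variance` (fraction of X variance per component).
#' @export
pls_da <- function(fpkm, samples, class_col = "group", n_components = 2L,
                   log_transform = TRUE) {
  m <- counts_to_matrix(fpkm)
  x <- t(if (log_transform) log2(m + 1) else m) # samples x genes
  cls <- samples[[class_col]][match(rownames(x), samples$sample_id)]
  if (any(is.na(cls))) abort("every sample column needs a class label")
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) abort("constant feature matrix: PLS-DA undefined")
  y <- stats::model.matrix(~ 0 + factor(cls))
  colnames(y) <- levels(factor(cls))
  y <- scale(y, center = TRUE, scale = FALSE)
  max_rank <- qr(x)$rank
  if (n_components > max_rank) {
    inform(sprintf(
      "n_components truncated from %d to matrix rank %d", n_components, max_rank
    ))
    n_components <- max_rank
  }
  ss_x <- sum(x^2)
  n <- nrow(x)
  scores <- matrix(0, n, n_components)
  loads <- matrix(0, ncol(x), n_components)
  expl <- numeric(n_components)
  xr <- x
  yr <- y
  for (a in seq_len(n_components)) {
    u <- yr[, which.max(colSums(yr^2))]
    for (it in 1:500) {
      w <- crossprod(xr, u)
      w <- w / sqrt(sum(w^2))
      t_new <- xr %*% w
      q <- crossprod(yr, t_new) / sum(t_new^2)
      u_new <- yr %*% q / sum(q^2)
      if (sqrt(sum((u_new - u)^2)) < 1e-10 * (1 + sqrt(sum(u^2)))) {
        u <- u_new
        break
      }
      u <- u_new
    }
    t_a <- xr %*% w
    p_a <- crossprod(xr, t_a) / sum(t_a^2)
    xr <- xr - t_a %*% t(p_a)
    yr <- yr - t_a %*% t(crossprod(yr, t_a) / sum(t_a^2))
    scores[, a] <- t_a
    loads[, a] <- p_a
    expl[a] <- sum(t_a^2) * sum(p_a^2) / ss_x
  }
  structure(
    list(
      scores = tibble(
        sample_id = rownames(x),
        class = as.character(cls)
      ) |>
        bind_cols(as_tibble(scores, .name_repair = ~ paste0("comp", seq_len(n_components)))),
      loadings = loads,
      explained_variance = expl,
      n_components = n_components
    ),
    class = "edit_plsda"
  )
}
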