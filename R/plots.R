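#' Volcano plot of a differential-expression result
#'
#' @param object an `edit_de` result from [nb_wald_de()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot edit_de
#' @export
autoplot.edit_de <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$log2fc, -log10(pmax(.data$padj, 1e-300)),
      colour = .data$significant
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p",
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}

#' Score plot of a PLS-DA fit
#'
#' @param object an `edit_plsda` object from [pls_da()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot edit_plsda
#' @export
autoplot.edit_plsda <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(.data$comp1, .data$comp2, colour = .data$class)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("Component 1 (%.1f%% X var)", 100 * object$explained_variance[1]),
      y = if (object$n_components >= 2) {
        sprintf("Component 2 (%.1f%% X var)", 100 * object$explained_variance[2])
      } else {
        "Component 2"
      }
    ) +
    ggplot2::theme_minimal()
}

#' Editing-type distribution bar chart
#'
#' Number of called sites per nucleotide change (transcript orientation),
#' split by group and tissue when a sample sheet is given.
#'
#' @param sites annotated site tibble.
#' @param samples optional sample sheet for condition facets.
#' @return a ggplot object.
#' @export
plot_type_distribution <- function(sites, samples = NULL) {
  if (!is.null(samples)) {
    sites <- sites |>
      left_join(samples |> select("sample_id", "group", "tissue"),
        by = "sample_id"
      )
  }
  p <- ggplot2::ggplot(sites, ggplot2::aes(.data$transcript_change)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "nucleotide change (transcript strand)", y = "edits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(samples)) {
    p <- p + ggplot2::facet_grid(group ~ tissue)
  }
  p
}

#' Genic-region distribution of called sites
#'
#' @inheritParams plot_type_distribution
#' @return a ggplot object.
#' @export
plot_region_distribution <- function(sites, samples = NULL) {
  sites$region <- factor(sites$region, levels = REGION_LEVELS)
  if (!is.null(samples)) {
    sites <- sites |>
      left_join(samples |> select("sample_id", "group", "tissue"),
        by = "sample_id"
      )
  }
  p <- ggplot2::ggplot(sites, ggplot2::aes(.data$region)) +
    ggplot2::geom_bar(fill = "darkseagreen4") +
    ggplot2::labs(x = "region", y = "edits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(samples)) p <- p + ggplot2::facet_grid(group ~ tissue)
  p
}

#' Repeat-class fractions per condition
#'
#' @param alu result of [alu_proportion()].
#' @return a ggplot object.
#' @export
plot_alu_fraction <- function(alu) {
  long <- alu$per_condition |>
    pivot_longer(
      cols = c("frac_alu", "frac_non_alu_repeat", "frac_nonrepetitive"),
      names_to = "class", values_to = "fraction"
    )
  ggplot2::ggplot(
    long,
    ggplot2::aes(paste(.data$group, .data$tissue, sep = "\n"),
      .data$fraction,
      fill = .data$class
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of called sites", fill = NULL) +
    ggplot2::theme_minimal()
}
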