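#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#'
#' @param x an `edit_de` result.
#' @param ... unused.
#' @return plain tibble of per-gene estimates.
#' @method tidy edit_de
#' @export
tidy.edit_de <- function(x, ...) {
  as_tibble(x) |> arrange(.data$padj, .data$wald_p)
}

#' One-row summary of a differential-expression result
#'
#' @param x an `edit_de` result.
#' @param ... unused.
#' @return tibble: gene totals, significant calls and contrast.
#' @method glance edit_de
#' @export
glance.edit_de <- function(x, ...) {
  ctr <- attr(x, "contrast")
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2fc > 0),
    n_down = sum(x$significant & x$log2fc < 0),
    contrast = paste(ctr, collapse = ":")
  )
}

#' Tidy a PLS-DA fit (per-sample scores)
#'
#' @param x an `edit_plsda` object.
#' @param ... unused.
#' @return tibble of sample scores with class labels.
#' @method tidy edit_plsda
#' @export
tidy.edit_plsda <- function(x, ...) {
  x$scores
}

#' One-row summary of a PLS-DA fit
#'
#' @param x an `edit_plsda` object.
#' @param ... unused.
#' @return tibble with components and explained X variance.
#' @method glance edit_plsda
#' @export
glance.edit_plsda <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    explained_variance_total = sum(x$explained_variance),
    explained_variance_1 = x$explained_variance[1]
  )
}
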