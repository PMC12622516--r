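#' @export
print.edges_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Coupled spatial NMF fit (d = %d)\n",
    "  genes: %d shared, %d unique; cells: %d ST, %d scRNA-seq\n",
    "  %d iterations, %sconverged; objective %.6g\n"),
    x$d, length(x$shared_genes), length(x$unique_genes),
    length(x$st_cells), length(x$sc_cells),
    x$n_iter, if (x$converged) "" else "NOT ",
    utils::tail(x$objective_trace, 1L)))
  invisible(x)
}

#' Summarize a fitted coupled factorization
#'
#' @param object an `"edges_fit"` object.
#' @param ... unused.
#' @return A list of class `"summary.edges_fit"` with convergence
#'   information and the per-pattern factor mass.
#' @export
summary.edges_fit <- function(object, ...) {
  tr <- object$objective_trace
  structure(list(
    d = object$d, n_iter = object$n_iter, converged = object$converged,
    objective_first = tr[1L], objective_final = utils::tail(tr, 1L),
    rel_decrease = if (length(tr) > 1L)
      (tr[1L] - utils::tail(tr, 1L)) / tr[1L] else 0,
    pattern_mass = colSums(object$W1),
    dims = c(S = length(object$shared_genes),
             U = length(object$unique_genes),
             c1 = length(object$st_cells),
             c2 = length(object$sc_cells))),
    class = "summary.edges_fit")
}

#' @export
print.summary.edges_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Coupled spatial NMF: d = %d, S = %d, U = %d, c1 = %d, c2 = %d\n",
    "  objective %.6g -> %.6g over %d iterations (%.2f%% decrease), %s\n",
    "  shared-gene mass per pattern:\n"),
    x$d, x$dims["S"], x$dims["U"], x$dims["c1"], x$dims["c2"],
    x$objective_first, x$objective_final, x$n_iter, 100 * x$rel_decrease,
    if (x$converged) "converged" else "iteration cap reached"))
  print(summary(x$pattern_mass))
  invisible(x)
}

#' Extract the factor matrices
#'
#' @param object an `"edges_fit"` object.
#' @param ... unused.
#' @return Named list of the four non-negative factors `W1` (shared genes x
#'   d), `W2` (unique genes x d), `H1` (d x ST cells), `H2` (d x scRNA-seq
#'   cells).
#' @export
coef.edges_fit <- function(object, ...) {
  object[c("W1", "W2", "H1", "H2")]
}

#' Predict spatial expression from a fitted model
#'
#' `type = "undetected"` returns the imputed spatial expression of the
#' unique (scRNA-seq-only) genes, `W2 %*% H1`; `type = "denoised"` the
#' low-rank reconstruction of the measured panel, `W1 %*% H1`. Both are
#' genes x ST-cells labeled matrices.
#'
#' @param object an `"edges_fit"` object.
#' @param type which output, see Details.
#' @param ... unused.
#' @return Labeled non-negative matrix over the ST cells.
#' @export
predict.edges_fit <- function(object, type = c("undetected", "denoised"),
                              ...) {
  type <- match.arg(type)
  if (type == "undetected") predict_undetected(object)
  else denoise_measured(object)
}

#' @export
fitted.edges_fit <- function(object, ...) denoise_measured(object)

#' Reconstruction residuals of the measured ST panel
#'
#' @param object an `"edges_fit"` object.
#' @param input the `"edges_input"` the model was fitted to.
#' @param ... unused.
#' @return `X1 - W1 %*% H1` as a genes x cells matrix.
#' @export
residuals.edges_fit <- function(object, input, ...) {
  input <- validate_edges_input(input)
  if (!identical(input$shared_genes, object$shared_genes))
    stop("'input' does not match the fitted gene set", call. = FALSE)
  input$X1 - object$W1 %*% object$H1
}

#' Plot the objective trace of a fit
#'
#' @param x an `"edges_fit"` object.
#' @param log plot the y axis on log scale (default TRUE).
#' @param ... passed to [graphics::plot()].
#' @export
plot.edges_fit <- function(x, log = TRUE, ...) {
  graphics::plot(seq_along(x$objective_trace), x$objective_trace,
                 type = "l", xlab = "iteration", ylab = "objective",
                 log = if (log) "y" else "", ...)
  invisible(x)
}
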