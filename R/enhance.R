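check_fitted <- function(fit) {
  if (!inherits(fit, "edges_fit"))
    stop("'fit' must be an 'edges_fit' object", call. = FALSE)
  fit
}

#' Predicted spatial expression of undetected genes
#'
#' The imputation output of the coupled model: `W2 %*% H1` maps the unique
#' (scRNA-seq-only) gene representations onto the ST cell representations,
#' giving each unmeasured gene a spatial expression profile. Values are
#' emitted as-is, with no rescaling to the measured library sizes.
#'
#' @param fit an `"edges_fit"` object.
#' @return Labeled matrix, unique genes x ST cells, non-negative.
#' @export
predict_undetected <- function(fit) {
  fit <- check_fitted(fit)
  labeled_matrix(fit$W2 %*% fit$H1, fit$unique_genes, fit$st_cells)
}

#' Denoised expression of the measured genes
#'
#' The rank-d reconstruction `W1 %*% H1` of the measured ST panel; the
#' low-rank structure shared with the scRNA-seq reference and the spatial
#' penalty act as the denoiser.
#'
#' @param fit an `"edges_fit"` object.
#' @return Labeled matrix, shared genes x ST cells, non-negative.
#' @export
denoise_measured <- function(fit) {
  fit <- check_fitted(fit)
  labeled_matrix(fit$W1 %*% fit$H1, fit$shared_genes, fit$st_cells)
}

#' Gene abundance scores
#'
#' Sums each shared gene's low-dimensional representation (its row of W1).
#' The score aggregates the expression mass the model assigns to a gene
#' across patterns and serves as a simple importance ranking.
#'
#' @param fit an `"edges_fit"` object.
#' @return Named non-negative numeric vector, one score per shared gene.
#' @export
gene_abundance_scores <- function(fit) {
  fit <- check_fitted(fit)
  stats::setNames(rowSums(fit$W1), fit$shared_genes)
}

#' Assign predicted genes to known expression patterns
#'
#' Each gene's predicted spatial profile is correlated (Pearson) with the
#' mean profile of every known pattern; the gene is assigned to a pattern
#' iff the correlation exceeds `threshold` (default 0.5), and to the
#' highest-correlating pattern when several qualify (exact ties broken by
#' lexical pattern name). Genes whose predicted profile has zero variance
#' are left unassigned.
#'
#' @param pred labeled genes x cells matrix of predicted expression.
#' @param patterns named list of per-cell mean expression profiles, each
#'   aligned to `pred`'s cell order.
#' @param threshold correlation needed for assignment (strict inequality).
#' @return Character vector over genes: a pattern name or `"unassigned"`.
#' @export
assign_patterns <- function(pred, patterns, threshold = 0.5) {
  pred <- labeled_matrix(pred)
  if (!is.list(patterns) || is.null(names(patterns)) ||
      anyDuplicated(names(patterns)))
    stop("'patterns' must be a uniquely named list of profiles",
         call. = FALSE)
  bad <- vapply(patterns, function(p) length(p) != ncol(pred), logical(1))
  if (any(bad))
    stop(sprintf("pattern profile length mismatch: %s",
                 paste(names(patterns)[bad], collapse = ", ")),
         call. = FALSE)
  pnames <- sort(names(patterns))     # lexical order settles exact ties
  prof <- vapply(patterns[pnames], as.numeric, numeric(ncol(pred)))
  out <- rep("unassigned", nrow(pred))
  names(out) <- rownames(pred)
  for (g in seq_len(nrow(pred))) {
    x <- pred[g, ]
    if (stats::sd(x) == 0) next
    r <- suppressWarnings(as.numeric(stats::cor(x, prof)))
    r[is.na(r)] <- -Inf              # zero-variance pattern never qualifies
    if (max(r) > threshold) out[g] <- pnames[which.max(r)]
  }
  out
}

#' Cluster unassigned genes into candidate novel patterns
#'
#' Genes that [assign_patterns()] left unassigned are grouped by k-means on
#' their standardized predicted profiles; each cluster is a candidate novel
#' expression pattern. The clustering backend is deliberately generic and
#' replaceable via `method`.
#'
#' @param pred labeled predicted-expression matrix.
#' @param assignments output of [assign_patterns()] over `pred`'s genes.
#' @param centers number of novel patterns to propose.
#' @param seed RNG seed for the clustering.
#' @param method clustering hook; only `"kmeans"` is built in.
#' @return Named integer vector of cluster labels for the unassigned genes
#'   (empty when fewer unassigned genes than `centers`).
#' @export
cluster_unassigned <- function(pred, assignments, centers = 2, seed = 1L,
                               method = c("kmeans")) {
  method <- match.arg(method)
  pred <- labeled_matrix(pred)
  un <- names(assignments)[assignments == "unassigned"]
  un <- intersect(un, rownames(pred))
  if (length(un) < centers) return(stats::setNames(integer(0), character(0)))
  x <- t(apply(pred[un, , drop = FALSE], 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  km <- with_seed(seed, stats::kmeans(x, centers = centers, nstart = 5L))
  stats::setNames(as.integer(km$cluster), un)
}
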