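check_pair <- function(x, y, min_len = 2L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("vectors must have equal length", call. = FALSE)
  if (length(x) < min_len)
    stop(sprintf("need at least %d observations", min_len), call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("inputs must be finite", call. = FALSE)
  list(x = x, y = y)
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L]) rep(0, length(x)) else (x - r[1L]) / (r[2L] - r[1L])
}

#' Pearson correlation between two expression profiles
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return Correlation in \[-1, 1\]; errors on zero variance.
#' @export
metric_pcc <- function(x, y) {
  v <- check_pair(x, y)
  if (stats::sd(v$x) == 0 || stats::sd(v$y) == 0)
    stop("Pearson correlation undefined for constant input", call. = FALSE)
  stats::cor(v$x, v$y)
}

#' Root-mean-square error on min-max-scaled profiles
#'
#' Both vectors are independently scaled to \[0, 1\] (constant vectors map
#' to zeros) before the RMSE is taken, following the benchmarking
#' convention for cross-assay expression comparison.
#'
#' @inheritParams metric_pcc
#' @return Non-negative RMSE.
#' @export
metric_rmse <- function(x, y) {
  v <- check_pair(x, y)
  sqrt(mean((minmax01(v$x) - minmax01(v$y))^2))
}

#' Global structural similarity of two expression profiles
#'
#' Single-window SSIM on vectors min-max scaled to \[0, 1\], with the
#' standard stabilizers C1 = 0.01^2 and C2 = 0.03^2 (dynamic range 1):
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#' {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with population (1/n) moments.
#'
#' @inheritParams metric_pcc
#' @return SSIM in \[-1, 1\].
#' @export
metric_ssim <- function(x, y) {
  v <- check_pair(x, y)
  if (stats::sd(v$x) == 0 || stats::sd(v$y) == 0)
    stop("SSIM undefined for constant input", call. = FALSE)
  xs <- minmax01(v$x); ys <- minmax01(v$y)
  n <- length(xs)
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- mean(xs); my <- mean(ys)
  vx <- sum((xs - mx)^2) / n
  vy <- sum((ys - my)^2) / n
  cxy <- sum((xs - mx) * (ys - my)) / n
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Jensen-Shannon divergence between two expression profiles
#'
#' The vectors are treated as unnormalized probability distributions:
#' negative entries are clipped to zero (with a warning), each vector is
#' normalized to sum 1, and the JS divergence is computed with base-2
#' logarithms so the value lies in \[0, 1\].
#'
#' @inheritParams metric_pcc
#' @return JS divergence in \[0, 1\]; errors on zero-sum vectors.
#' @export
metric_js <- function(x, y) {
  v <- check_pair(x, y)
  if (any(v$x < 0) || any(v$y < 0)) {
    warning("negative entries clipped to 0 before JS normalization")
    v$x <- pmax(v$x, 0); v$y <- pmax(v$y, 0)
  }
  if (sum(v$x) == 0 || sum(v$y) == 0)
    stop("JS divergence undefined for zero-sum vectors", call. = FALSE)
  p <- v$x / sum(v$x); q <- v$y / sum(v$y)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' All four prediction metrics for one gene
#'
#' @inheritParams metric_pcc
#' @return Named vector `(pcc, ssim, rmse, js)`; entries that are undefined
#'   for the pair (constant or zero-sum vectors) come back `NA`.
#' @export
expression_metrics <- function(x, y) {
  safe <- function(f) tryCatch(suppressWarnings(f(x, y)),
                               error = function(e) NA_real_)
  c(pcc = safe(metric_pcc), ssim = safe(metric_ssim),
    rmse = safe(metric_rmse), js = safe(metric_js))
}

#' Choose the cross-validation fold count from the panel size
#'
#' K = 3 for panels with fewer than 50 measured genes, K = 5 for 50-100,
#' K = 10 otherwise.
#'
#' @param n_genes number of measured (shared) genes, at least 3.
#' @return Integer K.
#' @export
choose_K <- function(n_genes) {
  check_scalar(n_genes, "n_genes", lower = 3, integer = TRUE)
  if (n_genes < 50) 3L else if (n_genes <= 100) 5L else 10L
}

#' Rank-aggregated accuracy score across methods
#'
#' Given each method's mean PCC, SSIM, RMSE and JS, ranks PCC and SSIM
#' ascending (best method gets rank N) and RMSE and JS descending (lowest
#' gets rank N), averages tied ranks, and returns
#' `AS = (RANK_PCC + RANK_SSIM + RANK_RMSE + RANK_JS) / (4N)`, which lies
#' in \[1/N, 1\] with higher meaning better.
#'
#' @param summary data frame with one row per method and columns `pcc`,
#'   `ssim`, `rmse`, `js` (and optionally `method` used for output names).
#' @return Named numeric vector of accuracy scores.
#' @export
accuracy_score <- function(summary) {
  need <- c("pcc", "ssim", "rmse", "js")
  if (!is.data.frame(summary) || !all(need %in% names(summary)))
    stop("'summary' needs columns pcc, ssim, rmse, js", call. = FALSE)
  if (anyNA(summary[need]))
    stop("missing metric value for some method", call. = FALSE)
  n <- nrow(summary)
  if (n < 1L) stop("need at least one method", call. = FALSE)
  as <- (rank(summary$pcc) + rank(summary$ssim) +
           rank(-summary$rmse) + rank(-summary$js)) / (4 * n)
  names(as) <- if ("method" %in% names(summary))
    as.character(summary$method) else rownames(summary)
  as
}

#' Moran's I spatial autocorrelation on the cell graph
#'
#' \deqn{I = \frac{n}{W}\,\frac{\sum_{ij} w_{ij}(x_i - \bar x)(x_j - \bar x)}
#' {\sum_i (x_i - \bar x)^2}}
#' with binary mutual-kNN adjacency weights (no row standardization) and
#' `W` their total. Values near 1 indicate strong spatial clustering of the
#' expression values, values near -1 dispersion; the null expectation is
#' `-1/(n-1)`.
#'
#' @param values per-cell numeric vector aligned to the graph nodes; must
#'   not be constant.
#' @param graph `"spatial_graph"` with at least one edge.
#' @return Moran's I.
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  x <- as.numeric(values)
  n <- length(graph$cell_ids)
  if (length(x) != n)
    stop("'values' length must equal the number of graph nodes",
         call. = FALSE)
  if (stats::sd(x) == 0)
    stop("Moran's I undefined for constant values", call. = FALSE)
  w <- sum(graph$degrees)
  if (w == 0) stop("graph has no edges", call. = FALSE)
  z <- x - mean(x)
  (n / w) * sum(z * as.numeric(graph$A %*% z)) / sum(z^2)
}

#' Hedges' g bias-corrected effect size
#'
#' Standardized mean difference `mean(a) - mean(b)` over the pooled SD,
#' multiplied by the small-sample correction
#' `J = 1 - 3 / (4(n_a + n_b) - 9)`.
#'
#' @param a,b numeric samples of size >= 2 with positive pooled variance.
#' @return Hedges' g (positive when `a` has the larger mean).
#' @export
hedges_g <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  j <- 1 - 3 / (4 * (na + nb) - 9)
  j * (mean(a) - mean(b)) / sqrt(sp2)
}
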