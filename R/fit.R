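#' Control parameters for the coupled factorization
#'
#' Collects the hyperparameters of the objective
#' \deqn{F = \theta_1\|X_1 - W_1H_1\|_F^2 + \|X_2 - W_1H_2\|_F^2 +
#'       \theta_2\|X_3 - W_2H_2\|_F^2 + \lambda_1\,\mathrm{tr}(H_1 L_1 H_1^T)
#'       + \lambda_2\left(\sum_j \|h_j\|_1^2 + \sum_j \|h'_j\|_1^2\right)}
#' and of its multiplicative solver. Defaults are the grid-searched values
#' reported for real imaging-ST panels.
#'
#' @param theta1 weight of the ST reconstruction term (default 0.1).
#' @param theta2 weight of the unique-gene scRNA-seq term (default 1e-4).
#' @param lambda1 spatial (graph Laplacian) penalty weight (default 1e-5).
#' @param lambda2 sparsity penalty weight on the squared column L1 norms of
#'   H1 and H2 (default 10).
#' @param tau relative-progress convergence threshold (default 1e-7): stop
#'   when `(F_t - F_{t+1}) / (F_1 - F_{t+1}) <= tau`, F_1 being the
#'   objective after the first iteration.
#' @param max_iter iteration cap (default 10000); the relative-progress
#'   rule at `tau = 1e-7` typically fires after a few thousand iterations,
#'   so a smaller cap would preempt the convergence criterion.
#' @param eps denominator guard added to every multiplicative ratio
#'   (default 1e-12) so exact zeros never produce 0/0.
#' @param update_rule `"split"` (default) moves the non-negative part
#'   `lambda1 * H1 %*% Ahat` of the Laplacian gradient to the numerator of
#'   the H1 update, keeping both operands non-negative while preserving the
#'   stationary points; `"as_printed"` keeps `lambda1 * H1 %*% L1` in the
#'   denominator, which can go negative and is provided for comparison
#'   only.
#' @return A list of class `"edges_control"`.
#' @export
edges_control <- function(theta1 = 1e-1, theta2 = 1e-4, lambda1 = 1e-5,
                          lambda2 = 10, tau = 1e-7, max_iter = 10000,
                          eps = 1e-12,
                          update_rule = c("split", "as_printed")) {
  check_scalar(theta1, "theta1", lower = 0)
  check_scalar(theta2, "theta2", lower = 0)
  check_scalar(lambda1, "lambda1", lower = 0)
  check_scalar(lambda2, "lambda2", lower = 0)
  check_scalar(tau, "tau", lower = 0, strict = TRUE)
  check_scalar(max_iter, "max_iter", lower = 1, integer = TRUE)
  check_scalar(eps, "eps", lower = 0, strict = TRUE)
  structure(list(theta1 = theta1, theta2 = theta2, lambda1 = lambda1,
                 lambda2 = lambda2, tau = tau,
                 max_iter = as.integer(max_iter), eps = eps,
                 update_rule = match.arg(update_rule)),
            class = "edges_control")
}

#' Initialize the four factor matrices
#'
#' Draws W1 (S x d), W2 (U x d), H1 (d x c1) and H2 (d x c2) i.i.d.
#' Uniform\[0, 1\] from a generator seeded with `seed`, so initialization is
#' deterministic given the seed and leaves the caller's RNG untouched.
#'
#' @param input `"edges_input"` triple (see [partition_input()]).
#' @param d latent dimension; must not exceed `min(S, c1, c2)`.
#' @param seed integer seed.
#' @return List with matrices `W1`, `W2`, `H1`, `H2`.
#' @export
edges_init <- function(input, d, seed = 1L) {
  input <- validate_edges_input(input)
  check_scalar(d, "d", lower = 1, integer = TRUE)
  s <- nrow(input$X1); u <- nrow(input$X3)
  c1 <- ncol(input$X1); c2 <- ncol(input$X2)
  if (d > min(s, c1, c2))
    stop(sprintf("d = %d exceeds min(S, c1, c2) = %d", d, min(s, c1, c2)),
         call. = FALSE)
  with_seed(seed, list(
    W1 = matrix(stats::runif(s * d), s, d),
    W2 = matrix(stats::runif(u * d), u, d),
    H1 = matrix(stats::runif(d * c1), d, c1),
    H2 = matrix(stats::runif(d * c2), d, c2)))
}

#' Evaluate the coupled-factorization objective
#'
#' Sum of the three weighted Frobenius reconstruction terms, the graph
#' Laplacian penalty on H1, and the squared column-wise L1 sparsity penalty
#' on H1 and H2 (see [edges_control()] for the formula).
#'
#' @param input `"edges_input"` triple.
#' @param factors list with `W1`, `W2`, `H1`, `H2`.
#' @param graph `"spatial_graph"` over the ST cells.
#' @param control `"edges_control"` hyperparameters.
#' @return Non-negative scalar objective value.
#' @export
edges_objective <- function(input, factors, graph, control = edges_control()) {
  f <- factors
  r1 <- input$X1 - f$W1 %*% f$H1
  r2 <- input$X2 - f$W1 %*% f$H2
  r3 <- input$X3 - f$W2 %*% f$H2
  control$theta1 * sum(r1 * r1) + sum(r2 * r2) +
    control$theta2 * sum(r3 * r3) +
    control$lambda1 * laplacian_quadratic(f$H1, graph) +
    control$lambda2 * (sum(colSums(f$H1)^2) + sum(colSums(f$H2)^2))
}

#' One multiplicative update of the gene factors
#'
#' With H1, H2 fixed:
#' `W1 <- W1 * (theta1 X1 H1' + X2 H2') / (theta1 W1 H1 H1' + W1 H2 H2')`,
#' `W2 <- W2 * (X3 H2') / (W2 H2 H2')`, elementwise, with `eps` added to the
#' denominators. Non-negativity is preserved and zero entries stay zero.
#'
#' @inheritParams edges_objective
#' @return Updated factor list.
#' @export
edges_update_w <- function(input, factors, control = edges_control()) {
  f <- factors
  th1 <- control$theta1; eps <- control$eps
  h1h1 <- tcrossprod(f$H1)        # H1 H1'
  h2h2 <- tcrossprod(f$H2)
  num1 <- th1 * tcrossprod(input$X1, f$H1) + tcrossprod(input$X2, f$H2)
  den1 <- th1 * f$W1 %*% h1h1 + f$W1 %*% h2h2
  f$W1 <- unname(f$W1 * num1 / (den1 + eps))
  num2 <- tcrossprod(input$X3, f$H2)
  den2 <- f$W2 %*% h2h2
  f$W2 <- unname(f$W2 * num2 / (den2 + eps))
  f
}

#' One multiplicative update of the cell factors
#'
#' With W1, W2 fixed, the default `"split"` rule decomposes the Laplacian
#' gradient term via `L1 = I - Ahat`:
#' `H1 <- H1 * (theta1 W1' X1 + lambda1 H1 Ahat) /`
#' `(theta1 W1' W1 H1 + lambda2 E H1 + lambda1 H1)`,
#' `H2 <- H2 * (W1' X2 + theta2 W2' X3) /`
#' `(W1' W1 H2 + theta2 W2' W2 H2 + lambda2 E H2)`,
#' where `E` is the all-ones d x d matrix (so `E %*% H` repeats the column
#' sums of H in every row). `"as_printed"` instead leaves
#' `lambda1 H1 L1` in the H1 denominator.
#'
#' @inheritParams edges_objective
#' @return Updated factor list.
#' @export
edges_update_h <- function(input, factors, graph,
                           control = edges_control()) {
  f <- factors
  th1 <- control$theta1; th2 <- control$theta2
  l1 <- control$lambda1; l2 <- control$lambda2; eps <- control$eps
  d <- nrow(f$H1)
  w1w1 <- crossprod(f$W1)
  ones_h <- function(h) matrix(colSums(h), d, ncol(h), byrow = TRUE)
  if (control$update_rule == "split") {
    num1 <- th1 * crossprod(f$W1, input$X1) +
      l1 * as.matrix(f$H1 %*% graph$Ahat)
    den1 <- th1 * w1w1 %*% f$H1 + l2 * ones_h(f$H1) + l1 * f$H1
  } else {
    num1 <- th1 * crossprod(f$W1, input$X1)
    den1 <- th1 * w1w1 %*% f$H1 + l2 * ones_h(f$H1) +
      l1 * as.matrix(f$H1 %*% graph$L)
  }
  f$H1 <- unname(f$H1 * num1 / (den1 + eps))
  w2w2 <- crossprod(f$W2)
  num2 <- crossprod(f$W1, input$X2) + th2 * crossprod(f$W2, input$X3)
  den2 <- w1w1 %*% f$H2 + th2 * w2w2 %*% f$H2 + l2 * ones_h(f$H2)
  f$H2 <- unname(f$H2 * num2 / (den2 + eps))
  f
}

#' Fit the spatially constrained coupled factorization
#'
#' Solves the non-convex objective of [edges_control()] by alternating
#' multiplicative updates (gene factors, then cell factors, each block using
#' the freshest co-factors) from a seeded Uniform\[0, 1\] start. After each
#' full iteration the objective is recorded; iteration stops when the
#' relative progress `(F_t - F_{t+1}) / (F_1 - F_{t+1})` drops to `tau` or
#' `max_iter` is reached. If no progress is measurable (`F_1 - F_{t+1} <=
#' 0`) the fit is declared converged.
#'
#' @param input `"edges_input"` triple from [partition_input()].
#' @param graph `"spatial_graph"` over the ST cells, or coordinates
#'   accepted by [spatial_graph()] (then built with neighborhood size `k`).
#' @param d latent dimension (number of expression patterns), default 20.
#' @param k mutual-kNN neighborhood size when `graph` is given as
#'   coordinates, default 5.
#' @param control `"edges_control"` hyperparameters.
#' @param seed seed for the factor initialization.
#' @return An object of class `"edges_fit"`: the four factors `W1`, `W2`,
#'   `H1`, `H2`, the `objective_trace`, `n_iter`, `converged`, plus the
#'   gene/cell identifiers, `d`, `seed`, `control` and the `graph`.
#' @examples
#' sim <- make_planted(S = 20, U = 10, c1 = 25, c2 = 30, d = 3, seed = 1)
#' fit <- edges_fit(sim$input, sim$coords, d = 3, seed = 1,
#'                  control = edges_control(max_iter = 50))
#' fit
#' @export
edges_fit <- function(input, graph, d = 20, k = 5,
                      control = edges_control(), seed = 1L) {
  input <- validate_edges_input(input)
  stopifnot(inherits(control, "edges_control"))
  if (!inherits(graph, "spatial_graph"))
    graph <- spatial_graph(graph, k = k)
  if (length(graph$cell_ids) != ncol(input$X1))
    stop("graph node count must equal the number of ST cells",
         call. = FALSE)
  f <- edges_init(input, d = d, seed = seed)
  trace <- numeric(0)
  converged <- FALSE
  for (t in seq_len(control$max_iter)) {
    f <- edges_update_w(input, f, control)
    f <- edges_update_h(input, f, graph, control)
    trace[t] <- edges_objective(input, f, graph, control)
    if (t >= 2L) {
      denom <- trace[1L] - trace[t]
      if (denom <= 0 || (trace[t - 1L] - trace[t]) / denom <= control$tau) {
        converged <- TRUE
        break
      }
    }
  }
  structure(list(
    W1 = f$W1, W2 = f$W2, H1 = f$H1, H2 = f$H2,
    objective_trace = trace, n_iter = length(trace),
    converged = converged,
    shared_genes = input$shared_genes, unique_genes = input$unique_genes,
    st_cells = colnames(input$X1), sc_cells = colnames(input$X2),
    d = as.integer(d), seed = seed, control = control, graph = graph),
    class = "edges_fit")
}
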