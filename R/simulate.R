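#' Simulate a planted coupled-factor dataset
#'
#' Generates paired ST and scRNA-seq matrices with known non-negative
#' factor structure: `X1 = W1 H1`, `X2 = W1 H2`, `X3 = W2 H2`. ST cells sit
#' on a jittered square grid; each row of `H1` is a spatially smooth
#' non-negative field, built by Gaussian-kernel smoothing of white noise
#' (bandwidth `spatial_smoothness`, in grid units) followed by softplus, so
#' neighboring cells carry similar loadings — the structure the graph
#' Laplacian penalty rewards. `H2` is sparse non-negative
#' (Bernoulli-masked Gamma draws, every cell kept nonzero) and the gene
#' factors are Uniform\[0, 1\]. With `noise_model = "poisson"` the observed
#' matrices are Poisson counts with the clean products, scaled to
#' `target_mean` expected counts per entry, as means.
#'
#' @param S,U,c1,c2 numbers of shared genes, unique genes, ST cells and
#'   scRNA-seq cells. `c1` must be a perfect square (grid layout).
#' @param d planted latent dimension, at most `min(S, c1, c2)`.
#' @param spatial_smoothness Gaussian bandwidth of the planted fields in
#'   grid units (default 1.5); larger is smoother.
#' @param noise_model `"none"` (observed = clean products) or `"poisson"`.
#' @param target_mean mean count per entry under Poisson noise (default 5,
#'   a typical imaging-ST depth).
#' @param seed RNG seed; everything is reproducible from it.
#' @param noise_seed optional separate seed for the measurement noise, so
#'   replicate noisy draws of the same planted structure can be generated;
#'   by default noise continues the `seed` stream.
#' @return List: `input` (`"edges_input"`), `coords` (jittered grid),
#'   `truth` (planted factors, clean matrices, noise model, seed).
#' @examples
#' sim <- make_planted(S = 20, U = 10, c1 = 16, c2 = 25, d = 3, seed = 7)
#' dim(sim$input$X1)
#' @export
make_planted <- function(S = 60, U = 40, c1 = 100, c2 = 100, d = 4,
                         spatial_smoothness = 1.5,
                         noise_model = c("none", "poisson"),
                         target_mean = 5, seed = 1L, noise_seed = NULL) {
  noise_model <- match.arg(noise_model)
  sizes <- c(S = S, U = U, c1 = c1, c2 = c2, d = d)
  for (nm in names(sizes))
    check_scalar(sizes[[nm]], nm, lower = 1, integer = TRUE)
  check_scalar(spatial_smoothness, "spatial_smoothness", lower = 0,
               strict = TRUE)
  g <- sqrt(c1)
  if (g != round(g))
    stop("'c1' must be a perfect square for the grid layout", call. = FALSE)
  if (d > min(S, c1, c2))
    stop("d exceeds min(S, c1, c2)", call. = FALSE)
  with_seed(seed, {
    gx <- rep(seq_len(g), each = g)
    gy <- rep(seq_len(g), times = g)
    coords <- data.frame(
      cell_id = sprintf("st%03d", seq_len(c1)),
      x = gx + stats::runif(c1, -0.1, 0.1),
      y = gy + stats::runif(c1, -0.1, 0.1))
    # smoothing operator over the grid (row-normalized Gaussian kernel)
    d2 <- as.matrix(stats::dist(cbind(gx, gy)))^2
    kern <- exp(-d2 / (2 * spatial_smoothness^2))
    kern <- kern / rowSums(kern)
    noise <- matrix(stats::rnorm(d * c1, sd = 2), d, c1)
    h1 <- unname(log1p(exp(noise %*% t(kern))))  # softplus, smoothed fields
    h2 <- matrix(stats::rgamma(d * c2, shape = 2, rate = 2) *
                   stats::rbinom(d * c2, 1L, 0.4), d, c2)
    for (j in which(colSums(h2) == 0))     # every cell loads some pattern
      h2[sample.int(d, 1L), j] <- stats::rgamma(1L, shape = 2, rate = 2)
    w1 <- matrix(stats::runif(S * d), S, d)
    w2 <- matrix(stats::runif(U * d), U, d)
    genes_s <- sprintf("shared%03d", seq_len(S))
    genes_u <- sprintf("unique%03d", seq_len(U))
    cells_sc <- sprintf("sc%03d", seq_len(c2))
    clean <- list(
      X1 = labeled_matrix(w1 %*% h1, genes_s, coords$cell_id),
      X2 = labeled_matrix(w1 %*% h2, genes_s, cells_sc),
      X3 = labeled_matrix(w2 %*% h2, genes_u, cells_sc))
    obs <- clean
    if (noise_model == "poisson") {
      if (!is.null(noise_seed)) set.seed(as.integer(noise_seed))
      obs <- lapply(clean, function(m) {
        mu <- m * target_mean / mean(m)
        labeled_matrix(matrix(stats::rpois(length(mu), mu), nrow(mu),
                              ncol(mu)), rownames(m), colnames(m))
      })
    }
    input <- structure(list(
      X1 = obs$X1, X2 = obs$X2, X3 = obs$X3,
      shared_genes = genes_s, unique_genes = genes_u),
      class = "edges_input")
    list(input = validate_edges_input(input), coords = coords,
         truth = list(W1 = w1, W2 = w2, H1 = h1, H2 = h2, clean = clean,
                      noise_model = noise_model, seed = seed))
  })
}

#' Hold out shared genes as prediction targets
#'
#' Moves a seeded random fraction of the shared genes into the unique set:
#' their ST rows are removed from `X1` (kept aside as ground truth) and
#' their scRNA-seq rows travel from `X2` to the end of `X3`. This mirrors
#' the gene-removal mechanics of the cross-validation protocol and of real
#' use, where the target genes were never measured spatially.
#'
#' @param input `"edges_input"`.
#' @param fraction fraction of shared genes to move, in (0, 1); the count
#'   is `round(fraction * S)`, at least 1.
#' @param seed RNG seed for the gene draw.
#' @return List: `input` (reduced `"edges_input"`), `held_genes`, `truth`
#'   (labeled matrix of the held genes' true ST profiles).
#' @export
holdout_genes <- function(input, fraction, seed = 1L) {
  input <- validate_edges_input(input)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("'fraction' must be in (0, 1)", call. = FALSE)
  s <- length(input$shared_genes)
  n_move <- max(1L, round(fraction * s))
  if (s - n_move < 2L)
    stop("holdout would leave fewer than 2 shared genes", call. = FALSE)
  held <- with_seed(seed, sample(input$shared_genes, n_move))
  keep <- setdiff(input$shared_genes, held)
  reduced <- structure(list(
    X1 = input$X1[keep, , drop = FALSE],
    X2 = input$X2[keep, , drop = FALSE],
    X3 = rbind(input$X3, input$X2[held, , drop = FALSE]),
    shared_genes = keep,
    unique_genes = c(input$unique_genes, held)), class = "edges_input")
  list(input = validate_edges_input(reduced), held_genes = held,
       truth = input$X1[held, , drop = FALSE])
}
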