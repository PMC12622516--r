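# Independent scalar-loop oracles. Everything here is written with explicit
# elementwise loops (no reuse of the package's matrix expressions) so the
# vectorized implementation is checked against an independent evaluation of
# the same formulas.

mat_mult_loop <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(ncol(b)))
      for (k in seq_len(ncol(a)))
        out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

frob2_loop <- function(x, y) {
  acc <- 0
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      acc <- acc + (x[i, j] - y[i, j])^2
  acc
}

oracle_objective <- function(input, f, graph, ctl) {
  l <- as.matrix(graph$L)
  w1h1 <- mat_mult_loop(f$W1, f$H1)
  w1h2 <- mat_mult_loop(f$W1, f$H2)
  w2h2 <- mat_mult_loop(f$W2, f$H2)
  lap <- 0
  hl <- mat_mult_loop(f$H1, l)
  for (r in seq_len(nrow(f$H1)))
    for (j in seq_len(ncol(f$H1)))
      lap <- lap + hl[r, j] * f$H1[r, j]
  sparse <- 0
  for (j in seq_len(ncol(f$H1))) sparse <- sparse + sum(f$H1[, j])^2
  for (j in seq_len(ncol(f$H2))) sparse <- sparse + sum(f$H2[, j])^2
  ctl$theta1 * frob2_loop(input$X1, w1h1) +
    frob2_loop(input$X2, w1h2) +
    ctl$theta2 * frob2_loop(input$X3, w2h2) +
    ctl$lambda1 * lap + ctl$lambda2 * sparse
}

oracle_update_w <- function(input, f, ctl) {
  th1 <- ctl$theta1; eps <- ctl$eps
  num1 <- th1 * mat_mult_loop(input$X1, t(f$H1)) +
    mat_mult_loop(input$X2, t(f$H2))
  den1 <- th1 * mat_mult_loop(mat_mult_loop(f$W1, f$H1), t(f$H1)) +
    mat_mult_loop(mat_mult_loop(f$W1, f$H2), t(f$H2))
  w1 <- f$W1
  for (i in seq_len(nrow(w1)))
    for (j in seq_len(ncol(w1)))
      w1[i, j] <- w1[i, j] * num1[i, j] / (den1[i, j] + eps)
  num2 <- mat_mult_loop(input$X3, t(f$H2))
  den2 <- mat_mult_loop(mat_mult_loop(f$W2, f$H2), t(f$H2))
  w2 <- f$W2
  for (i in seq_len(nrow(w2)))
    for (j in seq_len(ncol(w2)))
      w2[i, j] <- w2[i, j] * num2[i, j] / (den2[i, j] + eps)
  f$W1 <- w1; f$W2 <- w2
  f
}

oracle_update_h <- function(input, f, graph, ctl) {
  th1 <- ctl$theta1; th2 <- ctl$theta2
  l1 <- ctl$lambda1; l2 <- ctl$lambda2; eps <- ctl$eps
  d <- nrow(f$H1)
  ones <- matrix(1, d, d)
  ahat <- as.matrix(graph$Ahat)
  num1 <- th1 * mat_mult_loop(t(f$W1), input$X1) +
    l1 * mat_mult_loop(f$H1, ahat)
  den1 <- th1 * mat_mult_loop(mat_mult_loop(t(f$W1), f$W1), f$H1) +
    l2 * mat_mult_loop(ones, f$H1) + l1 * f$H1
  h1 <- f$H1
  for (i in seq_len(nrow(h1)))
    for (j in seq_len(ncol(h1)))
      h1[i, j] <- h1[i, j] * num1[i, j] / (den1[i, j] + eps)
  num2 <- mat_mult_loop(t(f$W1), input$X2) +
    th2 * mat_mult_loop(t(f$W2), input$X3)
  den2 <- mat_mult_loop(mat_mult_loop(t(f$W1), f$W1), f$H2) +
    th2 * mat_mult_loop(mat_mult_loop(t(f$W2), f$W2), f$H2) +
    l2 * mat_mult_loop(ones, f$H2)
  h2 <- f$H2
  for (i in seq_len(nrow(h2)))
    for (j in seq_len(ncol(h2)))
      h2[i, j] <- h2[i, j] * num2[i, j] / (den2[i, j] + eps)
  f$H1 <- h1; f$H2 <- h2
  f
}

# brute-force mutual-kNN over the all-pairs distance matrix
oracle_mutual_knn <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  directed <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ranked <- others[order(d[i, others], others)]
    directed[i, ranked[seq_len(k)]] <- TRUE
  }
  (directed & t(directed)) * 1
}

# small labeled random instance without planted structure
random_instance <- function(s, u, c1, c2, seed, k = 3) {
  set.seed(seed)
  gs <- sprintf("g%03d", seq_len(s))
  gu <- sprintf("u%03d", seq_len(u))
  cs <- sprintf("st%03d", seq_len(c1))
  cc <- sprintf("sc%03d", seq_len(c2))
  input <- structure(list(
    X1 = labeled_matrix(matrix(runif(s * c1), s, c1), gs, cs),
    X2 = labeled_matrix(matrix(runif(s * c2), s, c2), gs, cc),
    X3 = labeled_matrix(matrix(runif(u * c2), u, c2), gu, cc),
    shared_genes = gs, unique_genes = gu), class = "edges_input")
  coords <- data.frame(cell_id = cs, x = runif(c1, 0, 4), y = runif(c1, 0, 4))
  list(input = input, coords = coords,
       graph = spatial_graph(coords, k = k))
}
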