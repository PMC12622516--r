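test_that("metric closed forms hold at identity and anticorrelation", {
  x <- c(0.2, 1.4, 3.1, 0.8, 2.2)
  expect_equal(metric_pcc(x, x), 1)
  expect_equal(metric_ssim(x, x), 1)
  expect_equal(metric_rmse(x, x), 0)
  expect_equal(metric_js(x, x), 0)
  expect_equal(metric_pcc(x, -x + 10), -1)
  expect_error(metric_pcc(rep(1, 4), x[1:4]), "constant")
  expect_error(metric_ssim(rep(1, 5), x), "constant")
  expect_error(metric_pcc(1:3, 1:4), "equal length")
})

test_that("JS divergence of disjoint point masses is 1 bit and symmetric", {
  expect_equal(metric_js(c(1, 0), c(0, 1)), 1)
  set.seed(1)
  x <- runif(20); y <- runif(20)
  expect_equal(metric_js(x, y), metric_js(y, x), tolerance = 1e-14)
  expect_true(metric_js(x, y) >= 0 && metric_js(x, y) <= 1)
  expect_warning(j <- metric_js(c(-1, 2, 3), c(1, 1, 1)), "clipped")
  expect_error(metric_js(c(0, 0), c(1, 2)), "zero-sum")
})

test_that("rmse and ssim use the min-max scaling convention", {
  # scaled vectors: x -> (0, 1), y -> (1, 0); rmse = 1
  expect_equal(metric_rmse(c(3, 7), c(9, 2)), 1)
  # shift/scale invariance induced by min-max scaling
  set.seed(2)
  x <- runif(30); y <- runif(30)
  expect_equal(metric_rmse(2 * x + 5, y), metric_rmse(x, y))
  expect_equal(metric_ssim(3 * x + 1, y), metric_ssim(x, y),
               tolerance = 1e-12)
  # hand evaluation of the stabilized SSIM formula on a tiny pair
  xs <- c(0, 0.5, 1); ys <- c(1, 0, 0.5)
  n <- 3; c1 <- 1e-4; c2 <- 9e-4
  mx <- mean(xs); my <- mean(ys)
  vx <- mean((xs - mx)^2); vy <- mean((ys - my)^2)
  cxy <- mean((xs - mx) * (ys - my))
  ref <- (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(metric_ssim(c(0, 1, 2), c(3, 1, 2)), ref,
               tolerance = 1e-12)
})

test_that("choose_K implements the panel-size rule", {
  expect_identical(choose_K(33), 3L)
  expect_identical(choose_K(49), 3L)
  expect_identical(choose_K(50), 5L)
  expect_identical(choose_K(100), 5L)
  expect_identical(choose_K(101), 10L)
  expect_identical(choose_K(351), 10L)
  expect_error(choose_K(2), ">= 3")
})

test_that("accuracy score aggregates fractional ranks within [1/N, 1]", {
  one <- data.frame(method = "m", pcc = 0.5, ssim = 0.5, rmse = 1, js = 0.2)
  expect_equal(unname(accuracy_score(one)), 1)
  five <- data.frame(method = paste0("m", 1:5),
                     pcc = c(0.9, 0.1, 0.2, 0.3, 0.4),
                     ssim = c(0.8, 0.1, 0.2, 0.3, 0.4),
                     rmse = c(0.1, 0.9, 0.8, 0.7, 0.6),
                     js = c(0.05, 0.5, 0.4, 0.3, 0.2))
  as5 <- accuracy_score(five)
  expect_equal(unname(as5["m1"]), 1)    # best on all four metrics
  expect_equal(unname(as5["m2"]), 1 / 5)  # worst on all four
  # hand-computed rank table for N = 3:
  # pcc ranks (asc): a=1 b=3 c=2; ssim: a=2 b=3 c=1
  # rmse ranks (desc): a=3 b=1 c=2; js: a=3 b=2 c=1
  three <- data.frame(method = c("a", "b", "c"),
                      pcc = c(0.1, 0.9, 0.5), ssim = c(0.5, 0.9, 0.2),
                      rmse = c(0.1, 0.9, 0.3), js = c(0.1, 0.3, 0.5))
  expect_equal(unname(accuracy_score(three)),
               c((1 + 2 + 3 + 3) / 12, (3 + 3 + 1 + 2) / 12,
                 (2 + 1 + 2 + 1) / 12))
  # invariant to order-preserving transforms of a metric column
  three2 <- three; three2$pcc <- exp(10 * three$pcc)
  expect_equal(unname(accuracy_score(three2)),
               unname(accuracy_score(three)))
  # scores average to (N+1)/(2N) when there are no ties
  expect_equal(mean(accuracy_score(five)), (5 + 1) / (2 * 5))
  expect_error(accuracy_score(three[-2]), "pcc")
  three$js[1] <- NA
  expect_error(accuracy_score(three), "missing")
})

test_that("Moran's I matches direct evaluation and its permutation null", {
  g2 <- normalized_laplacian(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(morans_i(c(1, -1), g2), -1)
  expect_error(morans_i(c(1, 1), g2), "constant")
  # smooth field on a grid graph has positive spatial autocorrelation
  sim <- make_planted(S = 5, U = 3, c1 = 36, c2 = 10, d = 2,
                      noise_model = "none", seed = 3)
  g <- spatial_graph(sim$coords, k = 4)
  smooth_val <- sim$truth$H1[1, ]
  expect_gt(morans_i(smooth_val, g), 0)
  # permutation null: mean I over shuffles approaches -1/(n-1)
  set.seed(4)
  sims <- replicate(1000, morans_i(sample(smooth_val), g))
  expect_lt(abs(mean(sims) - (-1 / (36 - 1))),
            3 * stats::sd(sims) / sqrt(1000) + 1e-3)
})

test_that("Moran's I agrees with an independent implementation on a
           regular graph", {
  skip_if_not_installed("ape")
  # cycle graph: all degrees equal, so row standardization is a global
  # rescaling and both conventions must coincide
  n <- 12
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    a[i, j] <- a[j, i] <- 1
  }
  g <- normalized_laplacian(a)
  set.seed(5)
  x <- rnorm(n)
  expect_equal(morans_i(x, g), ape::Moran.I(x, a)$observed,
               tolerance = 1e-12)
})

test_that("Hedges' g is antisymmetric, zero at equal means, and exact on
           a hand-derived case", {
  a <- c(1, 2, 3, 4)
  b <- c(2.5, 1.5, 3.5, 2.5)
  expect_equal(hedges_g(a, a), 0)
  expect_equal(hedges_g(a, b), -hedges_g(b, a))
  # hand derivation: a = (0, 0.2), b = (1, 1.2)
  aa <- c(0, 0.2); bb <- c(1, 1.2)
  sp <- sqrt((var(aa) + var(bb)) / 2)
  j <- 1 - 3 / (4 * 4 - 9)
  expect_equal(hedges_g(aa, bb), j * (0.1 - 1.1) / sp)
  expect_error(hedges_g(c(1, 1), c(1, 1)), "variance")
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
})

test_that("expression_metrics reports NA where a metric is undefined", {
  em <- expression_metrics(rep(1, 4), c(1, 2, 3, 4))
  expect_true(is.na(em["pcc"]) && is.na(em["ssim"]))
  expect_false(is.na(em["rmse"]) || is.na(em["js"]))
})
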