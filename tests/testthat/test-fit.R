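test_that("initialization is seeded, uniform in [0,1], and size-checked", {
  ri <- random_instance(6, 4, 8, 9, seed = 1)
  f1 <- edges_init(ri$input, d = 3, seed = 10)
  f2 <- edges_init(ri$input, d = 3, seed = 10)
  f3 <- edges_init(ri$input, d = 3, seed = 11)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_true(all(vapply(f1, function(m) all(m >= 0 & m <= 1), logical(1))))
  expect_equal(dim(f1$W1), c(6L, 3L))
  expect_equal(dim(f1$H2), c(3L, 9L))
  expect_error(edges_init(ri$input, d = 7), "exceeds")
})

test_that("objective is zero at exact factorizations and explicit at zero", {
  ri <- random_instance(5, 3, 6, 7, seed = 2)
  f <- edges_init(ri$input, d = 2, seed = 3)
  exact <- ri$input
  exact$X1 <- f$W1 %*% f$H1
  exact$X2 <- f$W1 %*% f$H2
  exact$X3 <- f$W2 %*% f$H2
  ctl0 <- edges_control(lambda1 = 0, lambda2 = 0)
  expect_equal(edges_objective(exact, f, ri$graph, ctl0), 0,
               tolerance = 1e-20)
  zf <- lapply(f, function(m) m * 0)
  ctl <- edges_control()
  expect_equal(edges_objective(ri$input, zf, ri$graph, ctl),
               ctl$theta1 * sum(ri$input$X1^2) + sum(ri$input$X2^2) +
                 ctl$theta2 * sum(ri$input$X3^2))
})

test_that("exact factorizations are fixed points of the updates", {
  ri <- random_instance(5, 3, 6, 7, seed = 4)
  f <- edges_init(ri$input, d = 2, seed = 5)
  exact <- ri$input
  exact$X1 <- f$W1 %*% f$H1
  exact$X2 <- f$W1 %*% f$H2
  exact$X3 <- f$W2 %*% f$H2
  ctl0 <- edges_control(lambda1 = 0, lambda2 = 0)
  fw <- edges_update_w(exact, f, ctl0)
  expect_equal(fw$W1, f$W1, tolerance = 1e-10)
  expect_equal(fw$W2, f$W2, tolerance = 1e-10)
  fh <- edges_update_h(exact, f, ri$graph, ctl0)
  expect_equal(fh$H1, f$H1, tolerance = 1e-10)
  expect_equal(fh$H2, f$H2, tolerance = 1e-10)
})

test_that("updates preserve non-negativity and keep zeros at zero", {
  ri <- random_instance(6, 4, 8, 9, seed = 6)
  f <- edges_init(ri$input, d = 3, seed = 7)
  f$W1[1, 1] <- 0
  f$H1[2, 3] <- 0
  ctl <- edges_control()
  for (t in 1:100) {
    f <- edges_update_w(ri$input, f, ctl)
    f <- edges_update_h(ri$input, f, ri$graph, ctl)
  }
  expect_true(all(vapply(f, function(m) all(m >= 0) && all(is.finite(m)),
                         logical(1))))
  expect_identical(f$W1[1, 1], 0)
  expect_identical(f$H1[2, 3], 0)
})

test_that("non-negativity of all factors holds across many random fits", {
  for (s in 1:50) {
    ri <- random_instance(5, 3, 6, 6, seed = s)
    f <- edges_init(ri$input, d = 2, seed = s)
    ctl <- edges_control()
    for (t in 1:5) {
      f <- edges_update_w(ri$input, f, ctl)
      f <- edges_update_h(ri$input, f, ri$graph, ctl)
    }
    expect_true(all(vapply(f, function(m) all(m >= 0) && all(is.finite(m)),
                           logical(1))))
  }
})

test_that("objective trace is monotone with and without regularization", {
  for (s in 1:10) {
    ri <- random_instance(8, 5, 9, 10, seed = s)
    for (ctl in list(edges_control(max_iter = 120),
                     edges_control(lambda1 = 0, lambda2 = 0,
                                   max_iter = 120))) {
      fit <- edges_fit(ri$input, ri$graph, d = 3, control = ctl, seed = s)
      tr <- fit$objective_trace
      expect_true(all(diff(tr) <= 1e-9 * head(tr, -1)))
    }
  }
})

test_that("fit obeys the iteration contract and is seed-deterministic", {
  ri <- random_instance(6, 4, 8, 9, seed = 8)
  one <- edges_fit(ri$input, ri$graph, d = 2,
                   control = edges_control(max_iter = 1), seed = 1)
  expect_equal(one$n_iter, 1L)
  expect_false(one$converged)   # the ratio needs two objective values
  a <- edges_fit(ri$input, ri$graph, d = 2,
                 control = edges_control(max_iter = 60), seed = 2)
  b <- edges_fit(ri$input, ri$graph, d = 2,
                 control = edges_control(max_iter = 60), seed = 2)
  expect_identical(a$objective_trace, b$objective_trace)
  expect_identical(a$W1, b$W1)
})

test_that("planted noiseless data are recovered to small relative error", {
  sim <- make_planted(S = 30, U = 20, c1 = 36, c2 = 40, d = 3,
                      noise_model = "none", seed = 9)
  fit <- edges_fit(sim$input, sim$coords, d = 3,
                   control = edges_control(lambda1 = 0, lambda2 = 0),
                   seed = 10)
  rel <- norm(sim$input$X1 - fit$W1 %*% fit$H1, "F") /
    norm(sim$input$X1, "F")
  expect_lt(rel, 1e-2)
  expect_true(fit$converged)
})

test_that("the as-printed update rule reproduces the split rule when
           the Laplacian weight is zero", {
  ri <- random_instance(6, 4, 8, 9, seed = 12)
  f <- edges_init(ri$input, d = 2, seed = 12)
  ctl_s <- edges_control(lambda1 = 0, update_rule = "split")
  ctl_p <- edges_control(lambda1 = 0, update_rule = "as_printed")
  expect_equal(edges_update_h(ri$input, f, ri$graph, ctl_s),
               edges_update_h(ri$input, f, ri$graph, ctl_p),
               tolerance = 1e-15)
})

test_that("model methods expose the fit coherently", {
  sim <- make_planted(S = 12, U = 6, c1 = 16, c2 = 14, d = 2,
                      noise_model = "none", seed = 13)
  fit <- edges_fit(sim$input, sim$coords, d = 2,
                   control = edges_control(max_iter = 40), seed = 13)
  expect_output(print(fit), "Coupled spatial NMF")
  expect_output(print(summary(fit)), "objective")
  cf <- coef(fit)
  expect_named(cf, c("W1", "W2", "H1", "H2"))
  expect_equal(predict(fit), predict_undetected(fit))
  expect_equal(predict(fit, type = "denoised"), fitted(fit))
  res <- residuals(fit, sim$input)
  expect_equal(res, sim$input$X1 - fit$W1 %*% fit$H1, ignore_attr = TRUE)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
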