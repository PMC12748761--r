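test_that("published equations load verbatim and range-check their id", {
  eq2 <- load_printed_equation(2)
  expect_equal(eq2$intercept, 3465.0)
  expect_equal(Filter(function(tm) tm$name == "Al", eq2$terms)[[1]]$coef,
               955.0)
  expect_equal(unname(eq2$means["Al:P"]), 0.268)
  eq6 <- load_printed_equation(6)
  expect_equal(eq6$intercept, 285830)
  expect_error(load_printed_equation(7), "unknown equation")
})

test_that("predict_at evaluates the linear predictor with term-specific means", {
  eq3 <- load_printed_equation(3)
  at0 <- list(Al = 0, P = 0, `Al:P` = 0)
  expect_equal(predict_at(eq3, at0), 3661600)
  expect_equal(predict_at(eq3, list(Al = 1, P = 1, `Al:P` = 1)), 113300)
  expect_error(predict_at(eq3, list(Al = 1, P = 1)), "Al:P")
})

test_that("marginal effects reduce to the main coefficient without interactions", {
  eq3 <- load_printed_equation(3)
  # CM main effect in eq 1 has no interactions: the coefficient itself
  expect_equal(marginal_effect(load_printed_equation(1), "CM"), -1085)
  expect_error(marginal_effect(eq3, "Ta"), "not in the model")
})

test_that("backward elimination collapses a constant response to its intercept", {
  set.seed(2)
  tab <- expand.grid(CM = 0:1, Al = 0:1, P = 0:1)
  tab <- tab[rep(seq_len(nrow(tab)), 30), ]
  tab$yield_g <- 1200
  fit <- suppressWarnings(   # perfect fit: summary warns at each pass
    fit_dummy_regression(tab, "yield_g", c("CM", "Al", "P", "Al:P")))
  expect_length(fit$model$terms, 0)
  expect_equal(fit$model$intercept, 1200)
  # invalid designs are rejected with informative errors
  tab$bad <- 2
  expect_error(fit_dummy_regression(tab, "yield_g", "bad"), "0/1 dummy")
  tab$Al2 <- tab$Al
  expect_error(fit_dummy_regression(tab, "yield_g", c("Al", "Al2")),
               "collinear")
})

test_that("fitting recovers a known dummy-regression structure", {
  set.seed(17)
  des <- expand.grid(CM = 0:1, Al = 0:1, P = 0:1)
  tab <- des[rep(seq_len(nrow(des)), 200), ]
  truth <- c(`(Intercept)` = 3465, CM = -1091, Al = 955, P = 596.7,
             `Al:P` = -557.3)
  tab$yield_g <- truth[1] + truth[2] * tab$CM + truth[3] * tab$Al +
    truth[4] * tab$P + truth[5] * tab$Al * tab$P + rnorm(nrow(tab), 0, 50)
  fit <- fit_dummy_regression(tab, "yield_g",
                              c("CM", "Al", "P", "CM:Al", "CM:P", "Al:P",
                                "CM:Al:P"))
  cf <- coef(fit$lm)
  se <- summary(fit$lm)$coefficients[, "Std. Error"]
  for (nm in names(truth)) {
    expect_true(nm %in% names(cf))
    expect_lt(abs(cf[nm] - truth[nm]), 3 * se[nm])
  }
  # spurious terms are eliminated
  expect_false("CM:Al:P" %in% names(cf))
  # OLS identity: prediction at regressor means equals the response mean
  expect_equal(predict_at(fit$model), mean(tab$yield_g), tolerance = 1e-8)
})

test_that("percent reduction supports both published conventions", {
  expect_equal(percent_reduction(load_printed_equation(3), character(0)), 0)
  expect_error(percent_reduction(load_printed_equation(3), "Ta"),
               "not in the model")
  r97 <- percent_reduction(load_printed_equation(3), c("Al", "P"))
  expect_equal(round(r97), 97)
  r43 <- percent_reduction(load_printed_equation(6), c("Ta", "Am"),
                           mode = "marginal_vs_intercept")
  expect_equal(round(r43), 43)
})
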