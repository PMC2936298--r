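# Helper: a risk model with prescribed constant component risks, wrapped as
# a "fitted" object so meta-inference can be exercised with known values.
const_fit <- function(mix, probs) {
  cm <- cbind(qlogis(probs), matrix(0, mix$k, 4))
  risk_model(cm, mix, degree = 4L)
}

test_that("logit-scale combination is idempotent and antisymmetric", {
  mix <- toy_mixture()
  f <- const_fit(mix, c(0.2, 0.05))
  same <- list(f, f, f)
  meta <- combine_risk_estimates(same, 1, 2000)
  expect_equal(meta$estimate, 0.2, tolerance = 1e-12)
  expect_equal(meta$s_theta, 0)
  expect_equal(meta$n_rep, 3L)

  single <- combine_risk_estimates(list(f), 2, 3200)
  expect_equal(single$estimate, 0.05, tolerance = 1e-12)

  two <- list(const_fit(mix, c(0.2, 0.5)), const_fit(mix, c(0.8, 0.5)))
  m2 <- combine_risk_estimates(two, 1, 2000)
  expect_equal(m2$estimate, 0.5, tolerance = 1e-12)  # logits cancel
})

test_that("samples with the target undefined are excluded with reduced n_rep", {
  mix <- toy_mixture()
  good <- const_fit(mix, c(0.2, 0.05))
  dead <- const_fit(mix, c(0.3, 0.05))
  dead$estimable[1] <- FALSE
  expect_warning(
    meta <- combine_risk_estimates(list(good, good, dead), 1, 2000),
    "excluded")
  expect_equal(meta$n_rep, 2L)
  expect_equal(meta$n_rep_total, 3L)
  # outside the component's supported range the sample is excluded too
  expect_warning(
    expect_error(combine_risk_estimates(list(good, dead), 1, 5000), "fewer"),
    "excluded")
})

test_that("overlap constant obeys its closed-form limits and monotonicity", {
  expect_equal(overlap_constant(4, 0.7, 1), 4)
  expect_equal(overlap_constant(2.5, 0, 25), 2.5)
  expect_equal(overlap_constant(4, 1e-9, 25), 4, tolerance = 1e-6)
  expect_equal(overlap_constant(4.0, 0.2465, 25), 24.67085766,
               tolerance = 1e-7)
  expect_error(overlap_constant(4, 1, 5), "phi")
  expect_error(overlap_constant(4, -0.1, 5), "phi")

  for (nr in c(2, 5, 25)) {
    grid <- seq(0.001, 0.999, by = 0.001)
    vals <- vapply(grid, overlap_constant, numeric(1), c0 = 4, n_rep = nr)
    expect_true(all(diff(vals) > -1e-12))
    expect_gt(vals[1], 4 - 0.1)  # continuous at phi -> 0
  }
})

test_that("logit and probability intervals follow the half-width arithmetic", {
  meta <- bwmort:::new_meta(c(-3, -3), list(type = "risk", j = 1, x = 1000))
  meta$thetas <- NULL  # fields below drive the computation
  meta$theta_bar <- -3; meta$s_theta <- 0.5; meta$n_rep <- 25L
  meta$bias <- 0.1
  ci <- ci_theta(meta, 4)
  expect_equal(c(ci$lower, ci$upper), c(-3.5, -2.5))
  ci0 <- ci_theta(meta, 4, use_bias = FALSE)
  expect_equal(c(ci0$lower, ci0$upper), c(-3.4, -2.6))

  ri <- risk_interval(meta, 4)
  expect_equal(c(ri$lower, ri$upper), plogis(c(-3.5, -2.5)), tolerance = 1e-12)
  expect_equal(round(c(ri$lower, ri$upper), 4), c(0.0293, 0.0759))

  # degenerate: no spread, no bias
  meta$s_theta <- 0; meta$bias <- 0
  dg <- ci_theta(meta, 4)
  expect_true(dg$degenerate)
  expect_equal(dg$lower, dg$upper)
  expect_true(risk_interval(meta, 4)$degenerate)
})

test_that("the bias-adjusted interval always contains the unadjusted one", {
  set.seed(10)
  for (rep in 1:20) {
    meta <- bwmort:::new_meta(rnorm(8, -4, 1), list(type = "risk", j = 1, x = 1))
    meta$bias <- rexp(1, 5)
    a <- ci_theta(meta, 3.5)
    u <- ci_theta(meta, 3.5, use_bias = FALSE)
    expect_lte(a$lower, u$lower)
    expect_gte(a$upper, u$upper)
    # monotone mapping to the probability scale preserves endpoint order
    ra <- risk_interval(meta, 3.5)
    expect_true(ra$lower <= ra$point && ra$point <= ra$upper)
  }
})

test_that("within-population odds ratios are reciprocal and match arithmetic", {
  mix <- toy_mixture()
  f1 <- const_fit(mix, c(plogis(-3), plogis(-4)))
  fits <- list(f1, f1)
  or <- suppressWarnings(odds_ratio_within(fits, 1, 2, 2500, c = 4))
  expect_equal(or$point, exp(1), tolerance = 1e-12)
  expect_equal(or$meta$s_theta, 0)

  orr <- suppressWarnings(odds_ratio_within(fits, 2, 1, 2500, c = 4))
  expect_equal(or$point * orr$point, 1, tolerance = 1e-12)

  or_same <- odds_ratio_within(fits, 1, 1, 2500, c = 4)
  expect_equal(or_same$point, 1)
  expect_equal(or_same$meta$s_theta, 0)

  # varying fits: reciprocity of the point estimates still exact
  f2 <- const_fit(mix, c(0.1, 0.02))
  vr <- list(f1, f2)
  a <- odds_ratio_within(vr, 1, 2, 2500, c = 2)
  b <- odds_ratio_within(vr, 2, 1, 2500, c = 2)
  expect_equal(a$point * b$point, 1, tolerance = 1e-12)
})

test_that("between-population odds ratios combine spreads and biases", {
  m1 <- bwmort:::new_meta(rep(-3, 25), list(type = "risk", j = 2, x = 3000))
  m2 <- bwmort:::new_meta(rep(-3.5, 25), list(type = "risk", j = 2, x = 3000))
  m1$s_theta <- 0.5; m2$s_theta <- 0.5
  m1$bias <- 0.1; m2$bias <- 0.1
  or <- odds_ratio_between(m1, m2, c = 4)
  half <- 0.2 + 4 * sqrt(0.5^2 / 25 + 0.5^2 / 25)
  expect_equal(half, 0.7656854, tolerance = 1e-6)
  expect_equal(or$point, exp(0.5), tolerance = 1e-12)
  expect_equal(c(or$lower, or$upper), exp(0.5 + c(-1, 1) * half),
               tolerance = 1e-9)

  ident <- odds_ratio_between(m1, m1, c = 4)
  expect_equal(ident$point, 1)

  m2z <- m2; m2z$s_theta <- 0; m2z$bias <- 0
  m1z <- m1; m1z$s_theta <- 0; m1z$bias <- 0
  dg <- odds_ratio_between(m1z, m2z, c = 4)
  expect_true(dg$degenerate)
  expect_equal(dg$lower, dg$upper)

  m3 <- bwmort:::new_meta(rep(-3, 5), list(type = "risk", j = 1, x = 3000))
  expect_error(odds_ratio_between(m1, m3, c = 4), "different")
})

test_that("bias adjustment is seed-reproducible and order-invariant", {
  fits <- toy_fits(n_fits = 2, n = 1200)
  ov <- combined_risk(fits)
  targets <- list(list(type = "risk", j = 1, x = 2000),
                  list(type = "risk", j = 2, x = 3200),
                  list(type = "or_within", j1 = 1, j2 = 2, x = 2800))
  b1 <- bias_adjustment(ov, targets, n = 1200, n_sim = 2, seed = 5)
  b2 <- bias_adjustment(ov, targets, n = 1200, n_sim = 2, seed = 5)
  expect_equal(as.numeric(b1), as.numeric(b2))
  expect_true(all(b1 >= 0))

  b3 <- bias_adjustment(ov, rev(targets), n = 1200, n_sim = 2, seed = 5)
  expect_equal(as.numeric(b3), rev(as.numeric(b1)))
})

test_that("pointwise confidence bounds wrap the point curve", {
  fits <- toy_fits(n_fits = 3, n = 1200)
  grid <- seq(1800, 2200, by = 100)
  cb <- confidence_bounds(fits, 1, grid, c = 4, bias = 0.05)
  expect_equal(nrow(cb), length(grid))
  ok <- !is.na(cb$point)
  expect_true(all(cb$lower[ok] <= cb$point[ok]))
  expect_true(all(cb$upper[ok] >= cb$point[ok]))

  # identical fits collapse to the bias-only band
  same <- list(fits[[1]], fits[[1]])
  cb2 <- confidence_bounds(same, 1, grid, c = 4, bias = 0)
  ok2 <- !is.na(cb2$point)
  expect_equal(cb2$lower[ok2], cb2$point[ok2], tolerance = 1e-12)
})

test_that("covariate-within-component probability integrates the risk against the component density", {
  mix <- toy_mixture()
  cf <- const_fit(mix, c(0.37, 0.11))
  expect_equal(covariate_component_probability(cf, 1), 0.37, tolerance = 1e-8)
  expect_equal(covariate_component_probability(cf, 2), 0.11, tolerance = 1e-8)

  # Monte-Carlo oracle for a sloped and a steep curve
  lin <- risk_model(rbind(c(-2, 0.8, 0, 0, 0), c(-3, 0, 0, 0, 0)), mix)
  steep <- risk_model(rbind(c(-1, 4, 0, -2, 0), c(-3, 0, 0, 0, 0)), mix)
  set.seed(17)
  z <- rnorm(1e6)
  for (model in list(lin, steep)) {
    draws <- risk_eval(model, 1, mix$means[1] + mix$sds[1] * z)
    mc <- mean(draws)
    mc_se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(covariate_component_probability(model, 1) - mc), 3 * mc_se)
  }
})
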