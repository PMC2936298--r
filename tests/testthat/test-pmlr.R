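test_that("risk_eval applies the inverse-logit polynomial in standardized birthweight", {
  mix <- mixture_model(c(0.007, 0.182, 0.758, 0.052),
                       c(832, 2772, 3170, 3804), c(210, 740, 417, 413))
  zero <- risk_model(matrix(0, 4, 5), mix)
  expect_equal(risk_eval(zero, 1, 1234), 0.5)
  expect_equal(risk_eval(zero, 3, 100), 0.5)

  coef <- rbind(c(-4.6975, -0.2362, 0.3994, 0.1690, 0.1328),
                c(-4.0962, -0.7496, -0.0289, -0.1094, 0.0918),
                c(-5.7538, -1.7275, 1.6269, 0.1897, -0.0249),
                c(-5.3285, -0.2786, -0.1979, 0.0535, 0.0773))
  r <- risk_model(coef, mix)
  # z = 0 at the component mean: risk equals inverse logit of the intercept
  expect_equal(risk_eval(r, 3, 3170), plogis(-5.7538), tolerance = 1e-12)
  expect_equal(risk_eval(r, 3, 3170), 0.003160687559, tolerance = 1e-9)
  # z = 1: the polynomial is the plain sum of coefficients
  expect_equal(risk_eval(r, 1, 832 + 210), plogis(sum(coef[1, ])),
               tolerance = 1e-12)
  expect_equal(risk_eval(r, 1, 832 + 210), 0.01430835415, tolerance = 1e-9)

  # extreme birthweights stay strictly inside (0, 1) with finite logits
  ext <- risk_eval(r, 1, c(1, 50000))
  expect_true(all(ext > 0 & ext < 1))
  expect_true(all(is.finite(qlogis(ext))))
})

test_that("population_risk is the posterior-weighted combination of component risks", {
  mix1 <- flat_mixture()
  r1 <- flat_risk(0.07)
  xs <- c(2000, 3000, 4100)
  expect_equal(population_risk(r1, xs), risk_eval(r1, 1, xs))

  mix <- toy_mixture()
  same <- const_risk(mix, 0.23)
  expect_equal(population_risk(same, xs), rep(0.23, 3), tolerance = 1e-12)

  # two-component hand computation with constant risks 0.3 / 0.1
  m2 <- mixture_model(c(0.5, 0.5), c(1000, 3000), c(200, 200))
  rc <- risk_model(rbind(c(qlogis(0.3), 0, 0, 0, 0),
                         c(qlogis(0.1), 0, 0, 0, 0)), m2)
  t1 <- 0.5 * dnorm(2000, 1000, 200)
  t2 <- 0.5 * dnorm(2000, 3000, 200)
  expect_equal(population_risk(rc, 2000),
               (0.3 * t1 + 0.1 * t2) / (t1 + t2), tolerance = 1e-12)

  # convex-combination property over random models
  set.seed(8)
  for (rep in 1:10) {
    w <- rexp(2) + 0.2
    mm <- mixture_model(w / sum(w), sort(runif(2, 1000, 4000)),
                        runif(2, 200, 700))
    rr <- risk_model(matrix(rnorm(10, -3, 1), 2, 5), mm)
    x <- runif(5, 200, 5200)
    lo <- pmin(risk_eval(rr, 1, x), risk_eval(rr, 2, x))
    hi <- pmax(risk_eval(rr, 1, x), risk_eval(rr, 2, x))
    pr <- population_risk(rr, x)
    expect_true(all(pr >= lo - 1e-12 & pr <= hi + 1e-12))
  }
})

test_that("pmlr_loglik matches hand-expanded sums on tiny inputs", {
  mix1 <- flat_mixture()
  cm <- matrix(c(-2, 0.5, 0, 0, 0), 1)
  r_at <- function(x) plogis(-2 + 0.5 * (x - 3000) / 400)
  one_death <- birth_records(3400, 1)
  one_surv <- birth_records(3400, 0)
  expect_equal(pmlr_loglik(cm, one_death, mix1), log(r_at(3400)),
               tolerance = 1e-12)
  expect_equal(pmlr_loglik(cm, one_surv, mix1), log(1 - r_at(3400)),
               tolerance = 1e-12)

  # three records, two components, fully hand-expanded
  m2 <- mixture_model(c(0.4, 0.6), c(2000, 3200), c(300, 350))
  cm2 <- rbind(c(qlogis(0.3), 0, 0, 0, 0), c(qlogis(0.05), 0, 0, 0, 0))
  recs <- birth_records(c(1900, 2600, 3300), c(1, 0, 1))
  hand <- 0
  for (i in 1:3) {
    x <- recs$birthweight_g[i]; d <- recs$death[i]
    f1 <- 0.4 * dnorm(x, 2000, 300); f2 <- 0.6 * dnorm(x, 3200, 350)
    R <- (0.3 * f1 + 0.05 * f2) / (f1 + f2)
    hand <- hand + d * log(R) + (1 - d) * log(1 - R)
  }
  expect_equal(pmlr_loglik(cm2, recs, m2), hand, tolerance = 1e-12)
  expect_error(pmlr_loglik(cm2, recs[0, ], m2), "empty")
})

test_that("single-component PMLR on constant-risk data recovers the crude rate", {
  truth <- flat_mixture()
  rec <- simulate_records(truth, flat_risk(0.1), 4000, seed = 31)
  fit <- fit_pmlr(rec, truth, seed = 2)
  crude <- mean(rec$death)
  expect_lt(abs(plogis(fit$coeffs[1, 1]) - crude), 0.02)
  expect_true(all(abs(fit$coeffs[1, -1]) < 0.2))
  expect_gte(fit$loglik, fit$init_loglik)
})

test_that("single-component PMLR agrees with an independent polynomial-logistic fit", {
  truth <- flat_mixture()
  set.seed(61)
  x <- rnorm(4000, 3000, 400)
  z <- (x - 3000) / 400
  p <- plogis(-2.5 - 0.4 * z + 0.3 * z^2)
  rec <- birth_records(x, rbinom(4000, 1, p))
  fit <- fit_pmlr(rec, truth, seed = 2, opts = list(ridge = 0))
  ref <- glm(rec$death ~ poly(z, 4, raw = TRUE), family = binomial)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$coeffs[1, ]), unname(coef(ref)), tolerance = 1e-2)
})

test_that("PMLR rejects degenerate outcomes and flags event-poor components", {
  truth <- flat_mixture()
  all_dead <- birth_records(rnorm(100, 3000, 400), rep(1, 100))
  expect_error(fit_pmlr(all_dead, truth), "survival")
  none_dead <- birth_records(rnorm(100, 3000, 400), rep(0, 100))
  expect_error(fit_pmlr(none_dead, truth), "events")

  # a tiny far-off component with essentially no deaths is left unestimated
  mix <- mixture_model(c(0.97, 0.03), c(3000, 6000), c(300, 100))
  set.seed(3)
  x <- c(rnorm(2900, 3000, 300), rnorm(100, 6000, 100))
  d <- c(rbinom(2900, 1, 0.1), rep(0, 100))
  fit <- suppressWarnings(fit_pmlr(birth_records(x, d), mix, seed = 5))
  expect_false(fit$estimable[2])
  expect_true(fit$estimable[1])
  expect_true(all(is.na(fit$coeffs[2, ])))
  expect_error(risk_eval(fit, 2, 6000), "unestimated")
})

test_that("fitted PMLR log-likelihood never falls below its initialization", {
  fits <- toy_fits(n_fits = 2, n = 1200)
  for (f in fits) expect_gte(f$loglik, f$init_loglik)
})

test_that("empirical_mortality bins are half-open, zero-anchored, and conserving", {
  rec <- birth_records(c(2450, 2499), c(1, 0))
  em <- empirical_mortality(rec)
  row <- em[em$bin_lower == 2400, ]
  expect_equal(row$births, 2L)
  expect_equal(row$deaths, 1L)
  expect_equal(row$rate, 0.5)

  rec2 <- birth_records(c(500, 2550, 2600), c(0, 1, 0))
  em2 <- empirical_mortality(rec2)
  expect_equal(sum(em2$births), 3L)
  expect_equal(sum(em2$deaths), 1L)
  empty <- em2[em2$bin_lower == 1000, ]
  expect_equal(empty$births, 0L)
  expect_true(is.na(empty$rate))
  # boundary record lands in the bin whose lower edge it equals
  expect_equal(em2$bin_lower[1], 500)
})

test_that("curve_support clips to positive birthweights", {
  mix <- mixture_model(c(0.007, 0.182, 0.758, 0.052),
                       c(832, 2772, 3170, 3804), c(210, 740, 417, 413))
  expect_equal(unname(curve_support(mix, 1, 3)), c(202, 1462))
  expect_equal(unname(curve_support(mix, 1, 0)), c(832, 832))
  low <- mixture_model(c(0.5, 0.5), c(500, 3000), c(300, 300))
  expect_equal(unname(curve_support(low, 1, 3)), c(0, 1400))
})

test_that("model-implied mortality tracks binned empirical mortality on simulated data", {
  spec <- toy_scenario()
  rec <- simulate_records(spec$mixture, spec$risk, 20000, seed = 12)
  mix <- fit_mixture_em(rec, 2, seed = 3)
  fit <- fit_pmlr(rec, mix, seed = 3)
  binned <- empirical_mortality(rec)
  big <- binned[binned$births >= 500, ]
  mids <- (big$bin_lower + big$bin_upper) / 2
  pred <- population_risk(fit, mids)
  se <- sqrt(pred * (1 - pred) / big$births)
  expect_true(all(abs(pred - big$rate) <= 3 * se))
})

test_that("export_risk_curves reports per-component curves with support flags", {
  r <- toy_risk()
  curves <- export_risk_curves(r, grid = seq(1000, 4000, by = 500))
  expect_equal(nrow(curves), 2 * 7)
  expect_true(all(curves$risk > 0 & curves$risk < 1))
  c1 <- curves[curves$component == 1, ]
  supp <- curve_support(r$mixture, 1, 3)
  expect_equal(c1$in_support, c1$birthweight_g >= supp[1] & c1$birthweight_g <= supp[2])
})
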