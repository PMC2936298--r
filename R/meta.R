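# Multi-sample ("meta-sample") inference: combining per-sample PMLR fits on
# the logit scale, bias adjustment by parametric simulation, overlap-corrected
# interval constants, and odds ratios within and between populations.

# Is component j's curve usable at birthweight x in this per-sample fit?
# Requires the component to have been estimated and x to lie inside the
# component's supported range of the *sample's own* mixture fit.
component_defined_at <- function(fit, j, x, support_c = 3) {
  if (!fit$estimable[j]) return(FALSE)
  supp <- curve_support(fit$mixture, j, support_c)
  x >= supp[1] && x <= supp[2]
}

#' Combine per-sample risk estimates on the logit scale
#'
#' Given PMLR fits from `N_rep` samples of the same population, forms the
#' meta-sample of per-sample logit risks at a target (component j,
#' birthweight x): the overall point estimate is the inverse logit of their
#' mean. Samples in which the component is unestimated, or in which x falls
#' outside the component's supported range, are excluded with a warning and
#' the effective `N_rep` reduced.
#'
#' @param fits List of fitted `bw_risk` objects (component labels aligned by
#'   the mean-ordering convention).
#' @param j Component index.
#' @param x Target birthweight in grams (scalar).
#' @param support_c Support half-width in component standard deviations.
#' @return An object of class `bw_meta`: `thetas` (per-sample logit risks),
#'   `theta_bar`, `s_theta`, `n_rep` (effective), `n_rep_total`, `bias`
#'   (0 until set via [bias_adjustment()]), `estimate` (probability scale),
#'   and the target descriptor.
#' @export
combine_risk_estimates <- function(fits, j, x, support_c = 3) {
  stopifnot(length(x) == 1L, length(fits) >= 1L)
  keep <- vapply(fits, component_defined_at, logical(1), j = j, x = x,
                 support_c = support_c)
  if (!all(keep)) {
    warning(sprintf("component %d undefined at %g g in %d of %d samples; excluded",
                    j, x, sum(!keep), length(fits)))
  }
  if (sum(keep) == 0L || (length(fits) >= 2L && sum(keep) < 2L)) {
    stop("fewer than 2 samples retain the target; cannot combine")
  }
  thetas <- vapply(fits[keep], function(f) logit(risk_eval(f, j, x)), numeric(1))
  new_meta(thetas, target = list(type = "risk", j = j, x = x),
           n_rep_total = length(fits))
}

new_meta <- function(thetas, target, n_rep_total = length(thetas)) {
  structure(
    list(target = target, thetas = thetas, theta_bar = mean(thetas),
         s_theta = if (length(thetas) > 1L) stats::sd(thetas) else 0,
         n_rep = length(thetas), n_rep_total = n_rep_total, bias = 0,
         estimate = inv_logit(mean(thetas))),
    class = "bw_meta")
}

#' @export
print.bw_meta <- function(x, ...) {
  cat(sprintf("meta-sample estimate (%s): theta_bar = %.4f, s_theta = %.4f, n_rep = %d%s\n",
              paste(deparse(x$target), collapse = ""), x$theta_bar, x$s_theta,
              x$n_rep,
              if (x$bias > 0) sprintf(", bias = %.4f", x$bias) else ""))
  invisible(x)
}

#' Overlap-corrected interval constant
#'
#' When the `N_rep` samples each constitute a fraction `phi` of a finite
#' population, the calibration constant for the nominal-coverage interval is
#' \eqn{C_\phi = C_0\,\phi N_{rep} / \{1 - (1-\phi)^{N_{rep}}\}}. As
#' \eqn{\phi \to 0} (effectively infinite population) this tends to
#' \eqn{C_0}; `phi = 0` is accepted and returns `c0`.
#'
#' @param c0 The constant appropriate for non-overlapping samples.
#' @param phi Fraction of the population each sample constitutes, in [0, 1).
#' @param n_rep Number of samples.
#' @return The corrected constant.
#' @export
overlap_constant <- function(c0, phi, n_rep) {
  stopifnot(c0 > 0, n_rep >= 1L)
  if (phi < 0 || phi >= 1) stop("`phi` must lie in [0, 1)")
  if (phi == 0) return(c0)
  c0 * phi * n_rep / (1 - (1 - phi)^n_rep)
}

#' Logit-scale confidence interval for a meta-sample target
#'
#' The interval is `theta_bar` plus/minus `bias + c * s_theta / sqrt(n_rep)`;
#' with `use_bias = FALSE` the bias term is dropped (the narrower,
#' unadjusted interval, always contained in the adjusted one).
#'
#' @param meta A `bw_meta` (its `bias` field is used when `use_bias = TRUE`).
#' @param c Calibration constant (e.g. `C_0` or [overlap_constant()]).
#' @param use_bias Include the bias adjustment in the half-width?
#' @return An object of class `bw_interval` on the logit scale with fields
#'   `point`, `lower`, `upper`, `scale`, `c_used`, `degenerate`.
#' @export
ci_theta <- function(meta, c, use_bias = TRUE) {
  stopifnot(inherits(meta, "bw_meta"), c > 0)
  b <- if (isTRUE(use_bias)) meta$bias else 0
  stopifnot(b >= 0)
  half <- b + c * meta$s_theta / sqrt(meta$n_rep)
  structure(
    list(point = meta$theta_bar, lower = meta$theta_bar - half,
         upper = meta$theta_bar + half, scale = "logit", c_used = c,
         bias_used = b, degenerate = half == 0, target = meta$target,
         n_rep = meta$n_rep),
    class = "bw_interval")
}

#' @export
print.bw_interval <- function(x, ...) {
  cat(sprintf("%s-scale interval: %.4g (%.4g, %.4g)%s\n", x$scale, x$point,
              x$lower, x$upper, if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Probability-scale confidence interval for a component risk
#'
#' Applies the inverse logit transformation to the endpoints of the
#' logit-scale interval; monotonicity preserves their order.
#'
#' @inheritParams ci_theta
#' @return A `bw_interval` on the probability scale.
#' @export
risk_interval <- function(meta, c, use_bias = TRUE) {
  ci <- ci_theta(meta, c, use_bias)
  ci$point <- inv_logit(ci$point)
  ci$lower <- inv_logit(ci$lower)
  ci$upper <- inv_logit(ci$upper)
  ci$scale <- "probability"
  ci
}

# --- combined (overall) risk across samples --------------------------------

#' Overall risk model combining per-sample PMLR fits
#'
#' The overall curve for component j is the inverse logit of the mean of the
#' per-sample logit curves (evaluated pointwise over the samples where the
#' component was estimated); the overall mixture averages the per-sample
#' mixture parameters. This is the object used to simulate data for the bias
#' adjustment and to report overall curves.
#'
#' @param fits List of fitted `bw_risk` objects from `N_rep` samples.
#' @return An object of class `bw_meta_risk` usable with [risk_eval()] and
#'   [simulate_records()]; its `mixture` is the parameter-averaged mixture.
#' @export
combined_risk <- function(fits) {
  stopifnot(length(fits) >= 1L)
  k <- fits[[1L]]$mixture$k
  stopifnot(all(vapply(fits, function(f) f$mixture$k, integer(1)) == k))
  w <- rowMeans(vapply(fits, function(f) f$mixture$weights, numeric(k)))
  mu <- rowMeans(vapply(fits, function(f) f$mixture$means, numeric(k)))
  s <- rowMeans(vapply(fits, function(f) f$mixture$sds, numeric(k)))
  est <- rowSums(vapply(fits, function(f) f$estimable, logical(k))) > 0
  if (k == 1L) { w <- mean(w); mu <- mean(mu); s <- mean(s) }
  fb <- vapply(fits, function(f) f$fallback_intercept %||% NA_real_, numeric(1))
  structure(
    list(fits = fits, mixture = mixture_model(w, mu, s),
         estimable = est, n_rep = length(fits),
         fallback_intercept = if (all(is.na(fb))) NULL else mean(fb, na.rm = TRUE)),
    class = "bw_meta_risk")
}

#' @export
risk_eval.bw_meta_risk <- function(risk, j, x) {
  stopifnot(j >= 1L, j <= risk$mixture$k)
  if (!risk$estimable[j]) {
    stop(sprintf("component %d is unestimated in every sample", j))
  }
  use <- Filter(function(f) f$estimable[j], risk$fits)
  th <- vapply(use, function(f) logit(risk_eval(f, j, x)), numeric(length(x)))
  if (is.null(dim(th))) th <- matrix(th, nrow = length(x))
  inv_logit(rowMeans(th))
}

#' Simulation-based bias adjustment for meta-sample targets
#'
#' Generates `n_sim` synthetic data sets of size `n` from the overall mixture
#' with outcomes from the overall risk curves, refits the mixture (same k)
#' and PMLR to each, and for every target takes the mean absolute deviation
#' between the refitted logit-scale estimate and the overall estimate. One
#' shared bank of simulations serves all targets.
#'
#' @param overall_risk A [combined_risk()] (or single `bw_risk`) providing
#'   both the overall mixture and the overall curves.
#' @param targets List of target descriptors: `list(type = "risk", j, x)` or
#'   `list(type = "or_within", j1, j2, x)`.
#' @param n Size of each simulated data set (the per-sample size).
#' @param n_sim Number of simulated data sets (default 5).
#' @param seed Integer seed.
#' @param fit_opts,em_args Optional settings passed to [fit_pmlr()] /
#'   [fit_mixture_em()] for the refits.
#' @return Numeric vector of nonnegative biases, one per target (`NA` for a
#'   target undefined in every simulation), with attribute `n_sim_effective`.
#' @export
bias_adjustment <- function(overall_risk, targets, n, n_sim = 5L, seed = 1L,
                            fit_opts = list(), em_args = list()) {
  stopifnot(n_sim >= 1L, length(targets) >= 1L)
  mix <- overall_risk$mixture
  k <- mix$k

  target_theta <- function(risk, tg) {
    ok <- function(j) risk$estimable[j]
    if (tg$type == "risk") {
      if (!ok(tg$j)) return(NA_real_)
      logit(risk_eval(risk, tg$j, tg$x))
    } else if (tg$type == "or_within") {
      if (!ok(tg$j1) || !ok(tg$j2)) return(NA_real_)
      logit(risk_eval(risk, tg$j1, tg$x)) - logit(risk_eval(risk, tg$j2, tg$x))
    } else stop("unknown target type: ", tg$type)
  }

  theta_hat <- vapply(targets, function(tg) target_theta(overall_risk, tg),
                      numeric(1))
  dev <- matrix(NA_real_, n_sim, length(targets))
  n_fail <- 0L
  for (s in seq_len(n_sim)) {
    res <- tryCatch({
      rec <- simulate_records(mix, overall_risk, n, seed = derive_seed(seed, s))
      m <- do.call(fit_mixture_em,
                   c(list(records = rec, k = k, seed = derive_seed(seed, 500L + s)),
                     em_args))
      r <- fit_pmlr(rec, m, opts = fit_opts, seed = derive_seed(seed, 900L + s))
      vapply(targets, function(tg) target_theta(r, tg), numeric(1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      warning("bias simulation ", s, " failed and was dropped: ",
              conditionMessage(res))
      next
    }
    dev[s, ] <- abs(res - theta_hat)
  }
  if (n_fail == n_sim) stop("every bias simulation failed")
  bias <- colMeans(dev, na.rm = TRUE)
  bias[is.nan(bias)] <- NA_real_
  attr(bias, "n_sim_effective") <- colSums(!is.na(dev))
  bias
}

#' Pointwise confidence bounds for a component risk curve
#'
#' Applies [combine_risk_estimates()], [ci_theta()] and [risk_interval()] at
#' every grid point; connecting the per-point limits yields lower and upper
#' confidence bounds for the curve.
#'
#' @inheritParams combine_risk_estimates
#' @param grid Birthweight grid in grams.
#' @param c Calibration constant.
#' @param bias Nonnegative bias, scalar or one value per grid point.
#' @param use_bias Include the bias term?
#' @return Data frame with columns `birthweight_g`, `point`, `lower`,
#'   `upper` (probability scale), `n_rep_effective`; rows where the target is
#'   undefined in (nearly) all samples carry `NA`.
#' @export
confidence_bounds <- function(fits, j, grid, c, bias = 0, use_bias = TRUE,
                              support_c = 3) {
  bias <- rep_len(bias, length(grid))
  rows <- lapply(seq_along(grid), function(i) {
    meta <- tryCatch(
      suppressWarnings(combine_risk_estimates(fits, j, grid[i], support_c)),
      error = function(e) NULL)
    if (is.null(meta)) {
      return(data.frame(birthweight_g = grid[i], point = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        n_rep_effective = 0L))
    }
    meta$bias <- bias[i]
    ci <- risk_interval(meta, c, use_bias)
    data.frame(birthweight_g = grid[i], point = ci$point, lower = ci$lower,
               upper = ci$upper, n_rep_effective = meta$n_rep)
  })
  do.call(rbind, rows)
}

#' Odds ratio comparing two components of the same population
#'
#' The per-sample statistic is the difference of logit risks at `x0`,
#' \eqn{\theta_s = \mathrm{logit}\,\hat r_{j_1;s}(x_0) -
#' \mathrm{logit}\,\hat r_{j_2;s}(x_0)}; the point estimate is
#' \eqn{\exp(\bar\theta)} and the interval exponentiates the bias-adjusted
#' logit-scale interval. Samples where either component is undefined at `x0`
#' are excluded.
#'
#' @inheritParams combine_risk_estimates
#' @param j1,j2 Component indices (numerator, denominator).
#' @param x0 Birthweight in grams.
#' @param c Calibration constant.
#' @param bias Nonnegative bias for the composite logit-difference target
#'   (from [bias_adjustment()] with an `or_within` target).
#' @return A `bw_interval` on the odds-ratio scale; also carries the
#'   underlying `bw_meta` as `$meta`.
#' @export
odds_ratio_within <- function(fits, j1, j2, x0, c, bias = 0, support_c = 3) {
  keep <- vapply(fits, function(f) {
    component_defined_at(f, j1, x0, support_c) &&
      component_defined_at(f, j2, x0, support_c)
  }, logical(1))
  if (!all(keep)) {
    warning(sprintf("components (%d, %d) undefined at %g g in %d of %d samples; excluded",
                    j1, j2, x0, sum(!keep), length(fits)))
  }
  if (sum(keep) == 0L || (length(fits) >= 2L && sum(keep) < 2L)) {
    stop("fewer than 2 samples retain the target; cannot combine")
  }
  thetas <- vapply(fits[keep], function(f) {
    logit(risk_eval(f, j1, x0)) - logit(risk_eval(f, j2, x0))
  }, numeric(1))
  meta <- new_meta(thetas, target = list(type = "or_within", j1 = j1, j2 = j2,
                                         x = x0),
                   n_rep_total = length(fits))
  meta$bias <- bias
  ci <- ci_theta(meta, c, use_bias = TRUE)
  out <- structure(
    list(point = exp(ci$point), lower = exp(ci$lower), upper = exp(ci$upper),
         scale = "odds_ratio", c_used = c, bias_used = bias,
         degenerate = ci$degenerate, target = meta$target, n_rep = meta$n_rep,
         meta = meta),
    class = "bw_interval")
  out
}

#' Odds ratio comparing the same component of two populations
#'
#' Point estimate \eqn{\exp(\bar\theta_1 - \bar\theta_2)}; the log-scale
#' half-width sums the two populations' bias adjustments and combines their
#' meta-sample spreads,
#' \eqn{\hat B_1 + \hat B_2 + C\sqrt{S_1^2/N_{rep,1} + S_2^2/N_{rep,2}}}.
#'
#' @param meta1,meta2 `bw_meta` objects for the same component index and
#'   birthweight from two populations (their `bias` fields are used).
#' @param c Calibration constant.
#' @return A `bw_interval` on the odds-ratio scale.
#' @export
odds_ratio_between <- function(meta1, meta2, c) {
  stopifnot(inherits(meta1, "bw_meta"), inherits(meta2, "bw_meta"), c > 0)
  t1 <- meta1$target; t2 <- meta2$target
  if (!identical(t1$type, t2$type) || !identical(t1$j, t2$j) ||
      !isTRUE(all.equal(t1$x, t2$x))) {
    stop("meta estimates target different components/birthweights")
  }
  d <- meta1$theta_bar - meta2$theta_bar
  half <- meta1$bias + meta2$bias +
    c * sqrt(meta1$s_theta^2 / meta1$n_rep + meta2$s_theta^2 / meta2$n_rep)
  structure(
    list(point = exp(d), lower = exp(d - half), upper = exp(d + half),
         scale = "odds_ratio", c_used = c,
         bias_used = meta1$bias + meta2$bias, degenerate = half == 0,
         target = t1, n_rep = c(meta1$n_rep, meta2$n_rep)),
    class = "bw_interval")
}

#' Probability of a binary covariate within a mixture component
#'
#' For a risk model fitted with a binary covariate (e.g. preterm birth) as
#' the outcome, integrates \eqn{\hat r_j(x) f(x; \hat\mu_j, \hat\sigma_j)}
#' over the component's birthweight distribution (numerically, over
#' \eqn{\mu_j \pm 8\sigma_j}), giving the estimated covariate frequency
#' within component j.
#'
#' @param cov_risk A fitted `bw_risk` (or [combined_risk()]) whose outcome is
#'   the covariate.
#' @param j Component index.
#' @return A probability in (0, 1).
#' @export
covariate_component_probability <- function(cov_risk, j) {
  mix <- cov_risk$mixture
  stopifnot(j >= 1L, j <= mix$k)
  mu <- mix$means[j]; s <- mix$sds[j]
  q <- stats::integrate(function(x) risk_eval(cov_risk, j, x) * stats::dnorm(x, mu, s),
                        lower = mu - 8 * s, upper = mu + 8 * s,
                        rel.tol = 1e-9, abs.tol = 1e-12)
  if (q$message != "OK") {
    stop("quadrature failed for component ", j, ": ", q$message,
         " (abs.error = ", signif(q$abs.error, 3), ")")
  }
  q$value
}
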