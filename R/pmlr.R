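#' Component-specific birthweight mortality risk model
#'
#' Holds, for each mixture component j, the coefficients of a polynomial
#' \eqn{p_j(z)} in the standardized birthweight \eqn{z_j = (x - \mu_j)/\sigma_j},
#' defining the risk curve \eqn{r_j(x) = \mathrm{logit}^{-1}[p_j(z_j)]}.
#' Per-component standardization keeps coefficients on comparable scales and
#' conditions the optimization. Components without enough mortality
#' information to support a curve are flagged unestimated (`estimable`).
#'
#' @param coeffs k x (degree+1) matrix of polynomial coefficients, ascending
#'   powers of z (intercept first); one row per mixture component. Rows of a
#'   component marked unestimable may be `NA`.
#' @param mixture The [mixture_model()] the risk model is conditioned on.
#' @param degree Polynomial degree (default 4, allowing up to two changes of
#'   convexity per curve).
#' @param estimable Logical vector of length k; defaults to all `TRUE`.
#' @return An object of class `bw_risk`.
#' @export
risk_model <- function(coeffs, mixture, degree = 4L, estimable = NULL) {
  stopifnot(inherits(mixture, "bw_mixture"))
  coeffs <- as.matrix(coeffs)
  degree <- as.integer(degree)
  if (nrow(coeffs) != mixture$k) {
    stop("`coeffs` needs one row per mixture component")
  }
  if (ncol(coeffs) != degree + 1L) {
    stop("`coeffs` needs degree + 1 columns (ascending powers of z)")
  }
  estimable <- estimable %||% rep(TRUE, mixture$k)
  stopifnot(length(estimable) == mixture$k)
  if (any(!is.finite(coeffs[estimable, , drop = FALSE]))) {
    stop("coefficients of estimable components must be finite")
  }
  structure(
    list(coeffs = coeffs, degree = degree, mixture = mixture,
         estimable = as.logical(estimable),
         loglik = NA_real_, init_loglik = NA_real_, converged = NA,
         vcov = NULL, expected_deaths = NULL),
    class = "bw_risk")
}

#' @export
print.bw_risk <- function(x, ...) {
  cat(sprintf("PMLR risk model: degree-%d polynomials in z over %d components\n",
              x$degree, x$mixture$k))
  for (j in seq_len(x$mixture$k)) {
    if (x$estimable[j]) {
      cat(sprintf("  comp%d: r(mu_j) = %.5f  [%s]\n", j,
                  inv_logit(x$coeffs[j, 1]),
                  paste(sprintf("%.4f", x$coeffs[j, ]), collapse = ", ")))
    } else {
      cat(sprintf("  comp%d: unestimated (too few expected deaths)\n", j))
    }
  }
  if (is.finite(x$loglik)) cat(sprintf("log-likelihood %.3f\n", x$loglik))
  invisible(x)
}

# Horner evaluation of ascending-power coefficients at z (vectorized).
poly_eval <- function(coef, z) {
  out <- rep(coef[length(coef)], length(z))
  for (m in rev(seq_len(length(coef) - 1L))) out <- out * z + coef[m]
  out
}

#' Evaluate a component risk curve
#'
#' @param risk A `bw_risk` (or combined multi-sample risk) object.
#' @param j Component index.
#' @param x Birthweights in grams (vectorized).
#' @return Risk probabilities strictly in (0, 1).
#' @export
risk_eval <- function(risk, j, x) UseMethod("risk_eval")

#' @export
risk_eval.bw_risk <- function(risk, j, x) {
  stopifnot(j >= 1L, j <= risk$mixture$k)
  if (!risk$estimable[j]) {
    stop(sprintf("component %d is unestimated in this risk model", j))
  }
  z <- (x - risk$mixture$means[j]) / risk$mixture$sds[j]
  # clamp the linear predictor so the risk stays strictly inside (0, 1) and
  # its logit stays finite: beyond |p| ~ 36 the inverse logit rounds to an
  # exact 0 or 1 in double precision
  inv_logit(pmin(pmax(poly_eval(risk$coeffs[j, ], z), -33), 33))
}

#' Population (model-implied) mortality risk at a birthweight
#'
#' The overall risk function, by the law of total probability: the posterior
#' component probabilities at `x` weighting the component risk curves,
#' \eqn{\sum_j r_j(x)\, w_j f(x;\mu_j,\sigma_j) / \sum_j w_j f(x;\mu_j,\sigma_j)}.
#'
#' @inheritParams risk_eval
#' @param x Birthweights in grams (vectorized).
#' @return Probabilities in (0, 1), one per element of `x`.
#' @export
population_risk <- function(risk, x) {
  mix <- risk$mixture
  tau <- posterior_weights(x, mix)
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = length(x), byrow = length(x) == 1L)
  r <- vapply(seq_len(mix$k), function(j) risk_eval(risk, j, x),
              numeric(length(x)))
  if (is.null(dim(r))) r <- matrix(r, nrow = length(x))
  rowSums(tau * r)
}

# Precomputed quantities the PMLR objective reuses on every evaluation:
# posterior weights tau (n x k) and per-component design matrices in powers
# of z (each n x (degree+1)). These depend only on the conditioning mixture.
pmlr_workspace <- function(x, mixture, degree) {
  k <- mixture$k
  tau <- posterior_weights(x, mixture)
  if (is.null(dim(tau))) tau <- matrix(tau, nrow = length(x), byrow = length(x) == 1L)
  X <- vector("list", k)
  for (j in seq_len(k)) {
    z <- (x - mixture$means[j]) / mixture$sds[j]
    X[[j]] <- outer(z, 0:degree, `^`)
  }
  list(tau = tau, X = X, k = k, p = degree + 1L)
}

# Marginal Bernoulli log-likelihood with success probability
# R(x) = sum_j tau_j(x) r_j(x); `coefmat` is k x (degree+1).
pmlr_loglik_ws <- function(coefmat, d, ws) {
  R <- numeric(length(d))
  for (j in seq_len(ws$k)) {
    R <- R + ws$tau[, j] * inv_logit(drop(ws$X[[j]] %*% coefmat[j, ]))
  }
  R <- pmin(pmax(R, 1e-14), 1 - 1e-14)
  sum(d * log(R) + (1 - d) * log1p(-R))
}

pmlr_grad_ws <- function(coefmat, d, ws, free) {
  n <- length(d)
  r <- matrix(NA_real_, n, ws$k)
  for (j in seq_len(ws$k)) {
    r[, j] <- inv_logit(drop(ws$X[[j]] %*% coefmat[j, ]))
  }
  R <- pmin(pmax(rowSums(ws$tau * r), 1e-14), 1 - 1e-14)
  W <- d / R - (1 - d) / (1 - R)
  g <- matrix(0, ws$k, ws$p)
  for (j in which(free)) {
    g[j, ] <- drop(crossprod(ws$X[[j]], W * ws$tau[, j] * r[, j] * (1 - r[, j])))
  }
  g
}

# EM for the PMLR objective with fixed mixture posteriors tau: treating the
# record's component as missing data, the E-step reweights tau by the
# outcome (eta_ij proportional to tau_ij r_ij for deaths, tau_ij (1 - r_ij)
# for survivors) and the M-step is one weighted polynomial-logistic
# regression per free component. The marginal log-likelihood is monotone
# non-decreasing across iterations.
ridge_pen <- function(coefmat, free, lambda) {
  lambda * sum(coefmat[free, , drop = FALSE]^2)
}

pmlr_em <- function(coefmat, d, ws, free, maxit = 100L, reltol = 1e-8,
                    lambda = 0) {
  ll_old <- pmlr_loglik_ws(coefmat, d, ws) - ridge_pen(coefmat, free, lambda)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    r <- matrix(NA_real_, length(d), ws$k)
    for (j in seq_len(ws$k)) {
      r[, j] <- inv_logit(drop(ws$X[[j]] %*% coefmat[j, ]))
    }
    r <- pmin(pmax(r, 1e-12), 1 - 1e-12)
    num <- ws$tau * ifelse(d == 1, r, 1 - r)
    eta <- num / rowSums(num)
    new_cm <- coefmat
    for (j in which(free)) {
      w_j <- eta[, j]
      keep <- w_j > 1e-12
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(
          ws$X[[j]][keep, , drop = FALSE], d[keep], weights = w_j[keep],
          family = stats::quasibinomial(), start = coefmat[j, ],
          control = stats::glm.control(maxit = 10L))),
        error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(fit$coefficients))) {
        new_cm[j, ] <- fit$coefficients
      }
    }
    ll_new <- pmlr_loglik_ws(new_cm, d, ws) - ridge_pen(new_cm, free, lambda)
    if (ll_new < ll_old) break  # quasi-step failed to improve; polish takes over
    coefmat <- new_cm
    if (ll_new - ll_old < reltol * (abs(ll_old) + reltol)) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  list(coefmat = coefmat, loglik = ll_old, converged = converged)
}

#' PMLR log-likelihood of candidate risk coefficients
#'
#' The marginal Bernoulli log-likelihood of the death indicators where the
#' success probability at each birthweight is the posterior-weighted average
#' of the component risks, conditional on the fitted mixture:
#' \eqn{\sum_i d_i \log R(x_i) + (1-d_i)\log\{1-R(x_i)\}} with
#' \eqn{R(x) = \sum_j \tau_j(x) r_j(x)}.
#'
#' @param coeffs k x (degree+1) coefficient matrix (ascending powers of z).
#' @param records A [birth_records()] data frame.
#' @param mixture The conditioning [mixture_model()].
#' @return The log-likelihood (finite for finite coefficients).
#' @export
pmlr_loglik <- function(coeffs, records, mixture) {
  records <- as_birth_records(records)
  if (nrow(records) == 0L) stop("`records` is empty")
  coeffs <- as.matrix(coeffs)
  ws <- pmlr_workspace(records$birthweight_g, mixture, ncol(coeffs) - 1L)
  pmlr_loglik_ws(coeffs, records$death, ws)
}

#' Fit component-specific mortality curves by maximum likelihood (PMLR)
#'
#' Stage 2 of the two-stage procedure: conditional on the fitted mixture,
#' maximizes the marginal Bernoulli likelihood (see [pmlr_loglik()]) over the
#' per-component polynomial coefficients. Two starting points compete by
#' default: a flat start with every intercept at the logit of the overall
#' crude death rate, and a classification start fitting each component's
#' polynomial to the records it dominates; additional starts (`opts$n_start`)
#' jitter the flat start. The optimizer exploits the missing-component EM
#' structure of the objective
#' (E-step: outcome-reweighted mixture posteriors; M-step: one weighted
#' polynomial-logistic regression per component), followed by a quasi-Newton
#' polish of the marginal likelihood using the analytic gradient.
#'
#' Components whose posterior-weighted observed death count falls below
#' `opts$min_expected_deaths` (default 5) carry too little mortality
#' information for a stable curve: they are held at the constant
#' crude-rate risk during optimization and flagged unestimated in the result.
#'
#' @param records A [birth_records()] data frame with at least one death and
#'   one survival.
#' @param mixture The conditioning [mixture_model()].
#' @param degree Polynomial degree (default 4).
#' @param outcome Column used as the binary outcome: `"death"` (default) or
#'   `"covariate"` (e.g. preterm birth instead of mortality).
#' @param opts List of optimizer settings: `em_maxit` (EM iterations,
#'   default 100), `bfgs_maxit` (default 300), `reltol` (default 1e-8),
#'   `n_start` (default 2: flat + classification), `jitter_sd` (default 0.5),
#'   `min_expected_deaths` (default 5), `ridge` (weak L2 penalty on the
#'   coefficients, default 1e-3, which keeps a curve finite where an
#'   overlapping component can absorb all its events and the unpenalized
#'   estimate would diverge), `hessian` (default FALSE; when TRUE the
#'   coefficient covariance matrix from the observed information of the
#'   penalized objective is stored in `$vcov`).
#' @param seed Integer seed for multi-start jitter.
#' @return A fitted `bw_risk` with `loglik`, `init_loglik`, `converged`,
#'   `estimable`, and `expected_deaths`.
#' @export
fit_pmlr <- function(records, mixture, degree = 4L, outcome = c("death", "covariate"),
                     opts = list(), seed = 1L) {
  records <- as_birth_records(records)
  outcome <- match.arg(outcome)
  if (outcome == "covariate" && is.null(records$covariate)) {
    stop("records have no `covariate` column")
  }
  d <- records[[outcome]]
  if (sum(d) == 0) stop("no events in the outcome: risk curves are unidentifiable")
  if (sum(1 - d) == 0) stop("no survivals in the outcome: risk curves are unidentifiable")
  o <- list(em_maxit = 100L, bfgs_maxit = 300L, reltol = 1e-8,
            n_start = 2L, jitter_sd = 0.5, min_expected_deaths = 5,
            ridge = 1e-3, hessian = FALSE)
  o[names(opts)] <- opts
  degree <- as.integer(degree)
  x <- records$birthweight_g
  ws <- pmlr_workspace(x, mixture, degree)
  k <- ws$k
  p <- ws$p

  expd <- colSums(ws$tau * d)
  estimable <- expd >= o$min_expected_deaths
  if (!any(estimable)) stop("no component has enough events to estimate a curve")
  free <- estimable

  crude <- logit(mean(d))
  base <- matrix(0, k, p)
  base[, 1] <- crude  # unestimable components stay at the crude constant risk

  pack <- function(cm) as.vector(t(cm[free, , drop = FALSE]))
  unpack <- function(par) {
    cm <- base
    cm[free, ] <- matrix(par, nrow = sum(free), byrow = TRUE)
    cm
  }
  fn <- function(par) {
    cm <- unpack(par)
    -(pmlr_loglik_ws(cm, d, ws) - ridge_pen(cm, free, o$ridge))
  }
  gr <- function(par) {
    g <- pmlr_grad_ws(unpack(par), d, ws, free)
    -as.vector(t(g[free, , drop = FALSE])) + 2 * o$ridge * par
  }

  # start 1: every curve at the constant crude rate; start 2: per-component
  # polynomial-logistic fits on hard-assigned records (each component fit to
  # the records it dominates, a classification-style start that seeds the
  # curve shapes the components' own data suggest); further starts jitter
  # the crude start.
  starts <- list(base)
  cls <- base
  lab <- max.col(ws$tau)
  for (j in which(free)) {
    idx <- lab == j
    if (sum(d[idx]) >= 3 && sum(1 - d[idx]) >= 3) {
      g <- tryCatch(
        suppressWarnings(stats::glm.fit(
          ws$X[[j]][idx, , drop = FALSE], d[idx], family = stats::binomial(),
          control = stats::glm.control(maxit = 25L))),
        error = function(e) NULL)
      cf <- g$coefficients
      if (!is.null(g) && all(is.finite(cf)) && all(abs(cf) < 30)) {
        cls[j, ] <- cf
      }
    }
  }
  starts[[2L]] <- cls
  if (o$n_start > 2L) {
    for (i in seq_len(o$n_start - 2L)) {
      jit <- with_seed(derive_seed(seed, 100L + i),
                       matrix(stats::rnorm(k * p, 0, o$jitter_sd), k, p))
      cm <- base
      cm[free, ] <- cm[free, ] + jit[free, ]
      starts[[i + 2L]] <- cm
    }
  }

  init_ll <- pmlr_loglik_ws(base, d, ws)
  best <- NULL
  for (cm0 in starts) {
    em <- pmlr_em(cm0, d, ws, free, maxit = o$em_maxit, reltol = o$reltol,
                  lambda = o$ridge)
    qb <- stats::optim(pack(em$coefmat), fn, gr, method = "BFGS",
                       control = list(maxit = o$bfgs_maxit, reltol = o$reltol))
    cand <- if (-qb$value >= em$loglik) {
      list(par = qb$par, value = qb$value, converged = qb$convergence == 0L)
    } else {
      list(par = pack(em$coefmat), value = -em$loglik, converged = em$converged)
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  conv <- best$converged
  if (!conv) warning("PMLR optimizer did not report convergence")
  cm_full <- unpack(best$par)
  final_ll <- pmlr_loglik_ws(cm_full, d, ws)  # marginal, without the penalty
  cm <- cm_full
  cm[!estimable, ] <- NA_real_

  out <- risk_model(cm, mixture, degree = degree, estimable = estimable)
  out$loglik <- final_ll
  out$init_loglik <- init_ll
  out$converged <- conv
  out$expected_deaths <- expd
  out$outcome <- outcome
  out$fallback_intercept <- crude  # constant risk used for unestimated components
  if (isTRUE(o$hessian)) {
    H <- stats::optimHess(best$par, fn, gr)
    # near-flat directions (e.g. high-order terms of sparse components) can
    # leave H numerically singular; ridge it minimally before inverting
    V <- tryCatch(solve(H), error = function(e)
      tryCatch(solve(H + diag(1e-6, nrow(H))), error = function(e2) NULL))
    if (!is.null(V)) {
      nm_lab <- as.vector(t(outer(which(free), 0:degree,
                                  function(j, m) sprintf("c%d_%d", j, m))))
      dimnames(V) <- list(nm_lab, nm_lab)
    }
    out$vcov <- V
  }
  out
}

#' Crude mortality rates in fixed-width birthweight bins
#'
#' Bins are half-open `[a, a + width)` anchored at 0 g. Bins with no births
#' have an undefined (NA) rate rather than zero.
#'
#' @param records A [birth_records()] data frame.
#' @param bin_width Bin width in grams (default 100).
#' @return A data frame of class `bw_binned` with columns `bin_lower`,
#'   `bin_upper`, `births`, `deaths`, `rate`.
#' @export
empirical_mortality <- function(records, bin_width = 100) {
  records <- as_birth_records(records)
  if (nrow(records) == 0L) stop("`records` is empty")
  lo <- floor(records$birthweight_g / bin_width)
  rng <- seq.int(min(lo), max(lo))
  idx <- factor(lo, levels = rng)
  births <- as.integer(table(idx))
  deaths <- as.integer(tapply(records$death, idx, sum, default = 0))
  out <- data.frame(bin_lower = rng * bin_width,
                    bin_upper = (rng + 1) * bin_width,
                    births = births, deaths = deaths,
                    rate = ifelse(births > 0, deaths / births, NA_real_))
  class(out) <- c("bw_binned", "data.frame")
  out
}

#' Supported birthweight range of a component risk curve
#'
#' Curves are displayed/combined only within `c` component standard
#' deviations of the component mean (outside, the component has essentially
#' no births and its curve is unsupported by data), intersected with the
#' positive half-line.
#'
#' @param mixture A [mixture_model()].
#' @param j Component index.
#' @param c Number of standard deviations (default 3).
#' @return Numeric `c(lower, upper)` in grams, `lower >= 0`.
#' @export
curve_support <- function(mixture, j, c = 3) {
  stopifnot(inherits(mixture, "bw_mixture"), j >= 1L, j <= mixture$k)
  lo <- mixture$means[j] - c * mixture$sds[j]
  hi <- mixture$means[j] + c * mixture$sds[j]
  c(lower = max(0, lo), upper = hi)
}

#' Tabulate fitted risk curves on a birthweight grid
#'
#' @param risk A fitted `bw_risk`.
#' @param grid Birthweight grid in grams (default 250 to 5500 by 10).
#' @param support_c Support half-width in component standard deviations.
#' @return A data frame with columns `birthweight_g`, `component`, `risk`,
#'   `in_support` (rows for unestimated components carry `NA` risk).
#' @export
export_risk_curves <- function(risk, grid = seq(250, 5500, by = 10),
                               support_c = 3) {
  mix <- risk$mixture
  out <- do.call(rbind, lapply(seq_len(mix$k), function(j) {
    supp <- curve_support(mix, j, support_c)
    r <- if (risk$estimable[j]) risk_eval(risk, j, grid) else NA_real_
    data.frame(birthweight_g = grid, component = j, risk = r,
               in_support = grid >= supp[1] & grid <= supp[2])
  }))
  rownames(out) <- NULL
  out
}
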