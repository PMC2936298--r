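# Synthetic-data generation, overlapping-sample machinery, and the
# coverage/calibration study for the interval constant.

#' Full data-generating scenario specification
#'
#' Bundles a true mixture, true per-component risk curves, the population
#' size (finite, or `Inf` for independent samples), the per-sample size, the
#' number of samples, and a seed.
#'
#' @param mixture A [mixture_model()] (the true birthweight distribution).
#' @param risk A [risk_model()] with one curve per component (the true risks).
#' @param population_size Positive integer, or `Inf`.
#' @param n Per-sample size; must not exceed a finite `population_size`.
#' @param n_rep Number of samples drawn per study repetition.
#' @param seed Integer seed.
#' @return An object of class `bw_scenario`.
#' @export
scenario_spec <- function(mixture, risk, population_size, n, n_rep, seed = 1L) {
  stopifnot(inherits(mixture, "bw_mixture"), inherits(risk, "bw_risk"))
  if (risk$mixture$k != mixture$k) stop("risk and mixture component counts differ")
  if (!all(risk$estimable)) stop("true risk curves must be defined for every component")
  if (is.finite(population_size)) {
    population_size <- as.integer(population_size)
    if (n > population_size) stop("`n` exceeds the population size")
  }
  structure(
    list(mixture = mixture, risk = risk, population_size = population_size,
         n = as.integer(n), n_rep = as.integer(n_rep), seed = as.integer(seed)),
    class = "bw_scenario")
}

#' Built-in reference scenario: a heavily-burdened 4-component population
#'
#' A 4-component birthweight mixture with component-specific degree-4
#' logistic-polynomial mortality curves, emulating the pattern seen in a
#' population of white singletons born to heavily smoking mothers: a small
#' very-low-birthweight component, a broad intermediate component, a
#' dominant normal-birthweight component with a U-shaped risk curve, and a
#' small high-birthweight component. Component weights as printed
#' (0.007/0.182/0.758/0.052) are renormalized to sum to 1.
#'
#' @param population_size Population size (default 200000; `Inf` for
#'   non-overlapping samples).
#' @param n Per-sample size (default 50000).
#' @param n_rep Samples per repetition (default 25).
#' @param seed Integer seed (default 1).
#' @return A [scenario_spec()].
#' @export
reference_scenario <- function(population_size = 200000, n = 50000,
                               n_rep = 25L, seed = 1L) {
  mix <- mixture_model(weights = c(0.007, 0.182, 0.758, 0.052),
                       means = c(832, 2772, 3170, 3804),
                       sds = c(210, 740, 417, 413))
  coef <- rbind(
    c(-4.6975, -0.2362,  0.3994,  0.1690,  0.1328),
    c(-4.0962, -0.7496, -0.0289, -0.1094,  0.0918),
    c(-5.7538, -1.7275,  1.6269,  0.1897, -0.0249),
    c(-5.3285, -0.2786, -0.1979,  0.0535,  0.0773))
  risk <- risk_model(coef, mix, degree = 4L)
  scenario_spec(mix, risk, population_size, n, n_rep, seed)
}

# Risk used when *generating* outcomes: falls back to the stored constant
# crude-rate risk for components whose curve was not estimated.
sim_component_risk <- function(risk, j, x) {
  if (isTRUE(risk$estimable[j])) return(risk_eval(risk, j, x))
  fb <- risk$fallback_intercept
  if (is.null(fb)) stop("no risk curve available for component ", j)
  rep(inv_logit(fb), length(x))
}

#' Simulate birth records from a mixture and component risk curves
#'
#' Each record draws its component with probability equal to the component
#' weight, its birthweight from that component's normal distribution
#' (nonpositive draws are redrawn; birthweights are physically positive),
#' and its death indicator as Bernoulli with the drawn component's risk at
#' that birthweight. Fully reproducible given `seed`.
#'
#' @param mixture A [mixture_model()].
#' @param risk A [risk_model()] or [combined_risk()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @return A [birth_records()] data frame with the true component index
#'   attached as attribute `"component"`.
#' @export
simulate_records <- function(mixture, risk, n, seed = 1L) {
  stopifnot(n >= 1L)
  k <- mixture$k
  with_seed(seed, {
    comp <- sample.int(k, n, replace = TRUE, prob = mixture$weights)
    x <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
    bad <- which(x <= 0)
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), mixture$means[comp[bad]],
                             mixture$sds[comp[bad]])
      bad <- bad[x[bad] <= 0]
    }
    r <- numeric(n)
    for (j in seq_len(k)) {
      idx <- comp == j
      if (any(idx)) r[idx] <- sim_component_risk(risk, j, x[idx])
    }
    death <- as.numeric(stats::runif(n) < r)
    out <- birth_records(x, death)
    attr(out, "component") <- comp
    out
  })
}

#' Generate the fixed finite population of a scenario
#'
#' One seeded realization of [simulate_records()] of size
#' `population_size`, held fixed so that repeated sampling from it induces
#' the scenario's degree of overlap.
#'
#' @param spec A [scenario_spec()] with finite `population_size`.
#' @return A [birth_records()] data frame of length `population_size`.
#' @export
make_finite_population <- function(spec) {
  stopifnot(inherits(spec, "bw_scenario"))
  if (!is.finite(spec$population_size)) {
    stop("population size is infinite; samples are drawn fresh instead")
  }
  simulate_records(spec$mixture, spec$risk, spec$population_size,
                   seed = derive_seed(spec$seed, 1L))
}

#' Draw overlapping simple random samples from a finite population
#'
#' Each sample is a simple random sample of size `n` without replacement
#' within the sample; samples are drawn independently of one another, so
#' overlap between samples arises naturally from the finite population.
#'
#' @param population A [birth_records()] data frame.
#' @param n Sample size.
#' @param n_rep Number of samples.
#' @param seed Integer seed.
#' @return List of `n_rep` [birth_records()] data frames, each with the
#'   drawn row indices attached as attribute `"indices"`.
#' @export
draw_overlapping_samples <- function(population, n, n_rep, seed = 1L) {
  population <- as_birth_records(population)
  N <- nrow(population)
  if (n > N) stop("`n` exceeds the population size")
  with_seed(seed, {
    lapply(seq_len(n_rep), function(s) {
      idx <- sample.int(N, n, replace = FALSE)
      out <- population[idx, , drop = FALSE]
      class(out) <- c("bw_records", "data.frame")
      attr(out, "indices") <- idx
      out
    })
  })
}

#' Expected number of distinct records across overlapping samples
#'
#' Each population record appears in one sample with probability `n/N`,
#' so across `n_rep` independently drawn samples the expected distinct-record
#' count is \eqn{N\{1 - (1 - n/N)^{N_{rep}}\}}.
#'
#' @param population_size Population size N.
#' @param n Per-sample size.
#' @param n_rep Number of samples.
#' @return The expected count (a real number).
#' @export
expected_distinct_records <- function(population_size, n, n_rep) {
  stopifnot(n <= population_size, n_rep >= 1L)
  population_size * (1 - (1 - n / population_size)^n_rep)
}

# The 3k study targets: r_j at mu_j - sd_j, mu_j, mu_j + sd_j of the true
# mixture, scored against the logit of the true risk there.
study_targets <- function(spec) {
  mix <- spec$mixture
  do.call(rbind, lapply(seq_len(mix$k), function(j) {
    xs <- mix$means[j] + c(-1, 0, 1) * mix$sds[j]
    data.frame(j = j, x = xs,
               truth_theta = logit(risk_eval(spec$risk, j, xs)))
  }))
}

# Fit mixture (k fixed at truth) + PMLR to one sample; error propagates.
fit_one_sample <- function(records, k, seed, em_args, fit_opts) {
  m <- do.call(fit_mixture_em,
               c(list(records = records, k = k, seed = derive_seed(seed, 1L)),
                 em_args))
  fit_pmlr(records, m, opts = fit_opts, seed = derive_seed(seed, 2L))
}

#' Coverage study for the interval calibration constant
#'
#' For each study repetition: draws `n_rep` samples from the scenario
#' (overlapping samples from a fixed finite population, or fresh samples
#' when the population is infinite), fits the mixture (k fixed at the true
#' value) and PMLR to each, computes confidence intervals for the logit risks
#' at the 3k study targets (`r_j` at `mu_j - sd_j`, `mu_j`, `mu_j + sd_j`)
#' under every constant in `c_grid` — with and without the simulation-based
#' bias adjustment — and scores whether each interval contains the true
#' logit risk. Finite-population runs use the overlap-corrected constant
#' with `phi = n/N`; infinite-population runs use the constant as given.
#' Targets undefined in a repetition (component unestimated, or outside its
#' supported range, in nearly all samples) are excluded from that
#' repetition's totals.
#'
#' @param spec A [scenario_spec()].
#' @param c_grid Constants to evaluate.
#' @param n_study_reps Number of study repetitions (default 10).
#' @param seed Integer seed.
#' @param n_sim_bias Simulated data sets per bias bank (default 5).
#' @param em_args,fit_opts Optional settings for the per-sample fits.
#' @param support_c Curve support half-width in component sds.
#' @param max_retries Times a failed sample fit is redrawn before erroring.
#' @return An object of class `bw_coverage`: `table` (columns `C`,
#'   `population_size`, `bias_mode`, `count`, `total`, `percentage`),
#'   `targets`, and the scenario.
#' @export
coverage_study <- function(spec, c_grid, n_study_reps = 10L, seed = 1L,
                           n_sim_bias = 5L, em_args = list(),
                           fit_opts = list(), support_c = 3,
                           max_retries = 3L) {
  stopifnot(inherits(spec, "bw_scenario"), length(c_grid) >= 1L)
  c_grid <- sort(as.numeric(c_grid))
  tg <- study_targets(spec)
  k <- spec$mixture$k
  finite <- is.finite(spec$population_size)
  phi <- if (finite) spec$n / spec$population_size else 0
  pop <- if (finite) make_finite_population(spec) else NULL

  n_c <- length(c_grid)
  count <- total <- matrix(0L, n_c, 2L,
                           dimnames = list(NULL, c("adjusted", "unadjusted")))

  for (t in seq_len(n_study_reps)) {
    fits <- vector("list", spec$n_rep)
    for (s in seq_len(spec$n_rep)) {
      for (try_i in 0:max_retries) {
        samp_seed <- derive_seed(seed, t * 10000L + s * 10L + try_i)
        recs <- if (finite) {
          draw_overlapping_samples(pop, spec$n, 1L, seed = samp_seed)[[1L]]
        } else {
          simulate_records(spec$mixture, spec$risk, spec$n, seed = samp_seed)
        }
        fit <- tryCatch(
          fit_one_sample(recs, k, samp_seed, em_args, fit_opts),
          error = function(e) e)
        if (!inherits(fit, "error")) break
        message("sample fit failed (rep ", t, ", sample ", s, "): ",
                conditionMessage(fit), if (try_i < max_retries) "; redrawing")
      }
      if (inherits(fit, "error")) stop("sample fit failed after retries")
      fits[[s]] <- fit
    }

    metas <- lapply(seq_len(nrow(tg)), function(i) {
      tryCatch(
        suppressWarnings(
          combine_risk_estimates(fits, tg$j[i], tg$x[i], support_c)),
        error = function(e) NULL)
    })
    have <- !vapply(metas, is.null, logical(1))

    overall <- combined_risk(fits)
    bias_targets <- lapply(which(have), function(i) {
      list(type = "risk", j = tg$j[i], x = tg$x[i])
    })
    biases <- rep(NA_real_, nrow(tg))
    if (length(bias_targets) > 0L) {
      biases[have] <- suppressWarnings(
        bias_adjustment(overall, bias_targets, n = spec$n, n_sim = n_sim_bias,
                        seed = derive_seed(seed, 77000L + t),
                        fit_opts = fit_opts, em_args = em_args))
    }

    for (ci in seq_len(n_c)) {
      c_used <- overlap_constant(c_grid[ci], phi, spec$n_rep)
      for (i in which(have)) {
        meta <- metas[[i]]
        # unadjusted interval
        iv <- ci_theta(meta, c_used, use_bias = FALSE)
        total[ci, "unadjusted"] <- total[ci, "unadjusted"] + 1L
        if (tg$truth_theta[i] >= iv$lower && tg$truth_theta[i] <= iv$upper) {
          count[ci, "unadjusted"] <- count[ci, "unadjusted"] + 1L
        }
        # bias-adjusted interval (needs a usable bias)
        if (!is.na(biases[i])) {
          meta$bias <- biases[i]
          iv <- ci_theta(meta, c_used, use_bias = TRUE)
          total[ci, "adjusted"] <- total[ci, "adjusted"] + 1L
          if (tg$truth_theta[i] >= iv$lower && tg$truth_theta[i] <= iv$upper) {
            count[ci, "adjusted"] <- count[ci, "adjusted"] + 1L
          }
        }
      }
    }
  }

  tab <- do.call(rbind, lapply(c("adjusted", "unadjusted"), function(mode) {
    data.frame(C = c_grid, population_size = spec$population_size,
               bias_mode = mode, count = count[, mode], total = total[, mode],
               percentage = ifelse(total[, mode] > 0,
                                   100 * count[, mode] / total[, mode],
                                   NA_real_))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, targets = tg, spec = spec,
                 n_study_reps = n_study_reps, phi = phi),
            class = "bw_coverage")
}

#' @export
print.bw_coverage <- function(x, ...) {
  cat(sprintf("coverage study: %d repetitions, %d targets, population %s, phi = %.4f\n",
              x$n_study_reps, nrow(x$targets),
              if (is.finite(x$spec$population_size))
                format(x$spec$population_size) else "infinite", x$phi))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Calibrate the interval constant to a target coverage
#'
#' Runs [coverage_study()] over `c_grid` and returns the smallest constant
#' whose bias-adjusted coverage reaches the target; if none does, the
#' largest constant is returned with a warning.
#'
#' @inheritParams coverage_study
#' @param target_coverage Desired coverage probability (default 0.95).
#' @param ... Passed to [coverage_study()].
#' @return The selected constant, with the full `bw_coverage` attached as
#'   attribute `"study"`.
#' @export
calibrate_c <- function(spec, c_grid, target_coverage = 0.95, ...) {
  res <- coverage_study(spec, c_grid = c_grid, ...)
  adj <- res$table[res$table$bias_mode == "adjusted", ]
  adj <- adj[order(adj$C), ]
  ok <- which(!is.na(adj$percentage) & adj$percentage >= 100 * target_coverage)
  if (length(ok) == 0L) {
    warning("no constant in the grid reaches the target coverage; returning the largest")
    sel <- adj$C[nrow(adj)]
  } else {
    sel <- adj$C[ok[1L]]
  }
  structure(sel, study = res)
}
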