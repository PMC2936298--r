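# File formats: CSV records, JSON model export/import, YAML scenario
# configuration, CSV result tables.

#' Read birth records from a CSV file
#'
#' Expects a header with columns `birthweight_g`, `death`, and optionally
#' `covariate`. Rows with missing or nonpositive birthweight, or a death (or
#' covariate) value outside {0, 1}, are rejected; a per-row report of the
#' rejections is attached as attribute `"rejected"` and the kept/rejected
#' counts are reported via `message()`.
#'
#' @param path Path to a CSV file (UTF-8, header required).
#' @return A [birth_records()] data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("birthweight_g", "death") %in% names(raw))) {
    stop("CSV must have header columns `birthweight_g` and `death`")
  }
  bw <- suppressWarnings(as.numeric(raw$birthweight_g))
  d <- suppressWarnings(as.numeric(raw$death))
  bad <- !is.finite(bw) | bw <= 0 | !d %in% c(0, 1) | is.na(d)
  reason <- ifelse(!is.finite(bw) | bw <= 0, "bad birthweight", "bad death")
  has_cov <- "covariate" %in% names(raw)
  if (has_cov) {
    cv <- suppressWarnings(as.numeric(raw$covariate))
    cov_bad <- !is.na(raw$covariate) & (!cv %in% c(0, 1) | is.na(cv))
    reason[!bad & cov_bad] <- "bad covariate"
    bad <- bad | cov_bad
  }
  if (sum(!bad) == 0L) stop("no valid rows in ", path)
  rejected <- if (any(bad)) {
    data.frame(row = which(bad), reason = reason[bad])
  } else {
    data.frame(row = integer(0), reason = character(0))
  }
  message(sprintf("read %d records from %s (%d rejected)",
                  sum(!bad), path, sum(bad)))
  out <- birth_records(bw[!bad], d[!bad],
                       covariate = if (has_cov) cv[!bad])
  attr(out, "rejected") <- rejected
  out
}

#' Write birth records to CSV
#'
#' @param records A [birth_records()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- as_birth_records(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Export / import a fitted mixture model as JSON
#'
#' @param model A `bw_mixture`.
#' @param path Output path.
#' @return `path` (write) or a `bw_mixture` (read).
#' @export
write_mixture_json <- function(model, path) {
  stopifnot(inherits(model, "bw_mixture"))
  obj <- list(k = model$k, weights = model$weights, means_g = model$means,
              sds_g = model$sds, loglik = model$loglik,
              converged = model$converged, n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mixture_json
#' @export
read_mixture_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mixture_model(obj$weights, obj$means_g, obj$sds_g)
  m$loglik <- obj$loglik %||% NA_real_
  m$converged <- obj$converged %||% NA
  m$n <- obj$n %||% NA_integer_
  m
}

#' Export / import a fitted risk model as JSON
#'
#' The file records the polynomial degree, the per-component coefficient
#' arrays (ascending powers of the per-component standardized birthweight z),
#' the estimability flags, and the conditioning mixture.
#'
#' @param risk A `bw_risk`.
#' @param path Output path.
#' @return `path` (write) or a `bw_risk` (read).
#' @export
write_risk_json <- function(risk, path) {
  stopifnot(inherits(risk, "bw_risk"))
  obj <- list(degree = risk$degree,
              z_convention = "per_component_standardized",
              coeffs = apply(risk$coeffs, 1L, identity, simplify = FALSE),
              estimable = risk$estimable,
              loglik = risk$loglik,
              fallback_intercept = risk$fallback_intercept,
              mixture = list(k = risk$mixture$k, weights = risk$mixture$weights,
                             means_g = risk$mixture$means,
                             sds_g = risk$mixture$sds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_risk_json
#' @export
read_risk_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mix <- mixture_model(obj$mixture$weights, obj$mixture$means_g,
                       obj$mixture$sds_g)
  cm <- if (is.list(obj$coeffs)) do.call(rbind, obj$coeffs) else as.matrix(obj$coeffs)
  r <- risk_model(cm, mix, degree = obj$degree,
                  estimable = as.logical(obj$estimable))
  r$loglik <- obj$loglik %||% NA_real_
  r$fallback_intercept <- obj$fallback_intercept
  r
}

#' Write a scenario specification to YAML (and read it back)
#'
#' @param spec A [scenario_spec()].
#' @param path Output path.
#' @return `path` (write) or a `bw_scenario` (read).
#' @export
write_scenario_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "bw_scenario"))
  obj <- list(
    mixture = list(weights = spec$mixture$weights, means_g = spec$mixture$means,
                   sds_g = spec$mixture$sds),
    risk = list(degree = spec$risk$degree,
                coeffs = apply(spec$risk$coeffs, 1L, identity, simplify = FALSE)),
    population_size = if (is.finite(spec$population_size))
      spec$population_size else "infinite",
    n = spec$n, n_rep = spec$n_rep, seed = spec$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  mix <- mixture_model(unlist(obj$mixture$weights), unlist(obj$mixture$means_g),
                       unlist(obj$mixture$sds_g))
  cm <- do.call(rbind, lapply(obj$risk$coeffs, unlist))
  risk <- risk_model(cm, mix, degree = obj$risk$degree)
  ps <- if (identical(obj$population_size, "infinite")) Inf else obj$population_size
  scenario_spec(mix, risk, ps, obj$n, obj$n_rep, obj$seed)
}

#' Write a coverage study table to CSV
#'
#' @param study A `bw_coverage` from [coverage_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(study, path) {
  stopifnot(inherits(study, "bw_coverage"))
  utils::write.csv(study$table, path, row.names = FALSE)
  invisible(path)
}

# Format interval results as a tidy data.frame; risks optionally per 1,000.
interval_row <- function(iv, label, per_1000 = FALSE) {
  scale_f <- if (per_1000 && iv$scale == "probability") 1000 else 1
  data.frame(target = label, point = iv$point * scale_f,
             lower = iv$lower * scale_f, upper = iv$upper * scale_f,
             scale = if (scale_f == 1000) "per_1000" else iv$scale,
             C = iv$c_used, bias = iv$bias_used,
             n_rep_effective = iv$n_rep[1L])
}
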