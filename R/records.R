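#' Construct a validated set of birth records
#'
#' A birth record is one observation: a birthweight in grams, a binary death
#' indicator, and optionally a binary covariate (for example an indicator of
#' preterm birth or intrauterine growth restriction used in place of
#' mortality as the modeled outcome).
#'
#' @param birthweight_g Numeric vector of birthweights in grams; must be
#'   strictly positive and finite.
#' @param death Integer/numeric vector of 0/1 death indicators.
#' @param covariate Optional 0/1 vector of the same length.
#'
#' @return A `data.frame` of class `bw_records` with columns
#'   `birthweight_g`, `death`, and optionally `covariate`.
#' @export
#' @examples
#' birth_records(c(3100, 2450, 980), c(0, 0, 1))
birth_records <- function(birthweight_g, death, covariate = NULL) {
  birthweight_g <- as.numeric(birthweight_g)
  death <- as.numeric(death)
  if (length(birthweight_g) != length(death)) {
    stop("`birthweight_g` and `death` must have the same length")
  }
  if (any(!is.finite(birthweight_g)) || any(birthweight_g <= 0)) {
    stop("birthweights must be finite and strictly positive")
  }
  if (any(!death %in% c(0, 1))) {
    stop("`death` must be coded 0/1")
  }
  df <- data.frame(birthweight_g = birthweight_g, death = death)
  if (!is.null(covariate)) {
    covariate <- as.numeric(covariate)
    if (length(covariate) != length(death)) {
      stop("`covariate` must have the same length as `death`")
    }
    if (any(!covariate %in% c(0, 1))) {
      stop("`covariate` must be coded 0/1")
    }
    df$covariate <- covariate
  }
  class(df) <- c("bw_records", "data.frame")
  df
}

# Coerce data.frame-like input (e.g. straight from read.csv) to bw_records.
as_birth_records <- function(x) {
  if (inherits(x, "bw_records")) return(x)
  if (!is.data.frame(x)) stop("records must be a data.frame")
  if (!all(c("birthweight_g", "death") %in% names(x))) {
    stop("records need columns `birthweight_g` and `death`")
  }
  birth_records(x$birthweight_g, x$death,
                covariate = if ("covariate" %in% names(x)) x$covariate)
}
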