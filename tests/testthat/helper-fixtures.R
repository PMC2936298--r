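# Shared fixtures: a small, fast, well-identified 2-component scenario in
# which both components have plenty of events, so multi-sample machinery can
# be exercised at small n.

toy_mixture <- function() {
  mixture_model(weights = c(0.4, 0.6), means = c(2000, 3200),
                sds = c(300, 350))
}

toy_risk <- function(mix = toy_mixture()) {
  risk_model(rbind(c(-2.2, -0.5, 0.2, 0, 0),
                   c(-3.0,  0.3, -0.1, 0, 0)),
             mix, degree = 4L)
}

toy_scenario <- function(population_size = Inf, n = 1500, n_rep = 4,
                         seed = 99L) {
  scenario_spec(toy_mixture(), toy_risk(), population_size, n, n_rep, seed)
}

# One-component setup with a constant true risk, for closed-form checks.
flat_mixture <- function() mixture_model(1, 3000, 400)

flat_risk <- function(p = 0.1) {
  risk_model(matrix(c(qlogis(p), 0, 0, 0, 0), 1), flat_mixture(), degree = 4L)
}

# A constant-risk k-component model: every component at probability p.
const_risk <- function(mix, p) {
  risk_model(matrix(c(qlogis(p), 0, 0, 0, 0), mix$k, 5, byrow = TRUE),
             mix, degree = 4L)
}

# Fit mixture + PMLR to several independent draws of a scenario (cached per
# test file via local memoisation would be overkill; calls stay small).
toy_fits <- function(n_fits = 3, n = 1500, seed = 7L) {
  spec <- toy_scenario(n = n)
  lapply(seq_len(n_fits), function(s) {
    rec <- simulate_records(spec$mixture, spec$risk, n, seed = seed + s)
    m <- fit_mixture_em(rec, 2, seed = seed + s)
    suppressWarnings(fit_pmlr(rec, m, seed = seed + s))
  })
}
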