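# shared fixtures, all built in code

# two-knot identity curve: mu(theta) = theta, constant curve error
identity_curve <- function(old = 12000, young = 0, sigma = 1e-6) {
  cal_curve(c(young, old), c(young, old), c(sigma, sigma))
}

# the two production-pulse windows used throughout the synthetic studies
pulse_windows <- function() {
  tibble::tibble(old = c(7600, 6400), young = c(7100, 5900))
}

# interval overlap test on (old, young) pairs; vectorized over the first pair
overlaps <- function(a_old, a_young, b_old, b_young) {
  pmin(a_old, b_old) > pmax(a_young, b_young)
}
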