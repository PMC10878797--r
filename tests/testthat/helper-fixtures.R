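# shared fixtures: default event bounds, a narrow-event parameter set used
# for CLT-regime checks, and a rounded neutral sample generator

default_event <- function() event_params(0.005, 1, 14 / 9)

narrow_event <- function() event_params(5e-5, 1e-2, 14 / 9)

# simulate a neutral sample recorded at the survey resolution
rounded_neutral_sample <- function(lam, n, seed,
                                   event = default_event(),
                                   resolution = 0.005) {
  x <- simulate_damage(neutral_model(lam, event), n, seed = seed)
  neutralherb:::.record_damage(x, resolution, TRUE)
}

# trapezoid integral of the continuous density of a mixed distribution
trapz_density <- function(d) {
  n <- length(d$density)
  d$h * (sum(d$density) - (d$density[1] + d$density[n]) / 2)
}
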