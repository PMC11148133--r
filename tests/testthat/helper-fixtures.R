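# Shared fixtures, built in code. All randomness is seeded.

# raw sine over one cycle on an n-point gated grid
raw_sine <- function(n = 30L, a = 1, f = 1, offset = 0, phase = 0) {
  t <- (0:(n - 1L)) / n
  offset + a * sin(2 * pi * f * t + phase)
}

# default seeded synthetic pair, preprocessed
synth_pair <- function(seed = 42L) {
  syn <- generate_cardiac_waveforms(seed = seed)
  list(
    syn = syn,
    q_aq = preprocess_pcmri(syn$raw_aq),
    q_sas = preprocess_pcmri(syn$raw_sas)
  )
}

# trapezoid quadrature on a uniform grid
trapz <- function(t, y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(max(abs(x - y)) <= tol,
              label = sprintf("max|diff| = %.3g <= %.3g", max(abs(x - y)), tol))
}
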