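# Draw a valid random parameter set in physically sensible ranges
# (moderate exponents; used by the property-style tests).
random_params <- function() {
  N <- sample(100:2000, 1)
  af_params(
    N = N,
    m = sample(50:min(N, 500), 1),
    kb_ratio = stats::runif(1, 0, 10),
    f0 = 10^stats::runif(1, -12, 0),
    l0 = stats::runif(1, 5, 150),
    a = sample(1:20, 1),
    lam = stats::runif(1, 0.05, 1),
    T_kelvin = stats::runif(1, 280, 320),
    V = 10^stats::runif(1, -17, -15)
  )
}
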