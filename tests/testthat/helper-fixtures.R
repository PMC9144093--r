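# Shared fixtures, built in code once per test run.

fx <- make_fixtures(seed = 42)

# Noise-free clone of a model (no IIV, no residual error) for fixed-point
# and oracle checks.
strip_variability <- function(model) {
  m <- model
  m$omega <- NULL
  m$residual <- list(add = 0, prop = 0)
  m
}

noiseless_models <- lapply(fx$models, strip_variability)

random_params <- function(n, seed) {
  set.seed(seed)
  data.frame(CL = runif(n, 1, 8), V1 = runif(n, 10, 60),
             Q = runif(n, 2, 15), V2 = runif(n, 20, 100))
}

# Independent ODE oracle for the two-compartment infusion system.
ode_conc <- function(cl, v1, q, v2, reg, times) {
  rate_at <- function(t) {
    r <- 0
    for (d in seq_len(nrow(reg$doses))) {
      if (t >= reg$doses$time[d] && t < reg$doses$time[d] + reg$doses$dur[d]) {
        r <- r + reg$doses$amt[d] / reg$doses$dur[d]
      }
    }
    r
  }
  f <- function(t, y, p) {
    list(c(rate_at(t) - (cl / v1) * y[1] - (q / v1) * y[1] + (q / v2) * y[2],
           (q / v1) * y[1] - (q / v2) * y[2]))
  }
  out <- deSolve::ode(c(0, 0), c(0, times), f, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  out[-1, 2] / v1
}
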