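# shared fixtures, built in code; heavy states are cached per test run

# one species on one resource, coarse grid: fast solver/FMSY fixture
toy_model <- function(F = 0, Rmax = 1e8, no_w = 50) {
  sp <- species_params("one", w0 = 1e-3, Wi = 100, wmat = 25,
                       h = 20, beta = 100, sigma = 1.3,
                       Rmax = Rmax, F = F)
  rs <- resource_params("res", kappa = 1e10, w_min = 1e-7, w_max = 1)
  spectrum_model(sp, rs, theta_R = matrix(1, 1, 1), no_w = no_w)
}

# a hand-built 3-bin state for quadrature oracles
toy_state <- function(model, fill = 0) {
  st <- initial_state(model)
  st$N[] <- fill
  st$NR[] <- fill
  st
}

.cache <- new.env(parent = emptyenv())

# default archetype model and its steady state, computed once per run
default_steady <- function() {
  if (is.null(.cache$steady)) {
    m <- spectrum_model()
    .cache$model <- m
    .cache$steady <- run_to_steady(m)
  }
  list(model = .cache$model, state = .cache$steady)
}

toy_steady <- function() {
  if (is.null(.cache$toy_steady)) {
    m <- toy_model()
    .cache$toy_model <- m
    .cache$toy_steady <- run_to_steady(m)
  }
  list(model = .cache$toy_model, state = .cache$toy_steady)
}
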