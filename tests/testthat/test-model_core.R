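test_that("log-normal selectivity matches its closed form", {
  expect_equal(lognormal_selectivity(1, 100, beta = 100, sigma = 1), 1)
  # one sigma off the preferred ratio in log space
  s <- 0.7
  expect_equal(lognormal_selectivity(1, 100 * exp(s), beta = 100, sigma = s),
               exp(-1 / 2))
  # vanishing width kills off-ratio preference
  expect_lt(lognormal_selectivity(1, 150, beta = 100, sigma = 1e-4), 1e-10)
  expect_error(lognormal_selectivity(-1, 10, 100, 1), "positive")
})

test_that("selectivity integrates to sigma * sqrt(2*pi) in log prey weight", {
  for (sigma in c(0.8, 1.5, 2)) {
    lwp <- seq(-40, 40, by = 0.01)
    val <- sum(lognormal_selectivity(exp(lwp), 1e3, beta = 50,
                                     sigma = sigma)) * 0.01
    expect_equal(val, sigma * sqrt(2 * pi), tolerance = 1e-6)
  }
})

test_that("search-volume coefficient reproduces the printed formula", {
  # linear in h
  g1 <- search_volume_coefficient(0.6, 20, 100, 1, 2.05, 1e3)
  g2 <- search_volume_coefficient(0.6, 40, 100, 1, 2.05, 1e3)
  expect_equal(g2, 2 * g1)
  # lambda = 2 removes the beta and exponential terms
  expect_equal(search_volume_coefficient(0.6, 20, 100, 1, 2, 1e3),
               0.6 * 20 / (0.4 * sqrt(2 * pi) * 1e3))
  # independent hand evaluation, f0=0.6 h=20 beta=100 sigma=1 lambda=2.05
  hand <- 0.6 * 20 * 100^(-0.05) * exp(-0.05^2 * 1 / 2) /
    (0.4 * sqrt(2 * pi) * 1e3 * 1)
  expect_equal(search_volume_coefficient(0.6, 20, 100, 1, 2.05, 1e3), hand)
  expect_error(search_volume_coefficient(1, 20, 100, 1, 2.05, 1e3), "f0")
})

test_that("encounter, feeding level and net energy behave per contract", {
  expect_equal(encounter_rate(5, 0.8, 2, 0), 0)
  expect_equal(encounter_rate(5, 0.8, 1, 3), 15)
  expect_equal(encounter_rate(10, 0.8, 1, 3), 30)
  expect_equal(feeding_level(20 * 2^0.75, 20, 2, 0.75), 0.5)
  expect_equal(feeding_level(0, 20, 2, 0.75), 0)
  expect_equal(feeding_level(1e12, 20, 2, 0.75), 1, tolerance = 1e-10)
  sp <- species_params("x", w0 = 1e-3, Wi = 100, wmat = 25,
                       h = 20, ks = 2, alpha = 0.6)
  expect_equal(net_energy(0.5, 1, sp), 0.6 * 0.5 * 20 - 2)
  # intake below metabolism clamps at zero
  expect_equal(net_energy(0.05, 1, sp), 0)
  # exact boundary
  fstar <- 2 / (0.6 * 20)
  expect_equal(net_energy(fstar, 1, sp), 0)
})

test_that("maturity allocation rises from 0 to ~1 across the size range", {
  sp <- species_params("x", w0 = 1e-3, Wi = 1e4, wmat = 100)
  expect_lt(maturity_allocation(1, sp), 1e-4)
  expect_equal(maturity_allocation(1e4, sp), 1, tolerance = 1e-6)
  expect_equal(maturity_allocation(100, sp),
               0.5 * (100 / 1e4)^(1 - sp$n))
  w <- 10^seq(-3, 4, by = 0.05)
  expect_true(all(diff(maturity_allocation(w, sp)) >= -1e-12))
  expect_true(all(maturity_allocation(w, sp) >= 0 &
                  maturity_allocation(w, sp) <= 1))
})

test_that("somatic growth is the unallocated share and non-negative", {
  expect_equal(somatic_growth(4, 1), 0)
  expect_equal(somatic_growth(4, 0), 4)
  expect_equal(somatic_growth(4, 0.25), 3)
})

test_that("fixed feeding level growth decelerates toward Wi", {
  # integrate dw/da = E_net * (1 - psi) at constant f; asymptote near Wi
  sp <- species_params("x", w0 = 1e-3, Wi = 1000, wmat = 250, h = 30,
                       f0 = 0.6)
  f <- 0.6
  g <- function(w) somatic_growth(net_energy(f, w, sp),
                                  maturity_allocation(w, sp))
  w <- sp$w0; da <- 0.005
  traj <- numeric(0)
  for (s in seq_len(200 / da)) {
    w <- w + da * g(w)
    if (s %% 100 == 0) traj <- c(traj, w)   # every 0.5 yr
  }
  expect_equal(w, sp$Wi, tolerance = 0.05)
  expect_true(all(diff(traj) >= 0))
  # past the inflection (~0.3 Wi) increments shrink monotonically
  late <- traj[traj > 0.4 * sp$Wi & traj < 0.99 * sp$Wi]
  expect_true(all(diff(diff(late)) < 0))
})

test_that("background, starvation and fishing mortality follow closed forms", {
  sp <- species_params("x", w0 = 1e-3, Wi = 1, wmat = 0.5, mu0 = 0.6)
  expect_equal(background_mortality(sp), 0.6)
  sp16 <- sp; sp16$Wi <- 16; sp16$wmat <- 4
  expect_equal(background_mortality(sp16) / background_mortality(sp),
               16^(sp$n - 1))
  sp2 <- species_params("x", w0 = 1e-3, Wi = 100, wmat = 25, h = 20,
                        ks = 2, alpha = 0.6, xi = 0.1)
  expect_equal(starvation_mortality(0.9, 1, sp2), 0)     # surplus
  fstar <- 2 / (0.6 * 20)
  expect_equal(starvation_mortality(fstar, 1, sp2), 0)   # threshold
  # deficit D at w: D / (xi * w)
  expect_equal(starvation_mortality(0, 1, sp2), 2 / 0.1)
  spF <- species_params("x", w0 = 1e-3, Wi = 100, wmat = 25, F = 0.4)
  expect_equal(fishing_mortality(12.5, spF), 0)
  expect_equal(fishing_mortality(25, spF), 0.4)  # closed at wmat
  spF$F <- 0
  expect_equal(fishing_mortality(c(1, 25, 80), spF), c(0, 0, 0))
})

test_that("beverton_holt saturates at Rmax and is monotone", {
  expect_equal(beverton_holt(1e6, 1e6), 5e5)
  expect_equal(beverton_holt(1e12, 1e6), 1e6, tolerance = 1e-5)
  expect_equal(beverton_holt(10, 1e8), 10, tolerance = 1e-6)
  r <- beverton_holt(10^seq(0, 12, by = 0.5), 1e6)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= 1e6))
})

test_that("quadrature operations match term-by-term sum oracles", {
  m <- toy_model(no_w = 60)
  g <- m$grid
  st <- toy_state(m)
  # three occupied prey bins, hand-summed availability
  bins <- c(10, 20, 30)
  dens <- c(2e5, 3e4, 5e3)
  st$NR[1, bins] <- dens
  wi <- 10   # predator weight
  j <- which.min(abs(log(g$w) - log(wi)))
  hand <- sum(dens * g$w[bins] * g$dw[bins] *
              lognormal_selectivity(g$w[bins], g$w[j],
                                    m$species$beta, m$species$sigma))
  expect_equal(available_energy(st, m, 1, wi), hand,
               tolerance = 1e-12)
  # empty system
  expect_equal(available_energy(toy_state(m), m, 1, wi), 0)

  # predation mortality: one predator bin vs hand sum
  st2 <- toy_state(m)
  jpred <- which.min(abs(log(g$w) - log(10)))
  st2$N[1, jpred] <- 7e3
  rates <- compute_rates(m, st2)
  wp <- 0.1
  k <- which.min(abs(log(g$w) - log(wp)))
  hand_mu <- lognormal_selectivity(g$w[k], g$w[jpred], m$species$beta,
                                   m$species$sigma) *
    (1 - rates$f[1, jpred]) * m$gamma * g$w[jpred]^m$species$q *
    7e3 * g$dw[jpred]
  expect_equal(predation_mortality(st2, m, "resource", wp, resource = 1),
               hand_mu, tolerance = 1e-12)
  # satiated predators exert no predation
  expect_equal(thermspectrum:::predation_mortality_grid(st2, m,
                 rates = list(f = matrix(1, 1, g$n_w)))$fish,
               rep(0, g$n_w))
  expect_equal(predation_mortality(toy_state(m), m, "resource", wp,
                                   resource = 1), 0)

  # egg production: two occupied bins vs hand sum
  st3 <- toy_state(m)
  kk <- sapply(c(20, 50), function(x) which.min(abs(g$w - x)))
  st3$N[1, kk] <- c(1e3, 2e2)
  r3 <- compute_rates(m, st3)
  sp <- m$species
  hand_R <- sp$erepro / (2 * sp$w0) *
    sum(st3$N[1, kk] * r3$E_net[1, kk] * m$psi[1, kk] * g$dw[kk])
  expect_equal(egg_production(st3, m, 1), hand_R, tolerance = 1e-12)
  expect_equal(r3$R_phy[1], hand_R, tolerance = 1e-12)
  # doubling erepro doubles egg production
  m2 <- m; m2$species$erepro <- 2 * sp$erepro
  expect_equal(egg_production(st3, m2, 1), 2 * hand_R, tolerance = 1e-12)
  # psi == 0 kills reproduction
  m3 <- m; m3$psi[] <- 0
  expect_equal(egg_production(st3, m3, 1), 0)
})

test_that("rate invariants hold on an arbitrary admissible state", {
  ds <- default_steady()
  rates <- attr(ds$state, "rates")
  expect_true(all(rates$f >= 0 & rates$f <= 1))
  expect_true(all(ds$model$psi >= 0 & ds$model$psi <= 1))
  expect_true(all(rates$g >= 0))
  expect_true(all(rates$mu_pre >= 0) && all(rates$mu_stv >= 0) &&
              all(rates$mu_fis >= 0) && all(rates$mu_bac >= 0))
  # total mortality is the exact component sum at every weight
  expect_equal(rates$mu,
               rates$mu_pre + rates$mu_stv + rates$mu_fis +
                 matrix(rates$mu_bac, nrow(rates$mu), ncol(rates$mu)),
               tolerance = 1e-14)
  expect_true(all(rates$R <= ds$model$species$Rmax))
  expect_true(all(rates$R <= rates$R_phy + 1e-9))
})

test_that("parameter validation catches inadmissible inputs", {
  expect_error(species_params("x", w0 = 1, Wi = 0.5, wmat = 0.7), "w0")
  expect_error(species_params("x", w0 = 1e-3, Wi = 10, wmat = 2,
                              alpha = 1.5), "alpha")
  expect_error(species_params("x", w0 = 1e-3, Wi = 10, wmat = 2,
                              beta = 0.5), "beta")
  expect_error(resource_params("r", w_min = 1, w_max = 0.1), "w_min")
  expect_error(resource_params("r", kappa = -1), "positive")
  sp <- default_species_params(); rs <- default_resource_params()
  expect_error(spectrum_model(sp, rs, theta_R = matrix(2, 3, 2)), "theta_R")
  rs2 <- rs; rs2$lambda <- 1.9
  expect_warning(spectrum_model(sp, rs2), "lambda")
})

test_that("weight grid is log-spaced, increasing, and spans all ranges", {
  m <- spectrum_model()
  g <- m$grid
  expect_true(all(diff(g$w) > 0))
  expect_true(all(g$dw > 0))
  expect_equal(diff(log(g$w)), rep(diff(log(g$w))[1], g$n_w - 1),
               tolerance = 1e-9)
  expect_true(all(g$species_ranges >= 1 & g$species_ranges <= g$n_w))
  expect_true(all(g$resource_ranges >= 1 & g$resource_ranges <= g$n_w))
  # resource grid reaches at least 4 decades below the smallest egg
  expect_lte(min(g$w), min(m$species$w0) * 1e-4 * 1.0001)
})
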