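test_that("yield matches a hand integral and scales linearly in F", {
  m <- toy_model(F = 0.5)
  g <- m$grid
  st <- toy_state(m)
  expect_equal(as.numeric(yield(st, m)), 0)
  kk <- sapply(c(30, 60), function(x) which.min(abs(g$w - x)))
  st$N[1, kk] <- c(2e3, 4e2)
  hand <- 0.5 * sum(m$fsel[1, kk] * st$N[1, kk] * g$w[kk] * g$dw[kk])
  expect_equal(as.numeric(yield(st, m)), hand, tolerance = 1e-12)
  m2 <- m; m2$species$F <- 1
  expect_equal(as.numeric(yield(st, m2)), 2 * hand, tolerance = 1e-12)
  m0 <- m; m0$species$F <- 0
  expect_equal(as.numeric(yield(st, m0)), 0)
  # bins well above wmat carry full selectivity, well below none
  expect_equal(m$fsel[1, g$w > 1.2 * m$species$wmat],
               rep(1, sum(g$w > 1.2 * m$species$wmat)))
  expect_equal(m$fsel[1, g$w < 0.8 * m$species$wmat],
               rep(0, sum(g$w < 0.8 * m$species$wmat)))
})

test_that("mean weight is the abundance-weighted average", {
  m <- toy_model()
  g <- m$grid
  st <- toy_state(m)
  # equal numbers (N * dw) in two bins at ~1 g and ~3 g average to ~2 g
  k1 <- which.min(abs(g$w - 1)); k3 <- which.min(abs(g$w - 3))
  st$N[1, k1] <- 1 / g$dw[k1]
  st$N[1, k3] <- 1 / g$dw[k3]
  expect_equal(as.numeric(mean_weight(st, m)),
               (g$w[k1] + g$w[k3]) / 2, tolerance = 1e-12)
  st$N[1, k1] <- 0
  expect_equal(as.numeric(mean_weight(st, m)), g$w[k3], tolerance = 1e-12)
  # hand computation on an arbitrary toy spectrum
  st$N[1, ] <- 0; kk <- c(k1, k3, k3 + 2)
  st$N[1, kk] <- c(5, 2, 1)
  hand <- sum(st$N[1, kk] * g$w[kk] * g$dw[kk]) /
    sum(st$N[1, kk] * g$dw[kk])
  expect_equal(as.numeric(mean_weight(st, m)), hand, tolerance = 1e-12)
})

test_that("size_at_age integrates the growth field and refines cleanly", {
  m <- toy_model()
  ts <- toy_steady()
  waa <- size_at_age(m, ts$state, 1, ages = c(0, 1, 2, 4))
  expect_equal(waa[["0"]], m$species$w0)
  expect_true(all(diff(waa) > 0))
  # refinement oracle: halving the step changes weights < 0.5%
  fine <- size_at_age(m, ts$state, 1, ages = c(1, 2, 4), da = 0.002)
  expect_equal(as.numeric(waa[-1]) / as.numeric(fine), rep(1, 3),
               tolerance = 0.005)
})

test_that("relative metrics ratio, mask, and ensemble quantiles", {
  x <- matrix(1:6, 2)
  expect_equal(relative_metrics(x, x), matrix(1, 2, 3))
  b <- x; b[1, 1] <- 0
  expect_true(is.na(relative_metrics(x, b)[1, 1]))
  expect_error(relative_metrics(1:3, 1:4), "shape")
  draws <- lapply(1:100, function(d) c(a = d, b = 2 * d))
  q <- ensemble_quantiles(draws)
  expect_lt(q$q2.5[["a"]], q$q97.5[["a"]])
  expect_equal(as.numeric(q$q97.5[["b"]]), 2 * as.numeric(q$q97.5[["a"]]))
})

test_that("fmsy/yield slopes recover exact lines", {
  surf <- expand.grid(species = c("a", "b"), T_prop = c(0.9, 1, 1.1))
  surf$fmsy <- ifelse(surf$species == "a", 0.5 + 2 * surf$T_prop, 1)
  surf$msy <- ifelse(surf$species == "a", 10 - 3 * surf$T_prop, 7)
  sl <- fmsy_yield_slopes(surf)
  expect_equal(sl$slope_fmsy[sl$species == "a"], 2, tolerance = 1e-12)
  expect_equal(sl$slope_yield[sl$species == "a"], -3, tolerance = 1e-12)
  expect_equal(sl$slope_fmsy[sl$species == "b"], 0, tolerance = 1e-12)
  # 3 support points vs hand OLS
  d <- data.frame(species = "c", T_prop = c(1, 2, 4), fmsy = c(1, 3, 4),
                  msy = 0)
  hand <- sum((d$T_prop - mean(d$T_prop)) * (d$fmsy - mean(d$fmsy))) /
    sum((d$T_prop - mean(d$T_prop))^2)
  expect_equal(fmsy_yield_slopes(d)$slope_fmsy, hand, tolerance = 1e-12)
})

test_that("grid enumeration realizes the stated factorial design", {
  gs <- grid_spec()
  cells <- enumerate_grid(gs)
  expect_equal(length(gs$T_props), 51)
  expect_equal(length(gs$F_props), 39)
  expect_equal(nrow(cells), 1989)
  expect_equal(nrow(unique(cells)), 1989)
  expect_equal(range(gs$T_props), c(0.75, 1.25))
  expect_equal(range(gs$F_props), c(0.1, 2))
})

test_that("single-cell grid equals a direct steady run", {
  m <- toy_model()
  gs <- grid_spec(T_range = c(1, 1), F_range = c(1, 1))
  expect_equal(nrow(enumerate_grid(gs)), 1)
  solver <- solver_config(t_max = 80)
  surf <- run_constant_grid(m, gs, fmsy_ref = 0.4, solver = solver)
  st <- run_to_steady(m, solver = solver, F = 0.4)
  m2 <- m; m2$species$F <- 0.4
  expect_equal(surf$yield, as.numeric(yield(st, m2)), tolerance = 1e-6)
  expect_equal(surf$ssb, as.numeric(ssb(st, m2)), tolerance = 1e-6)
})

test_that("fmsy_search finds an interior optimum confirmed by a finer grid", {
  m <- toy_model()
  solver <- solver_config(t_max = 80)
  coarse <- fmsy_search(m, 1, F_grid = seq(0, 1.6, by = 0.2),
                        solver = solver)
  expect_gt(coarse$fmsy, 0)
  expect_false(coarse$on_boundary)
  # refinement oracle around the coarse optimum
  fine <- fmsy_search(m, 1,
                      F_grid = seq(max(0, coarse$fmsy - 0.3),
                                   coarse$fmsy + 0.3, by = 0.05),
                      solver = solver)
  expect_lte(abs(fine$fmsy - coarse$fmsy), 0.2)
  # SSB declines monotonically with F along the curve
  expect_true(all(diff(coarse$curve$ssb) < 0))
})

test_that("warming projection gates, baselines, and validates", {
  m <- toy_model(F = 0.2)
  years <- 1990:2000
  th <- data.frame(year = years,
                   T = 283.15 + 0.1 * (years - 1990))
  fh <- data.frame(year = 1990:1995, one = 0.2)
  expect_error(scenario_spec(fh, th[1:3, ], f_future = 0.2,
                             horizon_end = 2000),
               "cover")
  expect_error(scenario_spec(fh, th, f_future = 0.2, horizon_end = 2000,
                             baseline_freeze_year = 2040), "freeze")
  spc <- scenario_spec(fh, th, f_future = 0.3, burn_in = 30,
                       horizon_end = 2000, baseline_freeze_year = 1995,
                       n_draws = 2, seed = 5)
  # scenario "none": warming equals baseline exactly
  proj <- run_warming_projection(m, spc)
  expect_identical(proj$warming[[1]]$ssb, proj$baseline[[1]]$ssb)
  # identical up to the freeze year by construction
  expect_identical(proj$warming[[2]]$ssb[as.character(1990:1995), ],
                   proj$baseline[[2]]$ssb[as.character(1990:1995), ])
  # under "none" every draw gives the same trajectory
  expect_identical(proj$warming[[1]]$ssb, proj$warming[[2]]$ssb)
  # with physiology scaling, warming and baseline diverge after the freeze
  m2 <- m; m2$thermal <- thermal_config(scenario = "physiology")
  proj2 <- run_warming_projection(m2, spc)
  expect_false(identical(proj2$warming[[1]]$ssb["2000", ],
                         proj2$baseline[[1]]$ssb["2000", ]))
  expect_identical(proj2$warming[[1]]$ssb[as.character(1990:1995), ],
                   proj2$baseline[[1]]$ssb[as.character(1990:1995), ])
  ratio <- projection_size_at_age_ratio(m2, proj2, 1, ages = 1:3)
  expect_equal(dim(ratio), c(2, 3))
  expect_true(all(is.finite(ratio)))
})
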