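#' Scenario specification for warming projections
#'
#' @param f_history data.frame `year, <species...>` of historical fishing
#'   mortalities (one column per species, model order).
#' @param t_history data.frame `year, T` of annual temperature (K),
#'   covering every projection year.
#' @param f_future per-species fishing mortality applied after the last
#'   historical year (typically FMSY at the reference temperature).
#' @param burn_in years of constant forcing before the first historical
#'   year (default 100).
#' @param horizon_end final projection year (default 2050).
#' @param baseline_freeze_year year whose temperature the baseline holds
#'   fixed thereafter (default 1997, the calibration-window midpoint).
#' @param n_draws,seed activation-energy ensemble size and seed.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(f_history, t_history, f_future,
                          burn_in = 100, horizon_end = 2050,
                          baseline_freeze_year = 1997,
                          n_draws = 200, seed = 1) {
  if (burn_in < 0) stop("burn_in must be non-negative")
  years <- seq(min(f_history$year), horizon_end)
  if (!all(years %in% t_history$year))
    stop("t_history must cover every projection year")
  if (!(baseline_freeze_year %in% years))
    stop("baseline_freeze_year must lie within the projection horizon")
  structure(list(f_history = f_history, t_history = t_history,
                 f_future = f_future, burn_in = burn_in,
                 horizon_end = horizon_end,
                 baseline_freeze_year = baseline_freeze_year,
                 n_draws = n_draws, seed = seed), class = "scenario_spec")
}

# assemble per-year forcing (warming or frozen-baseline temperature)
scenario_forcing <- function(spec, n_sp, baseline = FALSE) {
  years <- seq(min(spec$f_history$year), spec$horizon_end)
  Fm <- matrix(NA_real_, length(years), n_sp)
  hist_years <- spec$f_history$year
  for (k in seq_along(years)) {
    y <- years[k]
    Fm[k, ] <- if (y <= max(hist_years))
      as.numeric(spec$f_history[match(y, hist_years), -1])
    else spec$f_future
  }
  Tv <- spec$t_history$T[match(years, spec$t_history$year)]
  if (baseline) {
    Tfreeze <- spec$t_history$T[match(spec$baseline_freeze_year,
                                      spec$t_history$year)]
    Tv[years > spec$baseline_freeze_year] <- Tfreeze
  }
  make_forcing(years, Tv, Fm)
}

#' Warming projection with an activation-energy ensemble
#'
#' For each ensemble draw: a burn-in under the first historical fishing
#' mortality and temperature, then a projection through the historical
#' fishing series and warming temperatures, switching to `f_future` after
#' the historical window; and an otherwise identical baseline run whose
#' temperature is frozen at its `baseline_freeze_year` value.
#'
#' @param model a `spectrum_model`.
#' @param spec a [scenario_spec()].
#' @param draws optional data.frame of activation energies (as from
#'   [sample_activation_energies()]); sampled from the model's thermal
#'   config (`spec$n_draws`, `spec$seed`) when omitted.
#' @param solver a [solver_config()].
#' @param state0 state from which each draw's burn-in starts (a fresh
#'   [initial_state()] by default; passing a pre-computed near-steady state
#'   shortens every burn-in).
#' @return list of class `warming_projection`: `warming` and `baseline`
#'   (lists of `sim_output`, one per draw), `draws`, `spec`.
#' @export
run_warming_projection <- function(model, spec, draws = NULL,
                                   solver = solver_config(),
                                   state0 = initial_state(model)) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_sp <- nrow(model$species)
  if (is.null(draws))
    draws <- sample_activation_energies(model$thermal, spec$n_draws,
                                        spec$seed)
  fw <- scenario_forcing(spec, n_sp, baseline = FALSE)
  fb <- scenario_forcing(spec, n_sp, baseline = TRUE)
  burn_solver <- solver
  burn_solver$t_max <- spec$burn_in
  warming <- baseline <- vector("list", nrow(draws))
  for (d in seq_len(nrow(draws))) {
    dr <- unlist(draws[d, c("E_met", "E_cons", "E_search", "E_mort",
                            "E_r0", "E_kappa")])
    st0 <- run_to_steady(model, state = state0, solver = burn_solver,
                         T = fw$T[1], F = fw$F[1, ], draw = dr)
    warming[[d]] <- project(st0, model, solver, fw, draw = dr)
    baseline[[d]] <- project(st0, model, solver, fb, draw = dr)
  }
  structure(list(warming = warming, baseline = baseline, draws = draws,
                 spec = spec), class = "warming_projection")
}

#' Final-year size-at-age ratios of a warming projection
#'
#' Weight-at-age of a cohort growing through the final projection year's
#' quasi-steady conditions, per draw, as a warming/baseline ratio.
#'
#' @param model a `spectrum_model`.
#' @param proj a `warming_projection`.
#' @param i species index or name.
#' @param ages ages (yr).
#' @return matrix draws x ages of ratios.
#' @export
projection_size_at_age_ratio <- function(model, proj, i, ages = 1:8) {
  n_d <- length(proj$warming)
  out <- matrix(NA_real_, n_d, length(ages),
                dimnames = list(NULL, ages))
  for (d in seq_len(n_d)) {
    dr <- unlist(proj$draws[d, c("E_met", "E_cons", "E_search", "E_mort",
                                 "E_r0", "E_kappa")])
    sw <- proj$warming[[d]]$state
    sb <- proj$baseline[[d]]$state
    tfw <- thermal_factors(model, sw$T, draw = dr)
    tfb <- thermal_factors(model, sb$T, draw = dr)
    ww <- size_at_age(model, sw, i, ages, tf = tfw)
    wb <- size_at_age(model, sb, i, ages, tf = tfb)
    out[d, ] <- relative_metrics(ww, wb)
  }
  out
}

#' Grid specification for constant temperature x fishing scenarios
#'
#' Full-factorial proportions of the reference temperature and of the
#' reference FMSY.  Default steps (0.01 on the temperature axis, 0.05 on
#' the fishing axis) give 51 x 39 = 1989 cells over the default ranges.
#'
#' @param T_range range of temperature proportions (of `Tref`, Kelvin
#'   scale), default `c(0.75, 1.25)`.
#' @param T_step temperature-proportion step, default 0.01.
#' @param F_range range of fishing proportions (of `FMSY` at `Tref`),
#'   default `c(0.1, 2)`.
#' @param F_step fishing-proportion step, default 0.05.
#' @return list of class `grid_spec` with `T_props`, `F_props`.
#' @export
grid_spec <- function(T_range = c(0.75, 1.25), T_step = 0.01,
                      F_range = c(0.1, 2), F_step = 0.05) {
  structure(list(T_props = seq(T_range[1], T_range[2], by = T_step),
                 F_props = seq(F_range[1], F_range[2], by = F_step)),
            class = "grid_spec")
}

#' Enumerate the cells of a constant-scenario grid
#'
#' @param gridspec a [grid_spec()].
#' @return data.frame with columns `T_prop`, `F_prop`, one row per cell.
#' @export
enumerate_grid <- function(gridspec) {
  expand.grid(T_prop = gridspec$T_props, F_prop = gridspec$F_props,
              KEEP.OUT.ATTRS = FALSE)
}

#' Steady-state yield surface over constant temperature and fishing
#'
#' Runs every grid cell to steady state at `T = T_prop * Tref` (Kelvin
#' scale) and `F_i = F_prop * fmsy_ref_i`, recording per-species yield and
#' SSB.  Runs warm-start along the fishing axis within each temperature.
#'
#' @param model a `spectrum_model`.
#' @param gridspec a [grid_spec()].
#' @param fmsy_ref per-species reference FMSY (1/yr).
#' @param solver a [solver_config()].
#' @param draw activation-energy draw (configured means by default).
#' @return data.frame `T_prop, F_prop, species, yield, ssb`.
#' @export
run_constant_grid <- function(model, gridspec, fmsy_ref,
                              solver = solver_config(),
                              draw = mean_draw(model$thermal)) {
  cells <- enumerate_grid(gridspec)
  sp_names <- model$species$name
  res <- vector("list", nrow(cells))
  k <- 0
  for (tp in gridspec$T_props) {
    st <- initial_state(model)
    for (fp in gridspec$F_props) {
      k <- k + 1
      st <- run_to_steady(model, state = st, solver = solver,
                          T = tp * model$thermal$Tref,
                          F = fp * fmsy_ref, draw = draw)
      m <- model; m$species$F <- fp * fmsy_ref
      res[[k]] <- data.frame(T_prop = tp, F_prop = fp, species = sp_names,
                             yield = as.numeric(yield(st, m)),
                             ssb = as.numeric(ssb(st, m)))
    }
  }
  do.call(rbind, res)
}

#' Search for the fishing mortality maximizing steady-state yield
#'
#' One-species-at-a-time grid search: the focal species' `F` is varied
#' over `F_grid` while all other species are held at `F_others`, each
#' candidate run to steady state (warm-started from the previous one), and
#' the `F` with the highest steady yield returned.
#'
#' @param model a `spectrum_model`.
#' @param species index or name of the focal species.
#' @param F_others per-species fishing mortalities for the non-focal
#'   species (the focal entry is ignored); defaults to the parameter-table
#'   values.
#' @param T temperature (K), default the reference.
#' @param F_grid candidate fishing mortalities, default `seq(0, 3, 0.05)`.
#' @param solver a [solver_config()].
#' @param draw activation-energy draw.
#' @return list: `fmsy`, `msy`, `curve` (data.frame `F, yield, ssb`),
#'   `on_boundary` (TRUE when the argmax sits on the grid edge).
#' @export
fmsy_search <- function(model, species, F_others = model$species$F,
                        T = model$thermal$Tref,
                        F_grid = seq(0, 3, by = 0.05),
                        solver = solver_config(),
                        draw = mean_draw(model$thermal)) {
  if (is.character(species)) species <- match(species, model$species$name)
  yields <- ssbs <- numeric(length(F_grid))
  st <- initial_state(model)
  for (k in seq_along(F_grid)) {
    Fv <- F_others
    Fv[species] <- F_grid[k]
    st <- run_to_steady(model, state = st, solver = solver, T = T,
                        F = Fv, draw = draw)
    m <- model; m$species$F <- Fv
    yields[k] <- yield(st, m, species)
    ssbs[k] <- ssb(st, m, species)
  }
  best <- which.max(yields)
  list(fmsy = F_grid[best], msy = yields[best],
       curve = data.frame(F = F_grid, yield = yields, ssb = ssbs),
       on_boundary = best %in% c(1L, length(F_grid)))
}

#' FMSY and maximum yield per temperature
#'
#' Repeats [fmsy_search()] for every species over a set of temperature
#' proportions, the input for [fmsy_yield_slopes()].
#'
#' @param model a `spectrum_model`.
#' @param T_props temperature proportions of `Tref`.
#' @param F_others baseline fishing mortalities for non-focal species.
#' @param F_grid candidate fishing mortalities.
#' @param solver a [solver_config()].
#' @param draw activation-energy draw.
#' @return data.frame `species, T_prop, fmsy, msy`.
#' @export
fmsy_by_temperature <- function(model, T_props,
                                F_others = model$species$F,
                                F_grid = seq(0, 3, by = 0.05),
                                solver = solver_config(),
                                draw = mean_draw(model$thermal)) {
  out <- list()
  for (i in seq_len(nrow(model$species))) {
    for (tp in T_props) {
      fs <- fmsy_search(model, i, F_others, T = tp * model$thermal$Tref,
                        F_grid = F_grid, solver = solver, draw = draw)
      out[[length(out) + 1]] <- data.frame(
        species = model$species$name[i], T_prop = tp,
        fmsy = fs$fmsy, msy = fs$msy)
    }
  }
  do.call(rbind, out)
}
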