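#' Calibration targets
#'
#' Bundles the observations the model is calibrated against: per-species
#' spawning-stock-biomass over a calibration window (as a window average or
#' an annual series), the window-mean fishing mortality, and optional
#' weight-at-age growth targets.
#'
#' @param ssb named per-species window-average SSB (model biomass units);
#'   may be omitted when `ssb_series` is given.
#' @param f_bar named per-species window-mean fishing mortality (1/yr).
#' @param ssb_series optional data.frame `species, year, ssb` from which
#'   the window average is computed.
#' @param growth optional data.frame `species, age, w` of weight-at-age
#'   targets.
#' @return list of class `calibration_targets`.
#' @export
calibration_targets <- function(ssb = NULL, f_bar, ssb_series = NULL,
                                growth = NULL) {
  if (is.null(ssb)) {
    if (is.null(ssb_series)) stop("supply ssb or ssb_series")
    agg <- tapply(ssb_series$ssb, ssb_series$species, mean)
    ssb <- as.numeric(agg); names(ssb) <- names(agg)
  }
  if (any(ssb <= 0)) stop("SSB targets must be positive")
  if (is.null(names(ssb)) || is.null(names(f_bar)))
    stop("ssb and f_bar must be named by species")
  structure(list(ssb = ssb, f_bar = f_bar, ssb_series = ssb_series,
                 growth = growth), class = "calibration_targets")
}

#' Calibrate maximum recruitment to SSB targets
#'
#' Fits `log10(Rmax)` for every species by minimizing the residual sum of
#' squares between log steady-state model SSB (at the reference
#' temperature and the targets' window-mean fishing mortality) and log
#' target SSB, using bounded quasi-Newton (`L-BFGS-B`) on the steady-state
#' map.  Successive objective evaluations warm-start from the previous
#' steady state, so the fit costs far less than independent 200-yr runs.
#'
#' @param model a `spectrum_model`.
#' @param targets a [calibration_targets()] object.
#' @param bounds half-width (dex) of the box around the starting
#'   `log10(Rmax)`, or a 2-column matrix of per-species `lower`, `upper`.
#' @param solver a [solver_config()].
#' @param control passed to [stats::optim()] (sensible defaults set).
#' @param presmooth number of multiplicative fixed-point pre-iterations
#'   (`Rmax <- Rmax * target/SSB`) used to find the quasi-Newton starting
#'   point (default 3; 0 disables).
#' @return list of class `rmax_fit`: `Rmax` (fitted), `log10_Rmax`,
#'   `objective`, `converged`, `coexist`, `ssb_model`, `ssb_target`,
#'   `optim` (raw result), and `model` with the fitted `Rmax` installed.
#' @export
calibrate_rmax <- function(model, targets, bounds = 3,
                           solver = solver_config(),
                           control = list(), presmooth = 3) {
  stopifnot(inherits(targets, "calibration_targets"))
  sp_names <- model$species$name
  tgt <- targets$ssb[sp_names]
  fbar <- targets$f_bar[sp_names]
  if (anyNA(tgt) || anyNA(fbar))
    stop("targets must cover every model species")
  start <- log10(model$species$Rmax)
  if (is.matrix(bounds)) {
    lo <- bounds[, 1]; hi <- bounds[, 2]
  } else {
    lo <- start - bounds; hi <- start + bounds
  }
  if (any(lo > hi)) stop("infeasible bounds: lower exceeds upper")

  # stage 1: multiplicative fixed-point pre-conditioning.  Steady SSB is
  # close to proportional to Rmax over decades, so Rmax <- Rmax * tgt/SSB
  # lands within a fraction of a dex of the optimum in a few steady runs,
  # leaving the quasi-Newton polish only local work
  st <- run_to_steady(model, solver = solver, F = fbar)
  par0 <- start
  for (it in seq_len(presmooth)) {
    s <- pmax(attr(st, "ssb_mean"), 1e-300)
    par0 <- pmin(pmax(par0 + log10(tgt / s), lo), hi)
    m <- model
    m$species$Rmax <- 10^par0
    st <- run_to_steady(m, state = st, solver = solver, F = fbar)
  }
  # stage 2: bounded quasi-Newton on the steady-state map.  Every
  # evaluation warm-starts from the same base steady state, so the
  # objective is a deterministic function of the parameters (a mutable
  # warm start would make line searches compare inconsistent values)
  base_state <- st
  # polish evaluations run on a capped horizon: after pre-conditioning the
  # state is near-steady, and a fixed budget keeps the objective smooth in
  # the parameters while bounding cost; the final refit uses the full
  # horizon
  obj_solver <- solver
  obj_solver$t_max <- min(solver$t_max, 80)
  n_eval <- 0L
  objective <- function(par) {
    m <- model
    m$species$Rmax <- 10^par
    st <- run_to_steady(m, state = base_state, solver = obj_solver,
                        F = fbar)
    n_eval <<- n_eval + 1L
    s <- attr(st, "ssb_mean")   # cycle-averaged, phase-insensitive
    sum((log(pmax(s, 1e-12 * tgt)) - log(tgt))^2)
  }
  ctrl <- utils::modifyList(list(maxit = 5, factr = 1e11,
                                 ndeps = rep(0.05, length(start))), control)
  opt <- stats::optim(par0, objective, method = "L-BFGS-B",
                      lower = lo, upper = hi, control = ctrl)
  m <- model
  m$species$Rmax <- 10^opt$par
  st <- run_to_steady(m, state = base_state, solver = solver, F = fbar)
  s <- ssb(st, m)
  coexist <- all(s > 1e-12 * tgt)
  if (!coexist)
    warning("calibration failure: at least one species effectively ",
            "extinct at the optimum")
  structure(list(Rmax = stats::setNames(10^opt$par, sp_names),
                 log10_Rmax = stats::setNames(opt$par, sp_names),
                 objective = opt$value, converged = opt$convergence == 0,
                 coexist = coexist, ssb_model = s, ssb_target = tgt,
                 n_eval = n_eval, optim = opt, model = m, state = st),
            class = "rmax_fit")
}

#' Tune maximum consumption to growth targets
#'
#' Stepwise multiplicative search on each species' maximum-consumption
#' coefficient `h`, minimizing the squared log error between emergent
#' steady-state weight-at-age and the supplied targets.  Deterministic
#' given its inputs; with `max_iter = 0` the initial `h` is returned with a
#' warning.
#'
#' @param model a `spectrum_model`.
#' @param growth_targets data.frame `species, age, w`.
#' @param step_factor multiplicative step (> 1), default 1.1.
#' @param max_iter maximum coordinate passes, default 10.
#' @param solver a [solver_config()].
#' @return list: `h` (tuned, named), `model` with tuned `h`, `objective`,
#'   `iterations`.
#' @export
tune_h_to_growth <- function(model, growth_targets, step_factor = 1.1,
                             max_iter = 10, solver = solver_config()) {
  if (max_iter == 0) {
    warning("max_iter = 0: returning initial h unchanged")
    return(list(h = stats::setNames(model$species$h, model$species$name),
                model = model, objective = NA_real_, iterations = 0L))
  }
  base_state <- run_to_steady(model, solver = solver)
  obj <- function(m) {
    st <- run_to_steady(m, state = base_state, solver = solver)
    tf <- thermal_factors(m, m$thermal$Tref)
    tot <- 0
    for (s in unique(growth_targets$species)) {
      i <- match(s, m$species$name)
      d <- growth_targets[growth_targets$species == s & growth_targets$age > 0, ]
      waa <- size_at_age(m, st, i, ages = d$age, tf = tf)
      tot <- tot + sum((log(pmax(waa, 1e-12)) - log(d$w))^2)
    }
    tot
  }
  m <- model
  best <- obj(m)
  it <- 0L
  repeat {
    it <- it + 1L
    improved <- FALSE
    for (i in seq_len(nrow(m$species))) {
      for (fac in c(step_factor, 1 / step_factor)) {
        m2 <- rebuild_with_h(m, i, m$species$h[i] * fac)
        v <- obj(m2)
        if (v < best - 1e-12) {
          m <- m2; best <- v; improved <- TRUE
          break
        }
      }
    }
    if (!improved || it >= max_iter) break
  }
  list(h = stats::setNames(m$species$h, m$species$name), model = m,
       objective = best, iterations = it)
}

# changing h changes the derived search-volume coefficient too
rebuild_with_h <- function(model, i, h_new) {
  sp <- model$species
  sp$h[i] <- h_new
  sp$ks[i] <- sp$ks[i] * h_new / model$species$h[i]  # keep fc fixed
  spectrum_model(sp, model$resources, model$theta_R, model$thermal,
                 no_w = length(model$grid$fish_idx))
}

#' Density-dependence ratio
#'
#' Ratio of physiological recruitment (egg production) to realized
#' recruitment; equals `1 + R_phy / Rmax` under Beverton-Holt, so 1 means
#' no density dependence and 2 means recruitment at half the cap.
#'
#' @param R_phy physiological recruitment (numbers/yr).
#' @param R realized recruitment (numbers/yr).
#' @return ratio `>= 1`.
#' @export
density_dependence_ratio <- function(R_phy, R) R_phy / R
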