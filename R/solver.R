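#' Solver configuration
#'
#' @param dt time step (yr), default 0.1.
#' @param t_max integration horizon (yr) for steady-state runs, default 200.
#' @param steady_tol relative SSB change over the detection window below
#'   which the state counts as steady (default 1e-4).
#' @param steady_window window length (yr) for steady-state detection.
#' @return list of class `solver_config`.
#' @export
solver_config <- function(dt = 0.1, t_max = 200, steady_tol = 1e-4,
                          steady_window = 10) {
  if (dt <= 0 || steady_tol <= 0) stop("dt and steady_tol must be positive")
  structure(list(dt = dt, t_max = t_max, steady_tol = steady_tol,
                 steady_window = steady_window), class = "solver_config")
}

#' One implicit upwind step of the fish spectra
#'
#' Advances every species' number density by `dt` with a first-order
#' upwind scheme, implicit in weight (forward substitution along the
#' bidiagonal system).  The egg-boundary density is set so the recruitment
#' number flux equals `R`: `N(w0) = R / g(w0)`.
#'
#' @param state a `model_state`.
#' @param rates output of [compute_rates()] at the current state.
#' @param model a `spectrum_model`.
#' @param dt time step (yr).
#' @return updated `model_state` (densities non-negative).
#' @export
step_fish <- function(state, rates, model, dt) {
  g <- model$grid
  N <- state$N
  for (i in seq_len(nrow(model$species))) {
    k0 <- g$species_ranges[i, 1]; kend <- g$species_ranges[i, 2]
    gi <- rates$g[i, ]; mui <- rates$mu[i, ]
    R <- rates$R[i]
    if (gi[k0] <= 0) {
      if (R > 0)
        stop("boundary singularity: zero growth at the egg weight with ",
             "positive recruitment (species ", model$species$name[i], ")")
      # 0/0 flux condition: leave the egg bin untouched
    } else {
      N[i, k0] <- R / gi[k0]
    }
    idx <- (k0 + 1):kend
    a <- dt * gi[idx - 1] / g$dw[idx]
    # exponentially fitted effective mortality: the plain implicit factor
    # 1/(1 + mu*dw/g) under-resolves survival where mu*dw/g is O(1); using
    # (g/dw)*expm1(mu*dw/g) makes the discrete steady flux ratio equal the
    # analytic exp(-mu*dw/g) while staying first-order and stable
    ratio <- mui / pmax(gi, 1e-300)
    x <- pmin(0.5 * (ratio[idx] + ratio[idx - 1]) * g$dw[idx], 30)
    mu_eff <- pmax(mui[idx], gi[idx] * expm1(x) / g$dw[idx])
    bden <- 1 + dt * mu_eff + dt * gi[idx] / g$dw[idx]
    Ni <- N[i, ]
    prev <- N[i, k0]
    for (j in seq_along(idx)) {
      k <- idx[j]
      prev <- (Ni[k] + a[j] * prev) / bden[j]
      Ni[k] <- prev
    }
    Ni[-(k0:kend)] <- 0
    N[i, ] <- pmax(Ni, 0)
  }
  state$N <- N
  state$t <- state$t + dt
  state
}

#' One semi-implicit step of the background resources
#'
#' Semi-chemostat relaxation toward the (temperature-scaled) carrying
#' capacity under the current predation mortality, unconditionally stable.
#'
#' @param state a `model_state`.
#' @param mu_pre_R resource x weight predation mortality (1/yr).
#' @param model a `spectrum_model`.
#' @param dt time step (yr).
#' @param tf thermal factors from [thermal_factors()] (identity if omitted).
#' @return updated `model_state`.
#' @export
step_resource <- function(state, mu_pre_R, model, dt, tf = NULL) {
  if (is.null(tf)) tf <- thermal_factors_identity(model)
  g <- model$grid
  NR <- state$NR
  for (r in seq_len(nrow(model$resources))) {
    rp <- model$resources[r, ]
    rng <- g$resource_ranges[r, 1]:g$resource_ranges[r, 2]
    rate <- tf$r0 * rp$r0 * g$w[rng]^(rp$p - 1)
    cc <- tf$kappa * model$cc[r, rng]
    NR[r, rng] <- (NR[r, rng] + dt * rate * cc) /
      (1 + dt * (rate + mu_pre_R[r, rng]))
    NR[r, -rng] <- 0
  }
  state$NR <- pmax(NR, 0)
  state
}

# advance one year of n_steps sub-steps under constant forcing; F is set on
# the model beforehand, tf computed from the year's temperature
advance_year <- function(model, state, tf, dt) {
  n_steps <- max(1L, round(1 / dt))
  for (s in seq_len(n_steps)) {
    rates <- compute_rates(model, state, tf)
    state <- step_fish(state, rates, model, dt)
    state <- step_resource(state, rates$mu_pre_R, model, dt, tf)
  }
  if (any(!is.finite(state$N)) || any(!is.finite(state$NR)))
    stop("non-finite densities at t = ", signif(state$t, 6))
  state
}

#' Build a forcing table
#'
#' @param years integer vector of consecutive years.
#' @param T temperature (K), recycled to `length(years)`.
#' @param F fishing mortality: matrix `length(years) x n_species`, or a
#'   vector of per-species constants.
#' @param n_sp number of species (needed when `F` is a constant vector).
#' @return list of class `forcing` with fields `years`, `T`, `F`.
#' @export
make_forcing <- function(years, T, F, n_sp = NULL) {
  if (any(diff(years) <= 0)) stop("forcing years must be increasing")
  T <- rep_len(T, length(years))
  if (is.matrix(F)) {
    if (nrow(F) != length(years)) stop("F must have one row per year")
  } else {
    if (is.null(n_sp)) n_sp <- length(F)
    F <- matrix(F, length(years), n_sp, byrow = TRUE)
  }
  if (any(F < 0)) stop("F must be non-negative")
  structure(list(years = years, T = T, F = F), class = "forcing")
}

#' Project the model through a forcing series
#'
#' Integrates the coupled fish and resource equations year by year,
#' holding each year's fishing mortality and temperature constant within
#' the year, and records annual summaries (SSB, yield, recruitment) and,
#' optionally, the spectra.
#'
#' @param state a `model_state` to start from.
#' @param model a `spectrum_model`.
#' @param solver a [solver_config()].
#' @param forcing a [make_forcing()] table covering the projection.
#' @param draw activation-energy draw (named vector); configured means by
#'   default.
#' @param keep_spectra `"final"`, `"annual"` or `"none"`.
#' @return list of class `sim_output`: `years`, matrices `ssb`, `yield`,
#'   `R_phy`, `R` (year x species), final `state`, final-year `rates`, and
#'   `spectra` (if requested).
#' @export
project <- function(state, model, solver = solver_config(), forcing,
                    draw = mean_draw(model$thermal),
                    keep_spectra = c("final", "annual", "none")) {
  keep_spectra <- match.arg(keep_spectra)
  if (!inherits(forcing, "forcing")) stop("forcing must come from make_forcing()")
  n_y <- length(forcing$years)
  n_sp <- nrow(model$species)
  ssb_m <- yld <- rphy <- rr <- matrix(NA_real_, n_y, n_sp,
    dimnames = list(forcing$years, model$species$name))
  spectra <- if (keep_spectra == "annual") vector("list", n_y) else NULL
  m <- model
  rates <- NULL
  if (n_y == 0) {
    return(structure(list(years = integer(0), ssb = ssb_m, yield = yld,
                          R_phy = rphy, R = rr, state = state, rates = NULL,
                          spectra = spectra), class = "sim_output"))
  }
  for (y in seq_len(n_y)) {
    m$species$F <- forcing$F[y, ]
    state$T <- forcing$T[y]
    tf <- thermal_factors(m, state$T, draw = draw)
    state <- advance_year(m, state, tf, solver$dt)
    rates <- compute_rates(m, state, tf)
    ssb_m[y, ] <- ssb(state, m)
    yld[y, ] <- yield(state, m)
    rphy[y, ] <- rates$R_phy
    rr[y, ] <- rates$R
    if (keep_spectra == "annual") spectra[[y]] <- state$N
  }
  structure(list(years = forcing$years, ssb = ssb_m, yield = yld,
                 R_phy = rphy, R = rr, state = state, rates = rates,
                 spectra = spectra, forcing = forcing, draw = draw),
            class = "sim_output")
}

#' Run to steady state under constant forcing
#'
#' Projects with constant temperature and fishing mortality until the
#' relative SSB change over the detection window drops below the tolerance
#' or `t_max` (default 200 yr) is reached.
#'
#' @param model a `spectrum_model`.
#' @param state starting `model_state`; a fresh [initial_state()] by
#'   default.
#' @param solver a [solver_config()].
#' @param T temperature (K), default the reference.
#' @param F per-species fishing mortality; defaults to the values in the
#'   parameter table.
#' @param draw activation-energy draw.
#' @return final `model_state` with attributes `converged` (logical),
#'   `years` (yr run), `ssb`, `rates`.
#' @export
run_to_steady <- function(model, state = initial_state(model),
                          solver = solver_config(),
                          T = model$thermal$Tref,
                          F = model$species$F,
                          draw = mean_draw(model$thermal)) {
  m <- model
  m$species$F <- F
  state$T <- T
  tf <- thermal_factors(m, T, draw = draw)
  win <- solver$steady_window
  hist <- matrix(NA_real_, 2 * win + 1, nrow(m$species))
  converged <- FALSE
  years <- 0L
  while (years < solver$t_max) {
    state <- advance_year(m, state, tf, solver$dt)
    years <- years + 1L
    hist <- rbind(hist[-1, , drop = FALSE], ssb(state, m))
    recent <- hist[(win + 2):(2 * win + 1), , drop = FALSE]
    if (!anyNA(recent)) {
      base <- pmax(hist[2 * win + 1, ], 1e-300)
      rel <- apply(abs(sweep(recent, 2, hist[2 * win + 1, ])), 2, max) / base
      if (max(rel) < solver$steady_tol) { converged <- TRUE; break }
      # small persistent limit cycles: accept once the cycle-averaged SSB
      # (consecutive window means) has stopped drifting
      if (!anyNA(hist)) {
        m_old <- colMeans(hist[1:win, , drop = FALSE])
        m_new <- colMeans(recent)
        if (max(abs(m_new - m_old) / pmax(m_new, 1e-300)) <
              solver$steady_tol) { converged <- TRUE; break }
      }
    }
  }
  rates <- compute_rates(m, state, tf)
  attr(state, "converged") <- converged
  attr(state, "years") <- years
  attr(state, "ssb") <- ssb(state, m)
  attr(state, "ssb_mean") <- colMeans(hist[(win + 2):(2 * win + 1), ,
                                           drop = FALSE])
  attr(state, "rates") <- rates
  state
}
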