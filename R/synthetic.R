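#' Specification for synthetic forcing and target generation
#'
#' Stands in for the external inputs a real application would take from
#' stock assessments and a regional climate model: annual SSB series,
#' annual fishing mortalities, and a smooth warming trajectory.
#'
#' @param seed RNG seed.
#' @param ssb_noise_cv lognormal CV of the SSB targets (default 0.05).
#' @param warming_delta_2050 warming (K) above the reference temperature
#'   reached by 2050 (default 2).
#' @param t_noise_sd AR(1) innovation sd of interannual temperature noise
#'   (K), default 0.15.
#' @param t_noise_ar AR(1) coefficient, default 0.6.
#' @param f_noise_cv lognormal CV around the piecewise fishing levels.
#' @param f_levels named list, per species, of data.frames `year, F`
#'   giving piecewise-constant levels (level holds from its year until the
#'   next); defaults sketch a rise-and-fall piscivore fishery and steadier
#'   forage-fish fisheries.
#' @param calibration_window years used for calibration averaging.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, ssb_noise_cv = 0.05,
                           warming_delta_2050 = 2,
                           t_noise_sd = 0.15, t_noise_ar = 0.6,
                           f_noise_cv = 0,
                           f_levels = NULL,
                           calibration_window = 1992:2002) {
  if (ssb_noise_cv < 0 || f_noise_cv < 0) stop("noise CVs must be >= 0")
  if (!is.finite(warming_delta_2050)) stop("warming_delta_2050 must be finite")
  if (is.null(f_levels))
    f_levels <- list(
      sprat   = data.frame(year = c(1974, 1990, 2005), F = c(0.2, 0.35, 0.3)),
      herring = data.frame(year = c(1974, 1990, 2005), F = c(0.2, 0.3, 0.25)),
      cod     = data.frame(year = c(1974, 1985, 2000), F = c(0.4, 0.9, 0.6)))
  structure(list(seed = seed, ssb_noise_cv = ssb_noise_cv,
                 warming_delta_2050 = warming_delta_2050,
                 t_noise_sd = t_noise_sd, t_noise_ar = t_noise_ar,
                 f_noise_cv = f_noise_cv, f_levels = f_levels,
                 calibration_window = calibration_window),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic annual temperature series
#'
#' A smooth accelerating warming trend with AR(1) interannual noise,
#' re-centered so the calibration-window mean equals `Tref` and scaled so
#' the trend reaches `Tref + warming_delta_2050` in 2050.
#'
#' @param spec a [synthetic_spec()].
#' @param years years to cover (default 1970:2050).
#' @param Tref reference temperature (K).
#' @return data.frame `year, T` (Kelvin).
#' @export
generate_temperature_series <- function(spec, years = 1970:2050,
                                        Tref = 283.15) {
  x <- (years - min(years)) / (2050 - min(years))
  raw <- x^2                                     # accelerating trend
  win <- years %in% spec$calibration_window
  raw <- raw - mean(raw[win])
  at2050 <- (2050 - min(years)) / (2050 - min(years))
  denom <- at2050^2 - mean(((spec$calibration_window - min(years)) /
                              (2050 - min(years)))^2)
  trend <- spec$warming_delta_2050 * raw / denom
  noise <- with_seed(spec$seed, {
    e <- stats::rnorm(length(years), 0, spec$t_noise_sd)
    as.numeric(stats::filter(e, spec$t_noise_ar, method = "recursive"))
  })
  T <- Tref + trend + noise
  T <- T - mean(T[win]) + Tref                   # exact window re-centering
  data.frame(year = years, T = T)
}

#' Generate a synthetic fishing-mortality history
#'
#' Piecewise-constant per-species levels with optional multiplicative
#' lognormal noise, clamped non-negative.
#'
#' @param spec a [synthetic_spec()].
#' @param years years to cover (default 1974:2012).
#' @return data.frame `year` plus one column per species.
#' @export
generate_fishing_history <- function(spec, years = 1974:2012) {
  out <- data.frame(year = years)
  noise_sd <- sqrt(log(1 + spec$f_noise_cv^2))
  with_seed(spec$seed + 1, {
    for (s in names(spec$f_levels)) {
      lv <- spec$f_levels[[s]]
      idx <- findInterval(years, lv$year)
      f <- lv$F[pmax(idx, 1)]
      if (spec$f_noise_cv > 0)
        f <- f * exp(stats::rnorm(length(f), -noise_sd^2 / 2, noise_sd))
      out[[s]] <- pmax(f, 0)
    }
  })
  out
}

#' Generate synthetic SSB calibration targets from a known model
#'
#' Runs the supplied model (with its "true" `Rmax`) to steady state at the
#' reference temperature and window-mean fishing mortality, then perturbs
#' the steady SSB with multiplicative lognormal noise of the given CV.
#' Used to test that calibration recovers known parameters.
#'
#' @param model a `spectrum_model` holding the true parameters.
#' @param spec a [synthetic_spec()] (`ssb_noise_cv`, `seed`).
#' @param f_bar per-species window-mean fishing mortality; parameter-table
#'   values by default.
#' @param solver a [solver_config()].
#' @return a [calibration_targets()] object; the unperturbed steady SSB is
#'   attached as attribute `ssb_true`.
#' @export
generate_ssb_targets <- function(model, spec, f_bar = NULL,
                                 solver = solver_config()) {
  if (is.null(f_bar))
    f_bar <- stats::setNames(model$species$F, model$species$name)
  st <- run_to_steady(model, solver = solver, F = f_bar)
  s_true <- ssb(st, model)
  sdlog <- sqrt(log(1 + spec$ssb_noise_cv^2))
  s_obs <- with_seed(spec$seed + 2,
    s_true * exp(stats::rnorm(length(s_true), -sdlog^2 / 2, sdlog)))
  tg <- calibration_targets(ssb = s_obs, f_bar = f_bar)
  attr(tg, "ssb_true") <- s_true
  tg
}

#' Generate von Bertalanffy weight-at-age growth targets
#'
#' Closed-form cube-of-length von Bertalanffy weight curve
#' `w(a) = W_inf * (1 - exp(-K * (a - a0)))^3`.
#'
#' @param vb data.frame `species, W_inf, K, a0` (a0 defaults to 0 when
#'   absent).
#' @param ages ages (yr).
#' @return data.frame `species, age, w`.
#' @export
generate_growth_targets <- function(vb, ages = 1:10) {
  if (is.null(vb$a0)) vb$a0 <- 0
  out <- expand.grid(species = vb$species, age = ages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- match(out$species, vb$species)
  out$w <- vb$W_inf[k] *
    pmax(0, 1 - exp(-vb$K[k] * (out$age - vb$a0[k])))^3
  out[order(out$species, out$age), ]
}
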