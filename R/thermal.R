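#' Thermal configuration
#'
#' Activation energies (mean, sd) for the six temperature-scaled rates, the
#' reference temperature, and the scenario switch deciding whether
#' temperature acts on fish physiology, on the background resources, on
#' both, or on neither.
#'
#' By convention search volume scales identically to maximum consumption
#' (both are feeding rates) and background mortality identically to
#' metabolism (longevity tracks metabolic rate); the six energies are
#' nonetheless sampled independently in ensembles.
#'
#' @param Tref reference temperature (K) where every correction factor is 1.
#' @param k_B Boltzmann constant (eV/K).
#' @param E_met,E_cons,E_search,E_mort,E_r0,E_kappa numeric `c(mean, sd)`
#'   in eV for metabolism, maximum consumption, search volume, background
#'   mortality, resource regeneration and resource carrying capacity.
#' @param scenario one of `"none"`, `"physiology"`, `"resources"`, `"both"`.
#' @return list of class `thermal_config`.
#' @export
thermal_config <- function(Tref = 283.15, k_B = 8.617e-5,
                           E_met = c(0.59, 0.08),
                           E_cons = c(0.69, 0.10),
                           E_search = E_cons,
                           E_mort = E_met,
                           E_r0 = c(0.63, 0.10),
                           E_kappa = E_r0,
                           scenario = c("none", "physiology", "resources",
                                        "both")) {
  scenario <- match.arg(scenario)
  es <- list(E_met = E_met, E_cons = E_cons, E_search = E_search,
             E_mort = E_mort, E_r0 = E_r0, E_kappa = E_kappa)
  for (nm in names(es)) {
    e <- es[[nm]]
    if (length(e) == 1) es[[nm]] <- c(e, 0)
    if (es[[nm]][2] < 0) stop(nm, ": sd must be non-negative")
  }
  if (Tref <= 0) stop("Tref must be positive (Kelvin)")
  structure(c(list(Tref = Tref, k_B = k_B, scenario = scenario), es),
            class = "thermal_config")
}

#' Arrhenius temperature correction factor
#'
#' Exponential rate multiplier equal to 1 at the reference temperature and
#' increasing with temperature when the activation energy is positive.
#'
#' @param E activation energy (eV); negative values give declining rates.
#' @param T temperature (K).
#' @param thermal a [thermal_config()] (supplies `Tref` and `k_B`).
#' @return dimensionless multiplier.
#' @export
arrhenius_factor <- function(E, T, thermal = thermal_config()) {
  exp(E * (T - thermal$Tref) / (thermal$k_B * T * thermal$Tref))
}

# mean activation energies of a thermal config as a draw
mean_draw <- function(thermal) {
  c(E_met = thermal$E_met[1], E_cons = thermal$E_cons[1],
    E_search = thermal$E_search[1], E_mort = thermal$E_mort[1],
    E_r0 = thermal$E_r0[1], E_kappa = thermal$E_kappa[1])
}

#' Sample activation-energy ensembles
#'
#' Draws `n_draws` independent sextets of activation energies from the
#' normal distributions in the thermal configuration.  Reproducible for a
#' given seed.
#'
#' @param thermal a [thermal_config()].
#' @param n_draws ensemble size (default 200).
#' @param seed RNG seed.
#' @return data.frame with columns `draw`, `E_met`, `E_cons`, `E_search`,
#'   `E_mort`, `E_r0`, `E_kappa` and attribute `seed`.
#' @export
sample_activation_energies <- function(thermal, n_draws = 200, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nm <- c("E_met", "E_cons", "E_search", "E_mort", "E_r0", "E_kappa")
  out <- data.frame(draw = seq_len(n_draws))
  for (v in nm)
    out[[v]] <- stats::rnorm(n_draws, thermal[[v]][1], thermal[[v]][2])
  attr(out, "seed") <- seed
  out
}

#' Standard deviation from a 95% confidence interval
#'
#' The sd for which a normal distribution centred on `mean` places 95% of
#' its mass inside `[ci_low, ci_high]`; for asymmetric intervals the mean
#' half-width is used.
#'
#' @param ci_low,ci_high interval bounds.
#' @param mean centre of the distribution.
#' @return standard deviation.
#' @export
sd_from_ci <- function(ci_low, ci_high, mean) {
  half <- ((mean - ci_low) + (ci_high - mean)) / 2
  half / stats::qnorm(0.975)
}

#' Temperature scaling of physiological rate coefficients
#'
#' Multiplies the coefficients of maximum consumption, search volume,
#' metabolism and background mortality by their Arrhenius factors.  Growth
#' is never scaled directly: its temperature response emerges from the
#' scaled intake and metabolism.  Identity unless the scenario includes
#' physiology.
#'
#' @param sp a `species_params` table (all species).
#' @param T temperature (K).
#' @param thermal a [thermal_config()].
#' @param draw named activation-energy vector (one ensemble member);
#'   defaults to the configured means.
#' @return `sp` with `h`, `ks`, `mu0` rescaled and a `gamma_factor`
#'   attribute holding the search-volume multiplier.
#' @export
scale_physiology <- function(sp, T, thermal, draw = mean_draw(thermal)) {
  tf <- thermal_factors(model = NULL, T = T, thermal = thermal, draw = draw,
                        n_sp = nrow(sp))
  out <- sp
  out$h <- sp$h * tf$h
  out$ks <- sp$ks * tf$ks
  out$mu0 <- sp$mu0 * tf$mu0
  attr(out, "gamma_factor") <- tf$gamma
  out
}

#' Temperature scaling of resource parameters
#'
#' Regeneration speeds up with temperature while carrying capacity declines
#' at the corresponding rate (negative exponent); the spectrum slope is
#' untouched.  Identity unless the scenario includes resources.
#'
#' @param rp a `resource_params` table.
#' @param T temperature (K).
#' @param thermal a [thermal_config()].
#' @param draw named activation-energy vector.
#' @return `rp` with `r0` and `kappa` rescaled.
#' @export
scale_resource <- function(rp, T, thermal, draw = mean_draw(thermal)) {
  tf <- thermal_factors(model = NULL, T = T, thermal = thermal, draw = draw,
                        n_sp = 1)
  out <- rp
  out$r0 <- rp$r0 * tf$r0
  out$kappa <- rp$kappa * tf$kappa
  out
}

#' Per-step thermal rate factors
#'
#' The multiplicative factors applied to reference-value coefficients at
#' temperature `T`.  Factors are always computed from the reference values,
#' never compounded across steps.
#'
#' @param model a `spectrum_model` (used for its thermal config and species
#'   count) or `NULL` when `thermal` and `n_sp` are given directly.
#' @param T temperature (K).
#' @param thermal,draw,n_sp overrides when `model` is `NULL`.
#' @return list with per-species vectors `h`, `gamma`, `ks`, `mu0` and
#'   scalars `r0`, `kappa`.
#' @export
thermal_factors <- function(model, T, thermal = model$thermal,
                            draw = mean_draw(thermal),
                            n_sp = nrow(model$species)) {
  phys <- thermal$scenario %in% c("physiology", "both")
  res <- thermal$scenario %in% c("resources", "both")
  one <- rep(1, n_sp)
  f <- list(h = one, gamma = one, ks = one, mu0 = one, r0 = 1, kappa = 1)
  if (phys) {
    f$h <- rep(arrhenius_factor(draw[["E_cons"]], T, thermal), n_sp)
    f$gamma <- rep(arrhenius_factor(draw[["E_search"]], T, thermal), n_sp)
    f$ks <- rep(arrhenius_factor(draw[["E_met"]], T, thermal), n_sp)
    f$mu0 <- rep(arrhenius_factor(draw[["E_mort"]], T, thermal), n_sp)
  }
  if (res) {
    f$r0 <- arrhenius_factor(draw[["E_r0"]], T, thermal)
    f$kappa <- arrhenius_factor(-draw[["E_kappa"]], T, thermal)
  }
  f
}

thermal_factors_identity <- function(model) {
  n_sp <- nrow(model$species)
  list(h = rep(1, n_sp), gamma = rep(1, n_sp), ks = rep(1, n_sp),
       mu0 = rep(1, n_sp), r0 = 1, kappa = 1)
}
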