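#' Log-normal prey-size selection
#'
#' Preference of a predator of weight `wi` for prey of weight `wp`,
#' maximal (= 1) when the predator/prey weight ratio equals `beta` and
#' falling off as a Gaussian in the log of that ratio with width `sigma`.
#'
#' @param wp prey weight (g), positive.
#' @param wi predator weight (g), positive.
#' @param beta preferred predator-prey mass ratio.
#' @param sigma selection width (ln units).
#' @return preference in `[0, 1]`; vectorized over `wp`/`wi`.
#' @export
lognormal_selectivity <- function(wp, wi, beta, sigma) {
  if (any(wp <= 0) || any(wi <= 0)) stop("weights must be positive")
  exp(-(log(wi / (wp * beta)))^2 / (2 * sigma^2))
}

#' Search-volume coefficient from an assumed feeding level
#'
#' Derives the allometric search-volume coefficient gamma so that a
#' predator feeding on a power-law spectrum `kappa * w^(-lambda)` realizes
#' the assumed average feeding level `f0`.
#'
#' @param f0 assumed feeding level, strictly in (0, 1).
#' @param h maximum-consumption coefficient.
#' @param beta,sigma selection parameters.
#' @param lambda spectrum exponent.
#' @param kappa spectrum coefficient.
#' @return gamma, the search-volume coefficient.
#' @export
search_volume_coefficient <- function(f0, h, beta, sigma, lambda, kappa) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie strictly in (0, 1)")
  f0 * h * beta^(2 - lambda) * exp(-(lambda - 2)^2 * sigma^2 / 2) /
    ((1 - f0) * sqrt(2 * pi) * kappa * sigma)
}

#' Biomass of suitably sized prey available to a predator
#'
#' Midpoint-rule quadrature of prey biomass (all resources plus all fish
#' species, weighted by the preference matrix and by the log-normal size
#' selection) as seen by one predator individual.
#'
#' @param state a `model_state`.
#' @param model a `spectrum_model`.
#' @param predator species index.
#' @param wi predator weight (g), must lie on the grid within the
#'   predator's range (nearest grid point is used).
#' @return available prey biomass (g).
#' @export
available_energy <- function(state, model, predator, wi) {
  g <- model$grid
  j <- which.min(abs(log(g$w) - log(wi)))
  b <- prey_biomass_density(state, model)  # species x n_w, biomass*dw
  sum(model$phi[[predator]][j, ] * b[predator, ])
}

# prey biomass per bin (already multiplied by dw): theta-weighted resources
# plus all fish (theta_ij = 1), one row per predator species
prey_biomass_density <- function(state, model) {
  g <- model$grid
  fish <- colSums(state$N) * g$w * g$dw
  res <- state$NR * rep(g$w * g$dw, each = nrow(state$NR))
  b <- model$theta_R %*% res               # n_sp x n_w
  sweep(b, 2, fish, "+")
}

#' Encountered food
#'
#' Available prey biomass scaled by the allometric search volume.
#'
#' @param gamma search-volume coefficient.
#' @param q search-volume exponent.
#' @param w predator weight (g).
#' @param E_ava available prey biomass (g).
#' @return encountered food (g/yr).
#' @export
encounter_rate <- function(gamma, q, w, E_ava) gamma * w^q * E_ava

#' Feeding level (degree of satiation)
#'
#' Holling type-II response: encountered food relative to encountered food
#' plus maximum consumption.
#'
#' @param E_enc encountered food (g/yr).
#' @param h maximum-consumption coefficient.
#' @param w weight (g).
#' @param n maximum-consumption exponent.
#' @return feeding level in `[0, 1]`.
#' @export
feeding_level <- function(E_enc, h, w, n) E_enc / (E_enc + h * w^n)

#' Net energy available for growth and reproduction
#'
#' Assimilated intake minus metabolic costs, clamped at zero (deficits are
#' expressed through starvation mortality instead).
#'
#' @param f feeding level.
#' @param w weight (g).
#' @param sp one row of a `species_params` table.
#' @return net energy (g/yr), non-negative.
#' @export
net_energy <- function(f, w, sp) {
  pmax(0, sp$alpha * f * sp$h * w^sp$n - sp$ks * w^sp$p)
}

# smooth maturity ogive, 0 -> 1 around wmat
maturity_ogive <- function(w, wmat, m) 1 / (1 + (w / wmat)^(-m))

#' Allocation of net energy to reproduction
#'
#' Rises smoothly from 0 around the maturation weight to 1 at the
#' asymptotic weight, combining the maturity ogive with an allometric
#' factor that shuts growth off at `Wi`.
#'
#' @param w weight (g).
#' @param sp one row of a `species_params` table.
#' @return allocation fraction psi.
#' @export
maturity_allocation <- function(w, sp) {
  pmin(1, maturity_ogive(w, sp$wmat, sp$m) * (w / sp$Wi)^(1 - sp$n))
}

#' Somatic growth rate
#'
#' The share of net energy not allocated to reproduction.
#'
#' @param E_net net energy (g/yr).
#' @param psi allocation to reproduction.
#' @return growth rate (g/yr), non-negative.
#' @export
somatic_growth <- function(E_net, psi) pmax(0, E_net * (1 - psi))

#' Predation mortality on a prey weight
#'
#' Quadrature over all predator species and sizes of unsatiated search
#' effort directed at prey of weight `wp`.
#'
#' @param state a `model_state`.
#' @param model a `spectrum_model`.
#' @param prey `"resource"` or a species index (the preference of every
#'   predator for any fish species is 1; for a resource use the `theta_R`
#'   column via `resource` argument).
#' @param wp prey weight (g); nearest grid point is used.
#' @param resource optional resource index when `prey = "resource"`.
#' @param tf thermal rate factors as returned by [thermal_factors()];
#'   defaults to no temperature scaling.
#' @return predation mortality (1/yr).
#' @export
predation_mortality <- function(state, model, prey, wp, resource = NULL,
                                tf = NULL) {
  g <- model$grid
  k <- which.min(abs(log(g$w) - log(wp)))
  mu <- predation_mortality_grid(state, model, tf)
  if (identical(prey, "resource")) mu$resource[resource, k]
  else mu$fish[k]
}

# predation mortality over the whole grid: fish prey (theta_ij = 1 so one
# vector serves all species) and per-resource prey
predation_mortality_grid <- function(state, model, tf = NULL, rates = NULL) {
  g <- model$grid
  n_sp <- nrow(model$species)
  if (is.null(tf)) tf <- thermal_factors_identity(model)
  pred_fish <- numeric(g$n_w)
  pred_res <- matrix(0, nrow(model$resources), g$n_w)
  for (i in seq_len(n_sp)) {
    f <- if (is.null(rates)) feeding_level_grid(state, model, tf)[i, ]
         else rates$f[i, ]
    eff <- (1 - f) * tf$gamma[i] * model$gamma[i] *
      g$w^model$species$q[i] * state$N[i, ] * g$dw
    contrib <- as.numeric(crossprod(model$phi[[i]], eff))
    pred_fish <- pred_fish + contrib
    for (r in seq_len(nrow(model$resources)))
      pred_res[r, ] <- pred_res[r, ] + model$theta_R[i, r] * contrib
  }
  list(fish = pred_fish, resource = pred_res)
}

# feeding level for all species over the grid
feeding_level_grid <- function(state, model, tf = NULL) {
  if (is.null(tf)) tf <- thermal_factors_identity(model)
  g <- model$grid
  b <- prey_biomass_density(state, model)
  sp <- model$species
  f <- matrix(0, nrow(sp), g$n_w)
  for (i in seq_len(nrow(sp))) {
    E_ava <- as.numeric(model$phi[[i]] %*% b[i, ])
    E_enc <- tf$gamma[i] * model$gamma[i] * g$w^sp$q[i] * E_ava
    f[i, ] <- E_enc / (E_enc + tf$h[i] * sp$h[i] * g$w^sp$n[i])
  }
  f
}

#' Background mortality
#'
#' Constant, species-specific allometric mortality scaled by the asymptotic
#' weight.
#'
#' @param sp one row of a `species_params` table.
#' @return mortality (1/yr).
#' @export
background_mortality <- function(sp) sp$mu0 * sp$Wi^(sp$n - 1)

#' Starvation mortality
#'
#' Zero while assimilated intake covers metabolism; otherwise the deficit
#' divided by the usable reserve fraction of body weight.
#'
#' @param f feeding level.
#' @param w weight (g).
#' @param sp one row of a `species_params` table.
#' @return mortality (1/yr), continuous at the threshold.
#' @export
starvation_mortality <- function(f, w, sp) {
  deficit <- sp$ks * w^sp$p - sp$alpha * f * sp$h * w^sp$n
  pmax(0, deficit) / (sp$xi * w)
}

#' Knife-edge fishing mortality
#'
#' Full fishing mortality `F` at and above the maturation weight, zero
#' below (weight at first catch equals weight at maturation).
#'
#' @param w weight (g).
#' @param sp one row of a `species_params` table.
#' @return mortality (1/yr).
#' @export
fishing_mortality <- function(w, sp) ifelse(w >= sp$wmat, sp$F, 0)

#' Total egg production
#'
#' Integral of energy allocated to reproduction across the population,
#' converted to egg numbers with efficiency `erepro`, halved for the female
#' share.
#'
#' @param state a `model_state`.
#' @param model a `spectrum_model`.
#' @param i species index.
#' @param E_net optional precomputed net-energy vector on the grid.
#' @return physiological recruitment R_phy (numbers/yr).
#' @export
egg_production <- function(state, model, i, E_net = NULL) {
  g <- model$grid
  sp <- model$species[i, ]
  if (is.null(E_net)) {
    f <- feeding_level_grid(state, model)[i, ]
    E_net <- net_energy(f, g$w, sp)
  }
  sp$erepro / (2 * sp$w0) *
    sum(state$N[i, ] * E_net * model$psi[i, ] * g$dw)
}

#' Beverton-Holt recruitment
#'
#' Saturating stock-recruit relationship capping realized recruitment at
#' `Rmax`.
#'
#' @param R_phy physiological recruitment (numbers/yr).
#' @param Rmax maximum recruitment (numbers/yr).
#' @return realized recruitment, `<= min(R_phy, Rmax)`.
#' @export
beverton_holt <- function(R_phy, Rmax) Rmax * R_phy / (R_phy + Rmax)

#' Evaluate all per-step rates
#'
#' Computes, for the current state and thermal factors, the feeding level,
#' net energy, growth, all mortality components and their total, egg
#' production and realized recruitment for every species, plus predation
#' mortality on each resource spectrum.
#'
#' @param model a `spectrum_model`.
#' @param state a `model_state`.
#' @param tf thermal rate factors from [thermal_factors()]; identity when
#'   omitted.
#' @return list with matrices (species x weight) `f`, `E_net`, `g`, `mu`,
#'   and components `mu_pre`, `mu_bac`, `mu_stv`, `mu_fis`; vectors `R_phy`,
#'   `R`; matrix `mu_pre_R` (resource x weight).
#' @export
compute_rates <- function(model, state, tf = NULL) {
  if (is.null(tf)) tf <- thermal_factors_identity(model)
  g <- model$grid
  sp <- model$species
  n_sp <- nrow(sp); n_w <- g$n_w
  w <- g$w

  b <- prey_biomass_density(state, model)
  f <- matrix(0, n_sp, n_w)
  E_net <- gr <- mu_stv <- mu_fis <- matrix(0, n_sp, n_w)
  mu_bac <- numeric(n_sp)
  pred_fish <- numeric(n_w)
  pred_res <- matrix(0, nrow(model$resources), n_w)

  for (i in seq_len(n_sp)) {
    E_ava <- as.numeric(model$phi[[i]] %*% b[i, ])
    E_enc <- tf$gamma[i] * model$gamma[i] * model$wq[i, ] * E_ava
    hmax <- tf$h[i] * sp$h[i] * model$wn[i, ]
    f[i, ] <- E_enc / (E_enc + hmax)
    intake <- sp$alpha[i] * f[i, ] * hmax
    met <- tf$ks[i] * sp$ks[i] * model$wp[i, ]
    E_net[i, ] <- pmax(0, intake - met)
    # growth at the top bin is an outflow: the few survivors reaching the
    # asymptotic weight leave the resolved range instead of piling up in a
    # grid-dependent boundary spike
    gr[i, ] <- E_net[i, ] * (1 - model$psi[i, ])
    gr[i, !model$present[i, ]] <- 0
    E_net[i, !model$present[i, ]] <- 0
    mu_stv[i, ] <- pmax(0, met - intake) / (sp$xi[i] * w)
    mu_fis[i, ] <- sp$F[i] * model$fsel[i, ]
    mu_bac[i] <- tf$mu0[i] * sp$mu0[i] * sp$Wi[i]^(sp$n[i] - 1)

    eff <- (1 - f[i, ]) * tf$gamma[i] * model$gamma[i] * model$wq[i, ] *
      state$N[i, ] * g$dw
    contrib <- as.numeric(crossprod(model$phi[[i]], eff))
    pred_fish <- pred_fish + contrib
    pred_res <- pred_res + tcrossprod(model$theta_R[i, ], contrib)
  }

  mu_pre <- matrix(pred_fish, n_sp, n_w, byrow = TRUE)
  mu <- mu_pre + mu_stv + mu_fis + mu_bac

  R_phy <- vapply(seq_len(n_sp), function(i)
    sp$erepro[i] / (2 * sp$w0[i]) *
      sum(state$N[i, ] * E_net[i, ] * model$psi[i, ] * g$dw), numeric(1))
  R <- beverton_holt(R_phy, sp$Rmax)

  list(f = f, E_net = E_net, g = gr, mu = mu, mu_pre = mu_pre,
       mu_bac = mu_bac, mu_stv = mu_stv, mu_fis = mu_fis,
       R_phy = R_phy, R = R, mu_pre_R = pred_res)
}
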