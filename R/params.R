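#' Species bioenergetic parameters
#'
#' Builds and validates the per-species parameter table used throughout the
#' model.  One row per species; columns follow the standard size-spectrum
#' bioenergetic parameterization.
#'
#' @param name character, species label.
#' @param w0 egg weight (g).
#' @param Wi asymptotic weight (g), where allocation to growth reaches zero.
#' @param wmat maturation weight (g).
#' @param m steepness of the maturity ogive (dimensionless).
#' @param n mass exponent of maximum consumption.
#' @param p mass exponent of standard metabolism.
#' @param q mass exponent of search volume.
#' @param h coefficient of maximum consumption, g^(1-n)/yr.
#' @param ks coefficient of standard metabolism, g^(1-p)/yr.  `NA` defaults to
#'   the critical-feeding-level convention `fc * alpha * h` with `fc = 0.2`.
#' @param alpha assimilation efficiency in (0, 1].
#' @param f0 assumed average feeding level in (0, 1), used only to derive the
#'   search-volume coefficient.
#' @param beta preferred predator-prey mass ratio (> 1).
#' @param sigma width of the log-normal prey-size selection (ln units).
#' @param mu0 background mortality constant, g^(1-n)/yr.
#' @param xi fraction of body weight usable as energy reserve before
#'   starvation mortality sets in (default 0.1).
#' @param erepro reproduction efficiency in (0, 1].
#' @param Rmax maximum recruitment (numbers/yr), the Beverton-Holt cap.
#' @param F fishing mortality (1/yr), knife-edge above `wmat`.
#'
#' @return a `data.frame` of class `species_params`.
#' @export
species_params <- function(name, w0, Wi, wmat,
                           m = 5, n = 0.75, p = 0.75, q = 0.8,
                           h = 20, ks = NA_real_,
                           alpha = 0.6, f0 = 0.6,
                           beta = 100, sigma = 1.5,
                           mu0 = 0.6, xi = 0.1, erepro = 0.01,
                           Rmax = 1e12, F = 0) {
  sp <- data.frame(name = as.character(name), w0 = w0, Wi = Wi, wmat = wmat,
                   m = m, n = n, p = p, q = q, h = h, ks = ks,
                   alpha = alpha, f0 = f0, beta = beta, sigma = sigma,
                   mu0 = mu0, xi = xi, erepro = erepro, Rmax = Rmax, F = F,
                   stringsAsFactors = FALSE)
  sp$ks <- ifelse(is.na(sp$ks), 0.2 * sp$alpha * sp$h, sp$ks)
  class(sp) <- c("species_params", "data.frame")
  validate_species_params(sp)
  sp
}

validate_species_params <- function(sp) {
  stopifnot(is.data.frame(sp))
  with(sp, {
    if (any(!(w0 > 0 & w0 < wmat & wmat < Wi)))
      stop("need 0 < w0 < wmat < Wi for every species")
    if (any(h <= 0 | ks <= 0 | mu0 <= 0 | Rmax <= 0))
      stop("h, ks, mu0, Rmax must be positive")
    if (any(alpha <= 0 | alpha > 1 | erepro <= 0 | erepro > 1))
      stop("alpha and erepro must lie in (0, 1]")
    if (any(f0 <= 0 | f0 >= 1))
      stop("f0 must lie strictly in (0, 1)")
    if (any(sigma <= 0)) stop("sigma must be positive")
    if (any(beta <= 1)) stop("beta must exceed 1")
    if (any(xi <= 0 | xi > 1)) stop("xi must lie in (0, 1]")
    if (any(F < 0)) stop("F must be non-negative")
  })
  invisible(sp)
}

#' Background resource parameters
#'
#' One row per resource spectrum.  Each resource regrows toward its
#' carrying-capacity spectrum `kappa * w^(-lambda)` at rate `r0 * w^(p-1)`
#' (semi-chemostat dynamics).
#'
#' @param name character label, e.g. "pelagic", "benthic".
#' @param r0 regeneration rate coefficient, g^(1-p)/yr.
#' @param kappa carrying-capacity coefficient, numbers g^(lambda-1) per unit
#'   habitat.
#' @param lambda exponent of the carrying-capacity spectrum.  Community
#'   consistency `lambda = 2 - n + q` is checked (with a warning) when the
#'   model is assembled.
#' @param w_min,w_max weight range (g) over which the resource exists.
#' @param p metabolic exponent used in the regeneration rate (default 0.75).
#' @return a `data.frame` of class `resource_params`.
#' @export
resource_params <- function(name, r0 = 4, kappa = 1e11, lambda = 2.05,
                            w_min = 1e-7, w_max = 0.1, p = 0.75) {
  rp <- data.frame(name = as.character(name), r0 = r0, kappa = kappa,
                   lambda = lambda, w_min = w_min, w_max = w_max, p = p,
                   stringsAsFactors = FALSE)
  if (any(rp$r0 <= 0 | rp$kappa <= 0)) stop("r0 and kappa must be positive")
  if (any(rp$w_min >= rp$w_max)) stop("need w_min < w_max")
  class(rp) <- c("resource_params", "data.frame")
  rp
}

#' Default three-species archetype parameterization
#'
#' Synthetic small-forage-fish / medium-forage-fish / large-piscivore
#' archetypes (sprat-, herring- and cod-like life histories).  These are NOT
#' fitted stock parameters: they are round-number life-history archetypes
#' chosen so that the three species coexist on the default resources.
#'
#' @return a `species_params` data.frame with three rows.
#' @export
default_species_params <- function() {
  rbind(
    species_params("sprat",   w0 = 1e-3, Wi = 25,    wmat = 7,
                   h = 18, beta = 3e4, sigma = 2.0, Rmax = 3e11, F = 0.3),
    species_params("herring", w0 = 1e-3, Wi = 250,   wmat = 40,
                   h = 15, beta = 3e4, sigma = 2.0, Rmax = 3e10, F = 0.25),
    species_params("cod",     w0 = 1e-3, Wi = 2e4,   wmat = 1000,
                   h = 25, beta = 300, sigma = 1.5, Rmax = 1e8,
                   erepro = 0.001, F = 0.7)
  )
}

#' Default two-resource parameterization
#'
#' A pelagic (plankton-like, small) and a benthic (invertebrate-like,
#' extending to larger weights) background spectrum.
#'
#' @return a `resource_params` data.frame with two rows.
#' @export
default_resource_params <- function() {
  rbind(
    resource_params("pelagic", r0 = 4, kappa = 1e11, lambda = 2.05,
                    w_min = 1e-7, w_max = 0.1),
    resource_params("benthic", r0 = 4, kappa = 5e9, lambda = 2.05,
                    w_min = 1e-5, w_max = 20)
  )
}

#' Default species-resource preference matrix
#'
#' Rows are species, columns resources; entries in `[0, 1]`.  The
#' species-species interaction matrix is fixed at 1 for all pairs and is not
#' configurable; only resource preferences vary between species.
#'
#' @param species a `species_params` table.
#' @param resources a `resource_params` table.
#' @return numeric matrix `length(species) x length(resources)`.
#' @export
default_theta_resource <- function(species = default_species_params(),
                                   resources = default_resource_params()) {
  th <- matrix(1, nrow(species), nrow(resources),
               dimnames = list(species$name, resources$name))
  if (all(c("sprat", "herring", "cod") %in% species$name) &&
      all(c("pelagic", "benthic") %in% resources$name)) {
    th["sprat", ]   <- c(pelagic = 1.0, benthic = 0.0)
    th["herring", ] <- c(pelagic = 0.7, benthic = 0.3)
    th["cod", ]     <- c(pelagic = 0.3, benthic = 1.0)
  }
  th
}

#' Construct the shared logarithmic weight grid
#'
#' A single log-spaced grid spans the resources' smallest weight up to the
#' largest asymptotic weight; species and resources occupy index ranges on
#' it.  `no_w` controls resolution as the number of bins across the fish
#' span (smallest egg to largest `Wi`); the resource extension below reuses
#' the same log spacing.
#'
#' @param species,resources parameter tables.
#' @param no_w number of grid points across the fish weight span
#'   (default 100).
#' @param min_w_full optional lower grid limit (g); defaults to the smaller
#'   of the resources' minimum and 4 decades below the smallest egg weight.
#' @return list of class `weight_grid` with fields `w`, `dw`, `n_w`,
#'   `fish_idx`, and per-species/resource index ranges.
#' @export
make_weight_grid <- function(species, resources, no_w = 100,
                             min_w_full = NULL) {
  w_min_fish <- min(species$w0)
  w_max <- max(species$Wi)
  if (is.null(min_w_full))
    min_w_full <- min(min(resources$w_min), w_min_fish * 1e-4)
  span_fish <- log10(w_max / w_min_fish)
  dlog <- span_fish / (no_w - 1)
  n_below <- ceiling(log10(w_min_fish / min_w_full) / dlog)
  w <- 10^(seq(log10(w_min_fish) - n_below * dlog, log10(w_max),
               by = dlog))
  n_w <- length(w)
  dw <- diff(w)
  dw <- c(dw, dw[n_w - 1] * w[n_w] / w[n_w - 1])  # geometric extrapolation
  snap <- function(x) pmin(pmax(sapply(x, function(v)
    which.min(abs(log(w) - log(v)))), 1L), n_w)
  sp_range <- cbind(start = snap(species$w0), end = snap(species$Wi))
  # resource ranges include the partially covered edge bins
  rs_range <- cbind(start = pmax(1L, findInterval(resources$w_min, w)),
                    end = pmin(n_w, findInterval(resources$w_max, w)))
  rownames(sp_range) <- species$name
  rownames(rs_range) <- resources$name
  structure(list(w = w, dw = dw, n_w = n_w,
                 fish_idx = seq(min(sp_range[, "start"]), n_w),
                 species_ranges = sp_range, resource_ranges = rs_range),
            class = "weight_grid")
}

#' Assemble a size-spectrum model object
#'
#' Combines species, resource, interaction and thermal configuration into a
#' single model object, pre-computing the weight grid, the log-normal
#' prey-selection kernels, the maturity ogive and allocation function, and
#' the search-volume coefficients.
#'
#' @param species a `species_params` table.
#' @param resources a `resource_params` table.
#' @param theta_R species x resource preference matrix with entries in
#'   `[0, 1]`; defaults to [default_theta_resource()].
#' @param thermal a [thermal_config()] object.
#' @param no_w grid resolution, see [make_weight_grid()].
#' @return object of class `spectrum_model`.
#' @export
spectrum_model <- function(species = default_species_params(),
                           resources = default_resource_params(),
                           theta_R = default_theta_resource(species, resources),
                           thermal = thermal_config(),
                           no_w = 100) {
  validate_species_params(species)
  theta_R <- as.matrix(theta_R)
  if (nrow(theta_R) != nrow(species) || ncol(theta_R) != nrow(resources))
    stop("theta_R must be species x resources")
  if (any(theta_R < 0 | theta_R > 1)) stop("theta_R entries must be in [0,1]")
  lambda_comm <- 2 - mean(species$n) + mean(species$q)
  bad <- abs(resources$lambda - lambda_comm) > 1e-8
  if (any(bad))
    warning(sprintf(
      "resource lambda (%s) differs from community value 2 - n + q = %.4g",
      paste(resources$lambda[bad], collapse = ", "), lambda_comm))

  grid <- make_weight_grid(species, resources, no_w = no_w)
  w <- grid$w; n_w <- grid$n_w
  n_sp <- nrow(species); n_rs <- nrow(resources)

  # selection kernels: phi[[i]][j, k] = preference of a predator of species i
  # at weight w[j] for prey at weight w[k] (Gaussian in ln predator/prey ratio)
  lw <- log(w)
  phi <- lapply(seq_len(n_sp), function(i) {
    z <- outer(lw, lw, "-") - log(species$beta[i])   # ln(wi/wp) - ln(beta)
    exp(-z^2 / (2 * species$sigma[i]^2))
  })

  # per-species masks and precomputed weight powers
  present <- matrix(FALSE, n_sp, n_w)
  for (i in seq_len(n_sp))
    present[i, grid$species_ranges[i, 1]:grid$species_ranges[i, 2]] <- TRUE
  psi <- ogive <- matrix(0, n_sp, n_w,
                         dimnames = list(species$name, NULL))
  for (i in seq_len(n_sp)) {
    og <- maturity_ogive(w, species$wmat[i], species$m[i])
    ogive[i, ] <- og
    psi[i, ] <- maturity_allocation(w, species[i, ])
  }

  # gamma is derived against the resource spectrum each species actually
  # feeds on: the preference-weighted sum of carrying-capacity coefficients
  gamma <- vapply(seq_len(n_sp), function(i)
    search_volume_coefficient(species$f0[i], species$h[i], species$beta[i],
                              species$sigma[i], lambda_comm,
                              sum(theta_R[i, ] * resources$kappa)),
    numeric(1))

  # resource carrying capacities on the grid; edge bins carry the fraction
  # of their log-width inside [w_min, w_max] so that total capacity does
  # not jump with grid resolution as the exact cutoffs move between bins
  cc <- matrix(0, n_rs, n_w, dimnames = list(resources$name, NULL))
  lw_edges <- c(log(w), log(w[n_w]) + log(w[n_w] / w[n_w - 1]))
  for (r in seq_len(n_rs)) {
    lo <- log(resources$w_min[r]); hi <- log(resources$w_max[r])
    frac <- pmax(0, pmin(hi, lw_edges[-1]) - pmax(lo, lw_edges[-(n_w + 1)])) /
      diff(lw_edges)
    cc[r, ] <- frac * resources$kappa[r] * w^(-resources$lambda[r])
  }

  # knife-edge fishing selectivity as per-bin overlap fractions with
  # [wmat, Inf): the finite-volume discretization of the indicator, so the
  # fished biomass does not jump as wmat moves between grid points
  fsel <- matrix(0, n_sp, n_w, dimnames = list(species$name, NULL))
  lw_e <- c(lw, lw[n_w] + (lw[n_w] - lw[n_w - 1]))
  for (i in seq_len(n_sp)) {
    fsel[i, ] <- pmax(0, pmin(lw_e[-1] - pmax(log(species$wmat[i]),
                                              lw_e[-(n_w + 1)]),
                              diff(lw_e))) / diff(lw_e)
  }

  # precomputed allometric weight powers (hot loop)
  wq <- t(vapply(species$q, function(e) w^e, numeric(n_w)))
  wn <- t(vapply(species$n, function(e) w^e, numeric(n_w)))
  wp <- t(vapply(species$p, function(e) w^e, numeric(n_w)))

  structure(list(species = species, resources = resources,
                 theta_R = theta_R, thermal = thermal, grid = grid,
                 lambda = lambda_comm, phi = phi, present = present,
                 psi = psi, ogive = ogive, gamma = gamma, cc = cc,
                 fsel = fsel, wq = wq, wn = wn, wp = wp),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat("Multi-species size-spectrum model\n")
  cat(sprintf("  %d species: %s\n", nrow(x$species),
              paste(x$species$name, collapse = ", ")))
  cat(sprintf("  %d resources: %s\n", nrow(x$resources),
              paste(x$resources$name, collapse = ", ")))
  cat(sprintf("  grid: %d bins, %.3g - %.3g g\n", x$grid$n_w,
              min(x$grid$w), max(x$grid$w)))
  cat(sprintf("  thermal scenario: %s (Tref = %.2f K)\n",
              x$thermal$scenario, x$thermal$Tref))
  invisible(x)
}

#' Initial model state
#'
#' Builds a starting state: resources at carrying capacity and fish on a
#' crude power-law guess that the solver relaxes toward steady state.
#'
#' @param model a `spectrum_model`.
#' @param temperature initial temperature (K), default the reference.
#' @return list of class `model_state` with fields `N` (species x weight
#'   number densities), `NR` (resource x weight), `t` (yr) and `T` (K).
#' @export
initial_state <- function(model, temperature = model$thermal$Tref) {
  g <- model$grid; w <- g$w
  n_sp <- nrow(model$species)
  N <- matrix(0, n_sp, g$n_w, dimnames = list(model$species$name, NULL))
  for (i in seq_len(n_sp)) {
    rng <- g$species_ranges[i, 1]:g$species_ranges[i, 2]
    # slope -lambda guess, scaled to a small fraction of resource abundance
    N[i, rng] <- 1e-4 * sum(model$resources$kappa) *
      w[rng]^(-model$lambda) * (1 - (w[rng] / model$species$Wi[i]))^2
    N[i, rng] <- pmax(N[i, rng], 0)
  }
  structure(list(N = N, NR = model$cc, t = 0, T = temperature),
            class = "model_state")
}
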