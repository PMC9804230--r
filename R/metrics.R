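#' Spawning stock biomass
#'
#' Biomass of mature individuals: number density weighted by the smooth
#' maturity ogive and body weight, integrated over the grid.
#'
#' @param state a `model_state`.
#' @param model a `spectrum_model`.
#' @param i species index or name; all species when omitted.
#' @return SSB (g per unit habitat), one value per requested species.
#' @export
ssb <- function(state, model, i = NULL) {
  g <- model$grid
  wdw <- g$w * g$dw
  out <- as.numeric((model$ogive * state$N) %*% wdw)
  names(out) <- model$species$name
  if (is.null(i)) out else out[i]
}

#' Instantaneous fisheries yield
#'
#' Knife-edge catch rate: `F` times the biomass at and above the
#' maturation weight.
#'
#' @inheritParams ssb
#' @return yield rate (g/yr per unit habitat) per requested species.
#' @export
yield <- function(state, model, i = NULL) {
  g <- model$grid
  sp <- model$species
  out <- vapply(seq_len(nrow(sp)), function(s) {
    sp$F[s] * sum(model$fsel[s, ] * state$N[s, ] * g$w * g$dw)
  }, numeric(1))
  names(out) <- sp$name
  if (is.null(i)) out else out[i]
}

#' Mean individual weight in a population
#'
#' Biomass divided by abundance over the species' weight range.
#'
#' @inheritParams ssb
#' @return mean weight (g) per requested species.
#' @export
mean_weight <- function(state, model, i = NULL) {
  g <- model$grid
  out <- vapply(seq_len(nrow(model$species)), function(s) {
    num <- sum(state$N[s, ] * g$w * g$dw)
    den <- sum(state$N[s, ] * g$dw)
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  names(out) <- model$species$name
  if (is.null(i)) out else out[i]
}

#' Weight-at-age along a cohort
#'
#' Integrates `dw/da = g(w)` through the (frozen) growth field of the
#' supplied state, i.e. the quasi-steady growth conditions a cohort would
#' experience if the state persisted.  Growth is interpolated log-linearly
#' in weight and integrated with a fixed-step 4th-order Runge-Kutta scheme.
#'
#' @param model a `spectrum_model`.
#' @param state a `model_state` defining the growth field.
#' @param i species index or name.
#' @param ages ages (yr) at which to report weight.
#' @param tf thermal factors in force (identity if omitted).
#' @param da integration step (yr), default 0.02.
#' @return named numeric vector of weights (g) at `ages`.
#' @export
size_at_age <- function(model, state, i, ages = 0:10, tf = NULL,
                        da = 0.02) {
  if (is.character(i)) i <- match(i, model$species$name)
  rates <- compute_rates(model, state, tf)
  gfun <- growth_interpolator(model, rates, i)
  w <- model$species$w0[i]
  amax <- max(ages)
  n_steps <- ceiling(amax / da)
  da <- if (n_steps > 0) amax / n_steps else da
  out <- numeric(length(ages))
  out[ages == 0] <- w
  a <- 0
  for (s in seq_len(n_steps)) {
    k1 <- gfun(w)
    k2 <- gfun(w + da / 2 * k1)
    k3 <- gfun(w + da / 2 * k2)
    k4 <- gfun(w + da * k3)
    w <- w + da / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    a <- a + da
    hit <- abs(ages - a) < da / 2 & ages > 0
    out[hit] <- w
  }
  names(out) <- ages
  out
}

# log-weight linear interpolator of the growth rate, clamped to the
# species range
growth_interpolator <- function(model, rates, i) {
  g <- model$grid
  rng <- g$species_ranges[i, 1]:g$species_ranges[i, 2]
  lw <- log(g$w[rng]); gv <- rates$g[i, rng]
  function(w) {
    x <- log(max(min(w, exp(lw[length(lw)])), exp(lw[1])))
    stats::approx(lw, gv, xout = x, rule = 2)$y
  }
}

#' Ratios of a warming output to a baseline
#'
#' Element-wise ratio of matching numeric summaries; coordinates where the
#' baseline is zero are masked as `NA` rather than returned as infinities.
#'
#' @param x,baseline numeric vectors/matrices/arrays of identical shape.
#' @return ratio array of the same shape.
#' @export
relative_metrics <- function(x, baseline) {
  if (!identical(dim(x), dim(baseline)) || length(x) != length(baseline))
    stop("x and baseline must have identical shape")
  out <- x / baseline
  out[baseline == 0] <- NA_real_
  out
}

#' Ensemble quantile bands
#'
#' Per-coordinate quantiles across a list of equally shaped numeric arrays
#' (one per ensemble draw).
#'
#' @param draws list of numeric vectors/matrices of identical shape.
#' @param probs quantile probabilities (default the 2.5 and 97.5
#'   percentiles).
#' @return list of arrays, one per probability.
#' @export
ensemble_quantiles <- function(draws, probs = c(0.025, 0.975)) {
  arr <- simplify2array(draws)
  nd <- length(dim(arr))
  out <- lapply(probs, function(p) {
    q <- apply(arr, seq_len(nd - 1), stats::quantile, probs = p,
               na.rm = TRUE)
    if (!is.null(dim(draws[[1]]))) dim(q) <- dim(draws[[1]])
    q
  })
  names(out) <- paste0("q", probs * 100)
  out
}

#' Slopes of FMSY and maximum yield against temperature
#'
#' Ordinary least-squares slopes, per species, of the per-temperature FMSY
#' and the corresponding maximum yield against the temperature proportion.
#'
#' @param surface data.frame with columns `species`, `T_prop`, `fmsy`,
#'   `msy` (one row per species x temperature).
#' @return data.frame with columns `species`, `slope_fmsy`, `slope_yield`.
#' @export
fmsy_yield_slopes <- function(surface) {
  sp <- unique(surface$species)
  out <- data.frame(species = sp, slope_fmsy = NA_real_,
                    slope_yield = NA_real_)
  for (k in seq_along(sp)) {
    d <- surface[surface$species == sp[k], ]
    out$slope_fmsy[k] <- stats::coef(stats::lm(fmsy ~ T_prop, data = d))[2]
    out$slope_yield[k] <- stats::coef(stats::lm(msy ~ T_prop, data = d))[2]
  }
  out
}
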