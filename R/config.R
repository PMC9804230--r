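#' Read a model configuration file
#'
#' JSON schema: objects `species` (array of rows with the
#' [species_params()] fields), `resources` ([resource_params()] fields),
#' `theta_R` (species x resource matrix), `thermal` ([thermal_config()]
#' fields, activation energies as `[mean, sd]`), optional `solver`
#' ([solver_config()] fields) and `no_w`.  Units as in the constructors.
#'
#' @param path path to a JSON configuration file.
#' @return list with elements `model` (a `spectrum_model`) and `solver`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  sp <- do.call(rbind, lapply(seq_len(nrow(cfg$species)), function(k)
    do.call(species_params, as.list(cfg$species[k, ]))))
  rs <- do.call(rbind, lapply(seq_len(nrow(cfg$resources)), function(k)
    do.call(resource_params, as.list(cfg$resources[k, ]))))
  th_args <- cfg$thermal
  thermal <- if (is.null(th_args)) thermal_config()
             else do.call(thermal_config, lapply(th_args, unlist))
  theta <- if (is.null(cfg$theta_R)) default_theta_resource(sp, rs)
           else if (is.matrix(cfg$theta_R)) cfg$theta_R
           else do.call(rbind, cfg$theta_R)
  dimnames(theta) <- list(sp$name, rs$name)
  no_w <- if (is.null(cfg$no_w)) 100 else cfg$no_w
  solver <- if (is.null(cfg$solver)) solver_config()
            else do.call(solver_config, as.list(cfg$solver))
  list(model = spectrum_model(sp, rs, theta, thermal, no_w = no_w),
       solver = solver)
}

#' Write a model configuration file
#'
#' Inverse of [read_model_config()]: serializes a model (and optionally a
#' solver configuration) to JSON.
#'
#' @param model a `spectrum_model`.
#' @param path output path.
#' @param solver optional [solver_config()].
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path, solver = NULL) {
  th <- model$thermal
  cfg <- list(
    species = as.data.frame(model$species),
    resources = as.data.frame(model$resources),
    theta_R = unname(apply(model$theta_R, 1, as.numeric, simplify = FALSE)),
    thermal = list(Tref = th$Tref, k_B = th$k_B, scenario = th$scenario,
                   E_met = th$E_met, E_cons = th$E_cons,
                   E_search = th$E_search, E_mort = th$E_mort,
                   E_r0 = th$E_r0, E_kappa = th$E_kappa),
    no_w = length(model$grid$fish_idx))
  if (!is.null(solver)) cfg$solver <- unclass(solver)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a simulation summary as CSV
#'
#' Long-format annual summaries (`year, species, ssb, yield, R_phy, R`).
#'
#' @param output a `sim_output` from [project()].
#' @param path output path.
#' @return the summary data.frame, invisibly.
#' @export
write_sim_summary <- function(output, path) {
  n_sp <- ncol(output$ssb)
  d <- data.frame(
    year = rep(output$years, n_sp),
    species = rep(colnames(output$ssb), each = length(output$years)),
    ssb = as.numeric(output$ssb), yield = as.numeric(output$yield),
    R_phy = as.numeric(output$R_phy), R = as.numeric(output$R))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}

#' Write spectra as a long-format CSV
#'
#' @param state a `model_state`.
#' @param model a `spectrum_model`.
#' @param path output path.
#' @return the data.frame, invisibly.
#' @export
write_spectra <- function(state, model, path) {
  g <- model$grid
  d <- rbind(
    data.frame(group = rep(model$species$name, each = g$n_w),
               w = rep(g$w, nrow(model$species)),
               density = as.numeric(t(state$N))),
    data.frame(group = rep(model$resources$name, each = g$n_w),
               w = rep(g$w, nrow(model$resources)),
               density = as.numeric(t(state$NR))))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
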