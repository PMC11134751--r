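#' Molar masses used for concentration bookkeeping (g/mol)
#' @keywords internal
MOLAR_MASS <- c(glucose = 180.16, xylose = 150.13, citrate = 192.12)

#' Kinetic parameters for dynamic FBA
#'
#' Uptake kinetics and switching rules for a glucose-xylose fermentation:
#' high-affinity Michaelis-Menten glucose transport always active, a
#' low-affinity system that switches on above `glc_low_affinity_threshold`
#' (75 g/L), transporter-mediated xylose uptake repressed whenever external
#' glucose exceeds `xyl_repression_threshold` (5 mM) leaving only passive
#' (linear-in-concentration) xylose entry, a non-growth-associated ATP
#' maintenance flux, a phosphate uptake cap, and the simulation start offset
#' after inoculation. All rates are mmol gDW^-1 h^-1. The default Vmax/Km
#' values are configuration placeholders at physiologically plausible
#' magnitudes; supply measured values where available.
#'
#' @param vmax_glc_high,km_glc_high high-affinity glucose uptake Vmax and Km
#'   (Km in g/L).
#' @param vmax_glc_low,km_glc_low low-affinity glucose system.
#' @param glc_low_affinity_threshold glucose level (g/L) above which the
#'   low-affinity system is active.
#' @param vmax_xyl,km_xyl transporter-mediated xylose uptake.
#' @param xyl_repression_threshold glucose level (mM) above which
#'   transporter-mediated xylose uptake is disabled.
#' @param k_passive_xyl passive xylose uptake constant,
#'   mmol gDW^-1 h^-1 per g/L.
#' @param ngam non-growth-associated maintenance, mmol ATP gDW^-1 h^-1.
#' @param vmax_pi phosphate uptake cap, mmol gDW^-1 h^-1.
#' @param t_start simulation start time after inoculation, h (lag phase).
#' @return A `kinetic_parameters` list.
#' @export
kinetic_parameters <- function(vmax_glc_high = 1.0, km_glc_high = 0.5,
                               vmax_glc_low = 1.5, km_glc_low = 20,
                               glc_low_affinity_threshold = 75,
                               vmax_xyl = 0.8, km_xyl = 2.0,
                               xyl_repression_threshold = 5,
                               k_passive_xyl = 0.005,
                               ngam = 1.9, vmax_pi = 0.1, t_start = 10) {
  p <- list(vmax_glc_high = vmax_glc_high, km_glc_high = km_glc_high,
            vmax_glc_low = vmax_glc_low, km_glc_low = km_glc_low,
            glc_low_affinity_threshold = glc_low_affinity_threshold,
            vmax_xyl = vmax_xyl, km_xyl = km_xyl,
            xyl_repression_threshold = xyl_repression_threshold,
            k_passive_xyl = k_passive_xyl, ngam = ngam,
            vmax_pi = vmax_pi, t_start = t_start)
  if (any(unlist(p) < 0))
    stop("kinetic parameters must be non-negative", call. = FALSE)
  if (glc_low_affinity_threshold <= 0 || xyl_repression_threshold <= 0)
    stop("switching thresholds must be positive", call. = FALSE)
  structure(p, class = "kinetic_parameters")
}

#' Glucose uptake bound from external concentration
#'
#' High-affinity Michaelis-Menten term always; the low-affinity term is
#' added only above the activation threshold (default 75 g/L).
#'
#' @param glucose external glucose, g/L.
#' @param p a [kinetic_parameters()] object.
#' @return Total allowed uptake, mmol gDW^-1 h^-1.
#' @export
glucose_uptake_bound <- function(glucose, p) {
  stopifnot(glucose >= 0)
  v <- p$vmax_glc_high * glucose / (p$km_glc_high + glucose)
  if (glucose > p$glc_low_affinity_threshold)
    v <- v + p$vmax_glc_low * glucose / (p$km_glc_low + glucose)
  v
}

#' Xylose uptake bound under glucose repression
#'
#' Passive entry (`k_passive_xyl * xylose`) is always available; the
#' transporter-mediated Michaelis-Menten term is added only when external
#' glucose is at or below the repression threshold (default 5 mM).
#'
#' @param xylose external xylose, g/L.
#' @param glucose_mM external glucose, mM.
#' @param p a [kinetic_parameters()] object.
#' @return Total allowed uptake, mmol gDW^-1 h^-1.
#' @export
xylose_uptake_bound <- function(xylose, glucose_mM, p) {
  sum(unlist(xylose_uptake_terms(xylose, glucose_mM, p)))
}

## passive and transporter-mediated components, kept separate for the
## sequential-use diagnostics
xylose_uptake_terms <- function(xylose, glucose_mM, p) {
  stopifnot(xylose >= 0, glucose_mM >= 0)
  transporter <- if (glucose_mM <= p$xyl_repression_threshold)
    p$vmax_xyl * xylose / (p$km_xyl + xylose) else 0
  list(passive = p$k_passive_xyl * xylose, transporter = transporter)
}

#' Construct a fermentation state
#'
#' @param t time, h. @param biomass gDW/L. @param glucose,xylose,citrate
#'   g/L. @param phosphate mM. @param co2_mmol cumulative CO2 vented,
#'   mmol/L (bookkeeping for the carbon balance).
#' @return A `fermentation_state` (one-row tibble).
#' @export
fermentation_state <- function(t = 10, biomass = 0.5, glucose = 80,
                               xylose = 40, citrate = 0, phosphate = 1,
                               co2_mmol = 0) {
  vals <- c(biomass, glucose, xylose, citrate, phosphate)
  if (any(vals < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(tibble::tibble(t = t, biomass = biomass, glucose = glucose,
                           xylose = xylose, citrate = citrate,
                           phosphate = phosphate, co2_mmol = co2_mmol),
            class = c("fermentation_state", class(tibble::tibble())))
}

#' Default mapping from fermentation roles to toy-model reaction ids
#' @export
default_dfba_roles <- function() {
  c(glucose = "EX_glc__D_e", xylose = "EX_xyl__D_e", phosphate = "EX_pi_e",
    citrate = "EX_cit_e", co2 = "EX_co2_e", atpm = "ATPM")
}

#' Apply kinetic uptake bounds for one dFBA step
#'
#' Sets the glucose and xylose exchange lower bounds to minus the kinetic
#' uptake bounds, caps phosphate uptake at `vmax_pi` while extracellular
#' phosphate remains and closes it otherwise, pins the ATP maintenance
#' reaction's lower bound at `ngam`, and opens citrate secretion. The input
#' model is unchanged.
#'
#' @param model a `metabolic_model`.
#' @param state a [fermentation_state()].
#' @param p a [kinetic_parameters()] object.
#' @param roles named character vector mapping roles `glucose`, `xylose`,
#'   `phosphate`, `citrate`, `co2`, `atpm` to reaction ids.
#' @return The bounded model copy.
#' @export
apply_kinetic_bounds <- function(model, state, p,
                                 roles = default_dfba_roles()) {
  need <- c("glucose", "xylose", "phosphate", "citrate", "atpm")
  missing_roles <- need[!roles[need] %in% model$reactions$id]
  if (length(missing_roles))
    stop("model lacks reactions for role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  glc_mM <- state$glucose / MOLAR_MASS[["glucose"]] * 1000
  model <- set_bounds(model, roles[["glucose"]],
                      lower_bound = -glucose_uptake_bound(state$glucose, p))
  model <- set_bounds(model, roles[["xylose"]],
                      lower_bound = -xylose_uptake_bound(state$xylose, glc_mM, p))
  model <- set_bounds(model, roles[["phosphate"]],
                      lower_bound = if (state$phosphate > 0) -p$vmax_pi else 0)
  model <- set_bounds(model, roles[["citrate"]], lower_bound = 0,
                      upper_bound = 1000)
  set_bounds(model, roles[["atpm"]], lower_bound = p$ngam)
}

#' Advance a fermentation state by one dFBA step
#'
#' Static-optimisation dFBA: apply kinetic bounds, solve the FBA LP under
#' the objective policy, then forward-Euler update biomass
#' (`X * (1 + mu dt)`), sugar and citrate concentrations (g/L, via molar
#' mass) and phosphate (mM). Concentrations are clamped at zero and the
#' clamp recorded. Under the `"growth_then_citrate"` policy the objective
#' switches to maximal citrate secretion once optimal growth falls below
#' `1e-4` per hour (e.g. after phosphate exhaustion).
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param state a [fermentation_state()].
#' @param p a [kinetic_parameters()] object.
#' @param dt step size, h.
#' @param objective_policy `"growth_then_citrate"` or `"growth"`.
#' @param roles see [apply_kinetic_bounds()].
#' @return The next `fermentation_state`, with attributes `diagnostics`
#'   (tibble of solver status, phase, uptake bounds, clamps).
#' @export
dfba_step <- function(model, state, p, dt = 0.1,
                      objective_policy = c("growth_then_citrate", "growth"),
                      roles = default_dfba_roles()) {
  stopifnot(dt > 0)
  objective_policy <- match.arg(objective_policy)
  glc_mM <- state$glucose / MOLAR_MASS[["glucose"]] * 1000
  xt <- xylose_uptake_terms(state$xylose, glc_mM, p)
  m <- apply_kinetic_bounds(model, state, p, roles)
  sol <- fba(m)
  phase <- "growth"
  if (sol$status != "optimal")
    stop("dFBA step at t = ", state$t, " h: LP ", sol$status, call. = FALSE)
  mu <- sol$objective_value
  if (objective_policy == "growth_then_citrate" && mu < 1e-4) {
    sol2 <- fba(m, objective = roles[["citrate"]])
    if (sol2$status == "optimal") {
      phase <- "citrate"
      sol <- sol2
      mu <- sol$fluxes$flux[match(model$objective, sol$fluxes$reaction)]
    }
  }
  fx <- stats::setNames(sol$fluxes$flux, sol$fluxes$reaction)
  v_glc <- -fx[[roles[["glucose"]]]]
  v_xyl <- -fx[[roles[["xylose"]]]]
  v_pi <- -fx[[roles[["phosphate"]]]]
  v_cit <- fx[[roles[["citrate"]]]]
  v_co2 <- if (roles[["co2"]] %in% names(fx)) fx[[roles[["co2"]]]] else 0
  X <- state$biomass

  raw <- c(glucose = state$glucose - v_glc * X * dt * MOLAR_MASS[["glucose"]] / 1000,
           xylose = state$xylose - v_xyl * X * dt * MOLAR_MASS[["xylose"]] / 1000,
           citrate = state$citrate + v_cit * X * dt * MOLAR_MASS[["citrate"]] / 1000,
           phosphate = state$phosphate - v_pi * X * dt)
  clamped <- names(raw)[raw < 0]
  raw[raw < 0] <- 0
  out <- fermentation_state(t = state$t + dt,
                            biomass = X * (1 + mu * dt),
                            glucose = raw[["glucose"]],
                            xylose = raw[["xylose"]],
                            citrate = raw[["citrate"]],
                            phosphate = raw[["phosphate"]],
                            co2_mmol = state$co2_mmol + v_co2 * X * dt)
  attr(out, "diagnostics") <- tibble::tibble(
    t = state$t, status = sol$status, phase = phase, mu = mu,
    glc_uptake_bound = glucose_uptake_bound(state$glucose, p),
    xyl_passive_bound = xt$passive,
    xyl_transporter_bound = xt$transporter,
    glucose_mM = glc_mM,
    clamped = paste(clamped, collapse = ","))
  out
}

#' Run a dynamic FBA fermentation simulation
#'
#' Repeats [dfba_step()] from `p$t_start` (the lag-phase offset after
#' inoculation) to `t_end`. An infeasible step (e.g. maintenance no longer
#' satisfiable after substrate exhaustion) terminates the run cleanly: the
#' trajectory is truncated at the last feasible state and the reason
#' recorded, never silently zeroed.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param p a [kinetic_parameters()] object.
#' @param initial a [fermentation_state()] at `t = p$t_start`.
#' @param t_end end time, h.
#' @param dt Euler step, h.
#' @param objective_policy,roles see [dfba_step()].
#' @param include_lag prepend constant pre-`t_start` states (for plotting
#'   from inoculation).
#' @return A `dfba_trajectory` tibble (columns of the state plus `mu` and
#'   `phase`), with attributes `diagnostics` (per-step tibble) and
#'   `termination` (`"t_end"` or the infeasibility message).
#' @export
run_dfba <- function(model, p, initial = fermentation_state(t = p$t_start),
                     t_end = 72, dt = 0.1,
                     objective_policy = c("growth_then_citrate", "growth"),
                     roles = default_dfba_roles(), include_lag = FALSE) {
  objective_policy <- match.arg(objective_policy)
  stopifnot(t_end > p$t_start)
  if (abs(initial$t - p$t_start) > 1e-9)
    stop("initial state must sit at t_start = ", p$t_start, " h", call. = FALSE)
  n_steps <- ceiling((t_end - initial$t) / dt - 1e-9)
  states <- vector("list", n_steps + 1L)
  diags <- vector("list", n_steps)
  states[[1L]] <- initial
  termination <- "t_end"
  state <- initial
  for (i in seq_len(n_steps)) {
    step_dt <- min(dt, t_end - state$t)
    nxt <- tryCatch(
      dfba_step(model, state, p, step_dt, objective_policy, roles),
      error = function(e) e)
    if (inherits(nxt, "error")) {
      termination <- conditionMessage(nxt)
      states <- states[seq_len(i)]
      diags <- diags[seq_len(i - 1L)]
      break
    }
    diags[[i]] <- attr(nxt, "diagnostics")
    attr(nxt, "diagnostics") <- NULL
    states[[i + 1L]] <- nxt
    state <- nxt
  }
  traj <- dplyr::bind_rows(states)
  diagnostics <- dplyr::bind_rows(diags)
  traj$mu <- c(if (nrow(diagnostics)) diagnostics$mu else numeric(), NA)[
    seq_len(nrow(traj))]
  traj$phase <- c(if (nrow(diagnostics)) diagnostics$phase else character(),
                  NA)[seq_len(nrow(traj))]
  if (include_lag && p$t_start > 0) {
    lag_t <- seq(0, p$t_start, by = dt)
    lag_t <- lag_t[lag_t < p$t_start - 1e-9]
    lag <- initial[rep(1L, length(lag_t)), ]
    lag$t <- lag_t
    lag$mu <- 0; lag$phase <- "lag"
    traj <- dplyr::bind_rows(lag, traj)
  }
  structure(traj, class = c("dfba_trajectory", class(tibble::tibble())),
            diagnostics = diagnostics, termination = termination,
            parameters = p, dt = dt)
}

#' Per-step carbon recovery of a dFBA trajectory
#'
#' Cumulative carbon bookkeeping from the start of the run: the fraction of
#' carbon taken up from the sugars that is recovered in new biomass, secreted
#' citrate and vented CO2. In an elementally balanced model recovery stays
#' at 1 up to Euler integration error. Steps with no cumulative consumption
#' yet report `NA`.
#'
#' @param trajectory a `dfba_trajectory`.
#' @param model the model the run used (for the biomass carbon content).
#' @param biomass_carbon mmol carbon per gDW; computed from the model's
#'   biomass reaction and metabolite formulas when omitted.
#' @return Tibble with `t`, `carbon_consumed`, `carbon_recovered` (both
#'   mmol C/L, cumulative) and `recovery`.
#' @export
carbon_balance <- function(trajectory, model = NULL, biomass_carbon = NULL) {
  if (is.null(biomass_carbon)) {
    if (is.null(model))
      stop("either model or biomass_carbon is required", call. = FALSE)
    biomass_carbon <- biomass_carbon_content(model)
  }
  t0 <- trajectory[1L, ]
  dC_sugar <- (t0$glucose - trajectory$glucose) / MOLAR_MASS[["glucose"]] * 1000 * 6 +
    (t0$xylose - trajectory$xylose) / MOLAR_MASS[["xylose"]] * 1000 * 5
  dC_out <- (trajectory$biomass - t0$biomass) * biomass_carbon +
    (trajectory$citrate - t0$citrate) / MOLAR_MASS[["citrate"]] * 1000 * 6 +
    (trajectory$co2_mmol - t0$co2_mmol)
  tibble::tibble(t = trajectory$t,
                 carbon_consumed = dC_sugar,
                 carbon_recovered = dC_out,
                 recovery = ifelse(dC_sugar > 1e-9, dC_out / dC_sugar, NA_real_))
}

#' Net carbon fixed per gDW by the biomass reaction
#'
#' @param model a `metabolic_model` whose objective is the biomass reaction
#'   and whose metabolites carry formulas.
#' @return mmol C per gDW.
#' @export
biomass_carbon_content <- function(model) {
  sto <- model$stoichiometry[model$stoichiometry$reaction_id == model$objective, ]
  carbons <- vapply(sto$metabolite_id, function(mid) {
    f <- parse_formula(model$metabolites$formula[match(mid, model$metabolites$id)])
    if (is.null(f) || !"C" %in% names(f)) 0 else f[["C"]]
  }, numeric(1))
  -sum(sto$coefficient * carbons)
}

#' Estimate the high-affinity glucose uptake Vmax from trajectory data
#'
#' Least-squares fit of `vmax_glc_high` to observed glucose concentrations:
#' the dFBA simulation is rerun for candidate values and the sum of squared
#' deviations at the observed time points (linear interpolation between
#' steps) minimised with one-dimensional search.
#'
#' @param observed tibble with columns `t` and `glucose` (replicate rows
#'   allowed).
#' @param model,p,initial,t_end,dt,roles simulation setup; `p` supplies all
#'   parameters except the fitted one.
#' @param interval search interval for `vmax_glc_high`.
#' @return List with `vmax_glc_high` (estimate) and `sse`.
#' @export
fit_glucose_vmax <- function(observed, model, p,
                             initial = fermentation_state(t = p$t_start),
                             t_end = max(observed$t), dt = 0.5,
                             roles = default_dfba_roles(),
                             interval = c(0.2, 4) * p$vmax_glc_high) {
  sse <- function(vmax) {
    pp <- p
    pp$vmax_glc_high <- vmax
    traj <- run_dfba(model, pp, initial, t_end = t_end, dt = dt,
                     roles = roles)
    pred <- stats::approx(traj$t, traj$glucose, xout = observed$t,
                          rule = 2)$y
    sum((pred - observed$glucose)^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-3)
  list(vmax_glc_high = opt$minimum, sse = opt$objective)
}

#' Plot a dFBA trajectory
#'
#' @param object a `dfba_trajectory`.
#' @param measured optional tibble of measured points (columns `t` plus any
#'   of `biomass`, `glucose`, `xylose`, `citrate`, `phosphate`) overlaid as
#'   dots.
#' @param ... unused.
#' @return A ggplot: one facet per tracked species.
#' @export
autoplot.dfba_trajectory <- function(object, measured = NULL, ...) {
  vars <- c("biomass", "glucose", "xylose", "citrate", "phosphate")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", vars)],
    dplyr::all_of(vars), names_to = "species", values_to = "value")
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time (h)",
                  y = "concentration (g/L; phosphate mM; biomass gDW/L)")
  if (!is.null(measured)) {
    mlong <- tidyr::pivot_longer(
      measured[, intersect(c("t", vars), names(measured))],
      dplyr::any_of(vars), names_to = "species", values_to = "value")
    gg <- gg + ggplot2::geom_point(data = mlong, alpha = 0.6)
  }
  gg
}
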