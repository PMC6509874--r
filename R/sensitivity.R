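#' Screening configuration
#'
#' Collects every tunable of the screening pipeline in one object.
#'
#' @param a Sensitivity threshold on the relative perturbation
#'   \eqn{\Delta E_i / E_{di}}; targets at or below `a` are sensitive
#'   (default 1: the perturbation may not exceed the initial concentration).
#' @param theta Normal-state fraction: the cumulative readout output must fall
#'   below `theta` times the disease-state output (default 0.10).
#' @param alpha Dose-reduction factor for the mixed (sensitive + insensitive)
#'   screen, \eqn{0 < \alpha < 1} (default 0.8: the sensitive target's dose is
#'   cut by 20% and the insensitive partner must cover the remainder).
#' @param dose_grid_step Fractional-dose grid step for isobolograms
#'   (default 0.1, i.e. fractions 0.1, 0.2, ..., 0.9 of the single dose).
#' @param effect_tolerance Relative tolerance for "just below" the
#'   normal-state threshold in all bisection searches (default 1e-3).
#' @param max_fold_increase Upper bound, as a fold change of the initial
#'   concentration, for increase-direction dose searches (default 1e18).
#' @param rtol,atol Integrator tolerances (defaults 1e-8, 1e-12).
#' @param n_save Number of evenly spaced saved time points (default 201).
#' @param readout_mode `"flux"` (cumulative production, default) or
#'   `"level"` (final readout concentration); see [cumulative_output()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(a = 1, theta = 0.10, alpha = 0.8,
                          dose_grid_step = 0.1, effect_tolerance = 1e-3,
                          max_fold_increase = 1e18,
                          rtol = 1e-8, atol = 1e-12, n_save = 201,
                          readout_mode = c("flux", "level")) {
  readout_mode <- match.arg(readout_mode)
  stopifnot(a > 0, theta > 0, theta < 1, alpha > 0, alpha < 1,
            dose_grid_step > 0, dose_grid_step < 1,
            effect_tolerance > 0, max_fold_increase > 1,
            rtol > 0, atol > 0, n_save >= 2)
  structure(list(
    a = a, theta = theta, alpha = alpha, dose_grid_step = dose_grid_step,
    effect_tolerance = effect_tolerance, max_fold_increase = max_fold_increase,
    rtol = rtol, atol = atol, n_save = as.integer(n_save),
    readout_mode = readout_mode
  ), class = "screen_config")
}

#' Normal-state criterion
#'
#' The normal (desired) state is reached when the cumulative readout output
#' over the horizon falls below `theta` times the disease-state output, i.e.
#' below 10% of baseline at the default `theta = 0.10`.
#'
#' @param disease_output Cumulative readout output of the unperturbed
#'   (disease) model; must be positive.
#' @param theta Normal-state fraction in (0, 1).
#' @return A list of class `state_criterion` with elements `disease_output`,
#'   `theta` and the derived `threshold = theta * disease_output`.
#' @seealso [disease_criterion()] to compute the baseline from a model.
#' @export
state_criterion <- function(disease_output, theta = 0.10) {
  stopifnot(is.finite(disease_output), disease_output > 0,
            theta > 0, theta < 1)
  structure(list(disease_output = disease_output, theta = theta,
                 threshold = theta * disease_output),
            class = "state_criterion")
}

#' Compute the disease baseline and normal-state criterion for a model
#'
#' Simulates the unperturbed model and wraps its cumulative readout output in
#' a [state_criterion()].
#'
#' @param model A valid [network_model()].
#' @param theta Normal-state fraction.
#' @param config A [screen_config()].
#' @return A `state_criterion`.
#' @export
disease_criterion <- function(model, theta = 0.10, config = screen_config()) {
  base <- cumulative_output(simulate_network(model, NULL, config))
  if (base <= 0) {
    abort("unperturbed model has zero cumulative readout output; no disease state to restore from",
          class = "synergyscreen_validation_error")
  }
  state_criterion(base, theta)
}

# cumulative output with the given perturbations
perturbed_effect <- function(model, perturbations, config) {
  cumulative_output(simulate_network(model, perturbations, config))
}

#' Is the network in the normal state under a perturbation?
#'
#' @param model A valid [network_model()].
#' @param perturbations `NULL` or a data frame of [perturbation()] rows.
#' @param criterion A [state_criterion()] computed from the same model and
#'   readout settings.
#' @param config A [screen_config()].
#' @return `TRUE` iff the cumulative readout output under `perturbations` is
#'   strictly below `theta * disease_output`.
#' @export
is_normal <- function(model, perturbations, criterion,
                      config = screen_config()) {
  stopifnot(inherits(criterion, "state_criterion"))
  perturbed_effect(model, perturbations, config) < criterion$threshold
}

# Bisection between a feasible concentration (effect < thr) and an infeasible
# one, tightening until the feasible effect is within rel. tol below thr.
bisect_between <- function(effect_fn, e_feas, f_feas, e_infeas, thr, tol,
                           max_iter = 100) {
  for (it in seq_len(max_iter)) {
    if (thr - f_feas <= tol * thr) break
    mid <- (e_feas + e_infeas) / 2
    if (mid == e_feas || mid == e_infeas) break # float resolution reached
    f_mid <- effect_fn(mid)
    if (f_mid < thr) {
      e_feas <- mid; f_feas <- f_mid
    } else {
      e_infeas <- mid
    }
  }
  list(conc = e_feas, effect = f_feas)
}

# Search one direction for the effective concentration of `target`.
# `f_at_base` is the (optional, precomputed) effect with the target left at
# E_di. Returns NULL when the direction cannot meet the criterion in bounds.
search_direction <- function(effect_fn, E_di, direction, thr, config,
                             f_at_base = NULL) {
  tol <- config$effect_tolerance
  if (direction == "decrease") {
    if (E_di <= 0) return(NULL)
    f_lo <- effect_fn(0)
    if (f_lo >= thr) return(NULL)
    f_di <- f_at_base %||% effect_fn(E_di)
    if (f_di < thr) { # already normal without perturbation: zero dose
      return(list(conc = E_di, effect = f_di))
    }
    bisect_between(effect_fn, 0, f_lo, E_di, thr, tol)
  } else {
    base <- if (E_di > 0) E_di else 1
    f_base <- (if (E_di > 0) f_at_base else NULL) %||% effect_fn(base)
    if (f_base < thr) return(list(conc = base, effect = f_base))
    hi <- base
    f_prev <- f_base
    n_rising <- 0
    repeat {
      hi <- hi * 2
      if (hi > base * config$max_fold_increase) return(NULL)
      f_hi <- tryCatch(effect_fn(hi), synergyscreen_simulation_error = function(e) NA_real_)
      # an integration failure at an extreme dose marks the practical search
      # bound for this direction
      if (is.na(f_hi)) return(NULL)
      if (f_hi < thr) break
      # effect moving away from the threshold: assume monotone dose-effect
      # and stop after three consecutive rises above the unperturbed level
      n_rising <- if (f_hi > f_prev && f_hi > f_base) n_rising + 1 else 0
      if (n_rising >= 3) return(NULL)
      f_prev <- f_hi
    }
    bisect_between(effect_fn, hi, f_hi, hi / 2, thr, tol)
  }
}

sensitivity_record <- function(target, E_di, found, direction, config,
                               threshold) {
  if (is.null(found)) {
    return(tibble(
      target = target, E_di = E_di, E_hi = NA_real_, delta_E = NA_real_,
      ratio = NA_real_, direction = NA_character_,
      classification = "infeasible", effect = NA_real_, threshold = threshold
    ))
  }
  delta <- abs(E_di - found$conc)
  ratio <- delta / E_di
  tibble(
    target = target, E_di = E_di, E_hi = found$conc, delta_E = delta,
    ratio = ratio, direction = direction,
    classification = if (ratio <= config$a) "sensitive" else "insensitive",
    effect = found$effect, threshold = threshold
  )
}

#' Find the effective single-target dose of an enzyme
#'
#' Searches both perturbation directions — decreasing the enzyme within
#' \eqn{[0, E_{di}]} and increasing it within
#' \eqn{[E_{di}, E_{di} \cdot max\_fold\_increase]} — by bracketing plus
#' bisection on the monotone dose–effect curve, for the concentration
#' \eqn{E_{hi}} at which the cumulative readout output is *just* below
#' `theta * disease_output` (within `effect_tolerance`, relative). The
#' cheaper direction (smaller \eqn{\Delta E_i / E_{di}}) is reported, and the
#' target is classified `sensitive` if the ratio is at most `a`,
#' `insensitive` if larger, or `infeasible` if neither direction reaches the
#' criterion within bounds.
#'
#' @param model A valid [network_model()].
#' @param target A target enzyme id (must be in `model$targets`).
#' @param criterion A [state_criterion()].
#' @param config A [screen_config()].
#' @return A one-row tibble: `target`, `E_di`, `E_hi`, `delta_E`
#'   (\eqn{|E_{di} - E_{hi}|}), `ratio` (\eqn{\Delta E_i / E_{di}}),
#'   `direction` (`"decrease"`/`"increase"`), `classification`, the achieved
#'   `effect` and the criterion `threshold`.
#' @export
find_effective_dose <- function(model, target, criterion,
                                config = screen_config()) {
  stopifnot(inherits(criterion, "state_criterion"))
  if (!target %in% model$targets) {
    abort(sprintf("'%s' is not a declared drug target", target),
          class = "synergyscreen_validation_error")
  }
  E_di <- model$species$initial[model$species$id == target]
  if (E_di <= 0) {
    return(sensitivity_record(target, E_di, NULL, NA, config,
                              criterion$threshold))
  }
  effect_fn <- function(conc) {
    perturbed_effect(model, perturbation(target, conc), config)
  }
  thr <- criterion$threshold
  f0 <- effect_fn(E_di) # unperturbed target: the disease-state effect
  dn <- search_direction(effect_fn, E_di, "decrease", thr, config, f_at_base = f0)
  up <- search_direction(effect_fn, E_di, "increase", thr, config, f_at_base = f0)
  rec_dn <- if (!is.null(dn)) sensitivity_record(target, E_di, dn, "decrease", config, thr)
  rec_up <- if (!is.null(up)) sensitivity_record(target, E_di, up, "increase", config, thr)
  if (is.null(rec_dn) && is.null(rec_up)) {
    sensitivity_record(target, E_di, NULL, NA, config, thr)
  } else if (is.null(rec_up) || (!is.null(rec_dn) && rec_dn$ratio <= rec_up$ratio)) {
    rec_dn
  } else {
    rec_up
  }
}

#' Rank all drug targets by their relative effective perturbation
#'
#' Runs [find_effective_dose()] for every declared target, sorts ascending by
#' \eqn{\Delta E_i / E_{di}} (infeasible targets last) and classifies each
#' against the sensitivity threshold `a`.
#'
#' @param model A valid [network_model()] with a non-empty target list.
#' @param criterion A [state_criterion()], or `NULL` to compute the disease
#'   baseline from the unperturbed model with `config$theta`.
#' @param config A [screen_config()].
#' @return A tibble, one row per target, with a leading `rank` column and the
#'   columns of [find_effective_dose()].
#' @export
rank_targets <- function(model, criterion = NULL, config = screen_config()) {
  stop_if_invalid(model)
  if (length(model$targets) == 0) {
    abort("model declares no drug targets", class = "synergyscreen_validation_error")
  }
  criterion <- criterion %||% disease_criterion(model, config$theta, config)
  records <- purrr::map_dfr(sort(model$targets), find_effective_dose,
                            model = model, criterion = criterion,
                            config = config)
  records |>
    dplyr::arrange(is.na(.data$ratio), .data$ratio, .data$target) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
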