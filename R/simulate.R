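# Compile a model into an index-based derivative evaluator. Returns a list
# with f(state) -> d(state)/dt and production(state) -> total synthesis flux
# into the readout (used for the cumulative-output auxiliary state).
compile_network <- function(model) {
  ids <- model$species$id
  idx <- setNames(seq_along(ids), ids)
  n <- length(ids)
  rxs <- purrr::map(model$reactions, function(rx) {
    list(
      kind = rx$law$law_kind,
      k = rx$law$constants,
      i_s = if (!is.null(rx$substrate)) idx[[rx$substrate]] else NA_integer_,
      i_p = if (!is.null(rx$product)) idx[[rx$product]] else NA_integer_,
      i_e = if (!is.null(rx$enzyme)) idx[[rx$enzyme]] else NA_integer_,
      i_i = if (!is.null(rx$modifiers$inhibitor)) idx[[rx$modifiers$inhibitor]] else NA_integer_,
      i_a = if (!is.null(rx$modifiers$activator)) idx[[rx$modifiers$activator]] else NA_integer_,
      i_g = if (!is.null(rx$modifiers$transcription_signal)) idx[[rx$modifiers$transcription_signal]] else NA_integer_
    )
  })
  i_read <- idx[[model$readout]]

  rate_of <- function(rx, x) {
    k <- rx$k
    switch(rx$kind,
      michaelis_menten =
        k[["K_cat"]] * x[rx$i_e] * x[rx$i_s] / (k[["K_m"]] + x[rx$i_s]),
      competitive_inhibition =
        k[["K_cat"]] * x[rx$i_e] * x[rx$i_s] /
          (k[["K_m"]] * (1 + x[rx$i_i] / k[["K_i"]]) + x[rx$i_s]),
      irreversible_inactivation =
        k[["K"]] * x[rx$i_e] * x[rx$i_i],
      activation =
        k[["K_cat"]] * (1 + x[rx$i_a] / k[["KI"]]) * x[rx$i_e] * x[rx$i_s] /
          (k[["K_m"]] + x[rx$i_s]),
      transcription_upregulation =
        k[["k_max"]] * x[rx$i_g]^2 / (x[rx$i_g]^2 + k[["k_half"]]^2)
    )
  }

  f <- function(state) {
    # rate laws are smooth through slightly negative integrator excursions
    # (|S| ~ atol) and self-correcting there; clipping is applied only when
    # states are reported, to keep the derivative smooth for the integrator
    x <- state
    dx <- numeric(n)
    prod_read <- 0
    for (rx in rxs) {
      v <- rate_of(rx, x)
      if (rx$kind == "irreversible_inactivation") {
        dx[rx$i_e] <- dx[rx$i_e] - v
        if (rx$i_e == i_read) prod_read <- prod_read # decay is consumption, not production
      } else if (rx$kind == "transcription_upregulation") {
        dx[rx$i_e] <- dx[rx$i_e] + v
        if (rx$i_e == i_read) prod_read <- prod_read + v
      } else {
        dx[rx$i_s] <- dx[rx$i_s] - v
        if (!is.na(rx$i_p)) {
          dx[rx$i_p] <- dx[rx$i_p] + v
          if (rx$i_p == i_read) prod_read <- prod_read + v
        }
      }
    }
    list(dx = dx, production = prod_read)
  }
  list(f = f, ids = ids, idx = idx, i_read = i_read)
}

#' Assemble the time-derivative function of a network
#'
#' Sums, for every species, the signed contributions of all reactions:
#' catalytic fluxes are applied as \eqn{-v} to the substrate and \eqn{+v} to
#' the product (substrates are consumed, 1:1 stoichiometry), irreversible
#' inactivation as \eqn{-v} to its enzyme pool, and transcriptional
#' up-regulation as \eqn{+v} to its enzyme pool.
#'
#' @param model A valid [network_model()].
#' @return A function mapping a named (or declared-order) state vector of
#'   concentrations to the vector \eqn{d(state)/dt}, in declared species
#'   order.
#' @export
assemble_rhs <- function(model) {
  stop_if_invalid(model)
  cm <- compile_network(model)
  function(state) {
    state <- as.numeric(state)
    if (length(state) != length(cm$ids)) {
      abort("state vector length does not match the number of species",
            class = "synergyscreen_consistency_error")
    }
    setNames(cm$f(state)$dx, cm$ids)
  }
}

#' Specify an enzyme-concentration perturbation
#'
#' A drug dose is represented as a step perturbation: the target enzyme
#' pool's initial concentration is replaced by `new_concentration` at
#' \eqn{t = 0}.
#'
#' @param target Enzyme-pool id (must be in `model$targets` when simulated).
#' @param new_concentration Replacement concentration, \eqn{\ge 0}.
#' @return A one-row tibble with columns `target` and `new_concentration`.
#'   [simulate_network()] accepts any data frame with these columns, so
#'   perturbations can be combined with `dplyr::bind_rows()`.
#' @export
perturbation <- function(target, new_concentration) {
  if (!is.finite(new_concentration) || new_concentration < 0) {
    abort("new_concentration must be a finite value >= 0",
          class = "synergyscreen_validation_error")
  }
  tibble(target = as.character(target),
         new_concentration = as.numeric(new_concentration))
}

apply_perturbations <- function(model, perturbations) {
  y0 <- setNames(model$species$initial, model$species$id)
  if (is.null(perturbations) || nrow(perturbations) == 0) return(y0)
  perturbations <- as_tibble(perturbations)
  if (anyDuplicated(perturbations$target)) {
    abort("perturbation targets must be distinct",
          class = "synergyscreen_validation_error")
  }
  for (i in seq_len(nrow(perturbations))) {
    tg <- perturbations$target[i]
    val <- perturbations$new_concentration[i]
    if (!tg %in% model$targets) {
      abort(sprintf("perturbation target '%s' is not in model$targets", tg),
            class = "synergyscreen_validation_error")
    }
    if (!is.finite(val) || val < 0) {
      abort("new_concentration must be a finite value >= 0",
            class = "synergyscreen_validation_error")
    }
    y0[[tg]] <- val
  }
  y0
}

#' Simulate a network under enzyme perturbations
#'
#' Integrates the model ODEs from the (perturbed) initial state over
#' \eqn{[0, horizon]} with a stiff-capable adaptive integrator
#' ([deSolve::lsoda()]). An auxiliary state accumulates the synthesis flux
#' into the readout species, so the cumulative production is integrated to
#' the same tolerance as the trajectory itself.
#'
#' @param model A valid [network_model()].
#' @param perturbations `NULL`, or a data frame of [perturbation()] rows with
#'   distinct targets.
#' @param config A [screen_config()]; `rtol`, `atol`, `n_save` and
#'   `readout_mode` are used here.
#' @return A `network_trajectory`: times, a states matrix (clipped at 0 for
#'   reporting), the running cumulative readout production, and the scalar
#'   `cumulative_readout` over the full horizon. Use [tidy()] for a long
#'   tibble and [cumulative_output()] for the scalar.
#' @export
simulate_network <- function(model, perturbations = NULL,
                             config = screen_config()) {
  stop_if_invalid(model)
  y0 <- apply_perturbations(model, perturbations)
  cm <- compile_network(model)
  times <- seq(0, model$horizon, length.out = config$n_save)
  deriv <- function(t, y, parms) {
    res <- cm$f(y[seq_along(cm$ids)])
    list(c(res$dx, res$production))
  }
  out <- try(deSolve::lsoda(
    y = c(y0, ..cumulative.. = 0), times = times, func = deriv, parms = NULL,
    rtol = config$rtol, atol = config$atol, maxsteps = 50000
  ), silent = TRUE)
  if (inherits(out, "try-error")) {
    abort(sprintf("integration failed: %s", attr(out, "condition")$message %||% "unknown"),
          class = "synergyscreen_simulation_error")
  }
  out <- unclass(out)
  if (nrow(out) < length(times)) {
    abort(sprintf("integration failed near t = %g", out[nrow(out), 1]),
          class = "synergyscreen_simulation_error")
  }
  states <- out[, cm$ids, drop = FALSE]
  states[states < 0] <- 0
  cum <- unname(out[, "..cumulative.."])
  cum_flux <- cum[length(cum)]
  readout_final <- unname(states[nrow(states), model$readout])
  structure(list(
    times = out[, 1],
    states = states,
    cumulative_production = cum,
    readout = model$readout,
    readout_mode = config$readout_mode,
    cumulative_readout = if (config$readout_mode == "flux") cum_flux else readout_final,
    cumulative_flux = cum_flux,
    readout_final = readout_final
  ), class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf(
    "<network_trajectory> %d time points over [0, %g]; cumulative %s output (%s mode): %g\n",
    length(x$times), max(x$times), x$readout, x$readout_mode, x$cumulative_readout
  ))
  invisible(x)
}

#' Tidy a simulated trajectory
#'
#' @param x A `network_trajectory`.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `species`, `concentration`.
#' @export
tidy.network_trajectory <- function(x, ...) {
  as_tibble(as.data.frame(x$states)) |>
    dplyr::mutate(time = x$times, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "species",
                        values_to = "concentration")
}

#' @export
glance.network_trajectory <- function(x, ...) {
  tibble(
    readout = x$readout, readout_mode = x$readout_mode,
    cumulative_readout = x$cumulative_readout,
    cumulative_flux = x$cumulative_flux,
    readout_final = x$readout_final,
    horizon = max(x$times), n_save = length(x$times)
  )
}

#' Cumulative readout output of a trajectory
#'
#' Under the default `readout_mode = "flux"` this is the time integral over
#' the horizon of the total synthesis flux into the readout species — the
#' cumulative production, which keeps consumption-side targets meaningful
#' (a readout that is itself degraded can have its *level* lowered without
#' its *production* changing). `readout_mode = "level"` instead reports the
#' readout's final concentration.
#'
#' @param trajectory A `network_trajectory` from [simulate_network()].
#' @param mode `"flux"` (default: integrated production) or `"level"` (final
#'   concentration); defaults to the mode the trajectory was simulated with.
#' @return A non-negative scalar.
#' @export
cumulative_output <- function(trajectory, mode = NULL) {
  stopifnot(inherits(trajectory, "network_trajectory"))
  mode <- mode %||% trajectory$readout_mode
  mode <- match.arg(mode, c("flux", "level"))
  if (mode == "flux") trajectory$cumulative_flux else trajectory$readout_final
}
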