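dir_sign <- function(direction) if (direction == "decrease") -1 else 1

#' Required dose of a target given a fixed partner perturbation
#'
#' With the partner's perturbation held fixed, bisects the target's
#' concentration (as in [find_effective_dose()]) for the dose magnitude
#' \eqn{\Delta E = |E_d - E_h|} that just meets the normal-state criterion.
#' If the criterion is already met by the partner alone the required dose is
#' zero. Infeasibility within the search bounds is reported as data
#' (`feasible = FALSE`), not as an error.
#'
#' @param model A valid [network_model()].
#' @param target Target enzyme id to dose.
#' @param partner `NULL`, or a data frame of [perturbation()] rows held fixed
#'   during the search.
#' @param criterion A [state_criterion()].
#' @param config A [screen_config()].
#' @param direction `"both"` (default: cheaper of the two), `"decrease"` or
#'   `"increase"`; isobologram construction fixes the direction to the
#'   target's single-dose direction so that fractional doses are comparable.
#' @return A one-row tibble: `target`, `E_di`, `E_hi`, `delta_E`, `ratio`,
#'   `direction`, `feasible`, `effect`.
#' @export
dose_for_effect <- function(model, target, partner = NULL, criterion,
                            config = screen_config(),
                            direction = c("both", "decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(inherits(criterion, "state_criterion"))
  E_di <- model$species$initial[model$species$id == target]
  thr <- criterion$threshold
  effect_fn <- function(conc) {
    perturbed_effect(model, dplyr::bind_rows(partner, perturbation(target, conc)),
                     config)
  }
  base_effect <- perturbed_effect(model, partner, config)
  if (base_effect < thr) { # partner alone already reaches the normal state
    return(tibble(target = target, E_di = E_di, E_hi = E_di, delta_E = 0,
                  ratio = 0, direction = direction, feasible = TRUE,
                  effect = base_effect))
  }
  dirs <- if (direction == "both") c("decrease", "increase") else direction
  found <- purrr::map(dirs, function(d) {
    res <- search_direction(effect_fn, E_di, d, thr, config,
                            f_at_base = base_effect)
    if (is.null(res)) NULL else c(res, list(direction = d))
  })
  found <- purrr::compact(found)
  if (length(found) == 0) {
    return(tibble(target = target, E_di = E_di, E_hi = NA_real_,
                  delta_E = NA_real_, ratio = NA_real_,
                  direction = NA_character_, feasible = FALSE,
                  effect = NA_real_))
  }
  best <- found[[which.min(purrr::map_dbl(found, ~ abs(E_di - .x$conc)))]]
  delta <- abs(E_di - best$conc)
  tibble(target = target, E_di = E_di, E_hi = best$conc, delta_E = delta,
         ratio = delta / E_di, direction = best$direction, feasible = TRUE,
         effect = best$effect)
}

categorise_isobologram <- function(ci, band = 0.10) {
  lo <- 1 - band
  hi <- 1 + band
  if (max(ci) < lo) "synergy"
  else if (min(ci) > hi) "antagonism"
  else if (all(ci >= lo & ci <= hi)) "additive"
  else "hybrid"
}

representative_ci_of <- function(ci_min, ci_max, category) {
  switch(category,
    synergy = ci_min,
    antagonism = ci_max,
    additive = if ((1 - ci_min) >= (ci_max - 1)) ci_min else ci_max,
    hybrid = c(ci_min, ci_max)
  )
}

#' Loewe combination-index isobologram for a pair of sensitive targets
#'
#' Constructs the equal-effect contour of a target pair: for each grid
#' fraction \eqn{f_1} of target A's single effective dose \eqn{(Dx)_1}, the
#' dose of B required (in B's own single-dose direction) to restore the
#' normal state is found by [dose_for_effect()], giving the dose point
#' \eqn{(f_1, f_2)} with combination index \eqn{CI = f_1 + f_2}
#' (Loewe additivity: \eqn{CI = 1}).
#'
#' The pair is categorised against the nearly-additive band
#' \eqn{|CI - 1| \le 0.10}: `synergy` if every CI is below the band,
#' `antagonism` if every CI is above it, `additive` if all fall inside, and
#' `hybrid` otherwise. The representative CI is the smallest CI for synergy,
#' the largest for antagonism, and both extremes for a hybrid pair (reported
#' as two graded entries). For the synergy tally a pair counts as
#' synergistic when its smallest CI is below 1.
#'
#' @param model A valid [network_model()].
#' @param pair Character vector of two target ids.
#' @param criterion A [state_criterion()].
#' @param config A [screen_config()]; `dose_grid_step` sets the fraction grid
#'   (default 0.1, 0.2, ..., 0.9; endpoints reduce to single-target cases and
#'   are excluded).
#' @param singles Optional precomputed [find_effective_dose()] records for
#'   the two targets (saves re-running the single-target searches).
#' @return An object of class `isobologram`; see [tidy.isobologram()],
#'   [glance.isobologram()], [autoplot.isobologram()].
#' @export
ci_isobologram <- function(model, pair, criterion, config = screen_config(),
                           singles = NULL) {
  stopifnot(length(pair) == 2, inherits(criterion, "state_criterion"))
  singles <- singles %||% purrr::map_dfr(pair, find_effective_dose,
                                         model = model, criterion = criterion,
                                         config = config)
  singles <- dplyr::filter(singles, .data$target %in% pair)
  rec1 <- dplyr::filter(singles, .data$target == pair[1])
  rec2 <- dplyr::filter(singles, .data$target == pair[2])
  if (nrow(rec1) != 1 || nrow(rec2) != 1 ||
      rec1$classification == "infeasible" || rec2$classification == "infeasible") {
    abort(sprintf("pair (%s, %s): both targets need a finite single effective dose",
                  pair[1], pair[2]),
          class = "synergyscreen_screen_error")
  }
  if (any(c(rec1$classification, rec2$classification) != "sensitive")) {
    warn(sprintf("pair (%s, %s): isobologram requested for a non-sensitive target",
                 pair[1], pair[2]))
  }
  Dx1 <- rec1$delta_E
  Dx2 <- rec2$delta_E
  s1 <- dir_sign(rec1$direction)
  step <- config$dose_grid_step
  f1_grid <- seq(step, 1 - step / 2, by = step)
  f1_grid <- f1_grid[f1_grid < 1]
  points <- purrr::map_dfr(f1_grid, function(f1) {
    E_h1 <- rec1$E_di + s1 * f1 * Dx1
    partner <- perturbation(pair[1], E_h1)
    res <- dose_for_effect(model, pair[2], partner, criterion, config,
                           direction = rec2$direction)
    if (!res$feasible) {
      warn(sprintf("pair (%s, %s): dropping infeasible grid point f1 = %g",
                   pair[1], pair[2], f1))
      return(NULL)
    }
    tibble(f1 = f1, f2 = res$delta_E / Dx2, ci = f1 + res$delta_E / Dx2,
           dose_1 = f1 * Dx1, dose_2 = res$delta_E,
           E_h1 = E_h1, E_h2 = res$E_hi, effect = res$effect)
  })
  if (nrow(points) == 0) {
    abort(sprintf("pair (%s, %s): every isobologram grid point is infeasible",
                  pair[1], pair[2]),
          class = "synergyscreen_screen_error")
  }
  ci_min <- min(points$ci)
  ci_max <- max(points$ci)
  category <- categorise_isobologram(points$ci)
  rep_ci <- representative_ci_of(ci_min, ci_max, category)
  structure(list(
    pair = pair, points = points, singles = dplyr::bind_rows(rec1, rec2),
    ci_min = ci_min, ci_max = ci_max, category = category,
    representative_ci = rep_ci, grades = grade_ci(rep_ci),
    synergistic = ci_min < 1
  ), class = "isobologram")
}

#' @export
print.isobologram <- function(x, ...) {
  cat(sprintf("<isobologram> %s-%s: %d points, CI in [%.4g, %.4g], %s\n",
              x$pair[1], x$pair[2], nrow(x$points), x$ci_min, x$ci_max,
              x$category))
  for (i in seq_len(nrow(x$grades))) {
    cat(sprintf("  CI %.4g: %s (%s)\n", x$grades$ci[i], x$grades$description[i],
                x$grades$symbols[i]))
  }
  invisible(x)
}

#' Tidy an isobologram into its dose points
#'
#' @param x An `isobologram`.
#' @param ... Unused.
#' @return A tibble of equal-effect dose points (`f1`, `f2`, `ci`, absolute
#'   doses and perturbed concentrations), with the pair ids prepended.
#' @export
tidy.isobologram <- function(x, ...) {
  dplyr::mutate(x$points, target_1 = x$pair[1], target_2 = x$pair[2],
                .before = 1)
}

#' One-row summary of an isobologram
#'
#' @param x An `isobologram`.
#' @param ... Unused.
#' @return A one-row tibble with the CI range, interaction category, primary
#'   representative CI and its grade (hybrid pairs carry their second graded
#'   entry in `representative_ci_2`/`description_2`/`symbols_2`).
#' @export
glance.isobologram <- function(x, ...) {
  g <- x$grades
  tibble(
    target_1 = x$pair[1], target_2 = x$pair[2], n_points = nrow(x$points),
    ci_min = x$ci_min, ci_max = x$ci_max, category = x$category,
    representative_ci = x$representative_ci[1],
    description = g$description[1], symbols = g$symbols[1],
    representative_ci_2 = if (x$category == "hybrid") x$representative_ci[2] else NA_real_,
    description_2 = if (x$category == "hybrid") g$description[2] else NA_character_,
    symbols_2 = if (x$category == "hybrid") g$symbols[2] else NA_character_,
    synergistic = x$synergistic
  )
}

# Table-4-style graded rows: one per representative CI (two for hybrids).
isobologram_grades <- function(x) {
  dplyr::mutate(x$grades, target_1 = x$pair[1], target_2 = x$pair[2],
                category = x$category, .before = 1)
}

joint_concentrations <- function(E_di, directions, s) {
  purrr::pmap_dbl(list(E_di, directions, s), function(e, d, si) {
    if (d == "decrease") e * (1 - si) else e * (1 + si)
  })
}

#' Screen a pair of insensitive targets by joint perturbation
#'
#' Searches for a joint perturbation of two targets — neither of which can
#' restore the normal state alone at an acceptable dose — such that the
#' criterion is met with both relative doses \eqn{\Delta E_i / E_{di} \le 1}.
#' A common relative-dose scalar \eqn{s \in (0, 1]} is applied to both
#' targets in each target's cheaper direction (decrease:
#' \eqn{E_{di}(1 - s)}; increase: \eqn{E_{di}(1 + s)}, so the relative dose
#' equals \eqn{s} either way and the \eqn{\le 1} bound holds by
#' construction), bisected to the smallest feasible \eqn{s}, then refined per
#' axis. Direction assignments are tried in order of the single-target
#' searches' preference, falling back over all four combinations. The pair
#' is synergistic iff a feasible joint point exists.
#'
#' @param model A valid [network_model()].
#' @param pair Character vector of two target ids.
#' @param criterion A [state_criterion()].
#' @param config A [screen_config()].
#' @param singles Optional precomputed single-target records.
#' @return A one-row tibble: the pair, `branch = "insensitive"`,
#'   `synergistic`, the found relative doses `ratio_1`/`ratio_2`, directions
#'   and perturbed concentrations (`NA` when no feasible point exists).
#' @export
screen_insensitive_pair <- function(model, pair, criterion,
                                    config = screen_config(), singles = NULL) {
  stopifnot(length(pair) == 2, inherits(criterion, "state_criterion"))
  singles <- singles %||% purrr::map_dfr(pair, find_effective_dose,
                                         model = model, criterion = criterion,
                                         config = config)
  thr <- criterion$threshold
  tol <- config$effect_tolerance
  dir_prefs <- purrr::map(pair, function(tg) {
    rec <- dplyr::filter(singles, .data$target == tg)
    if (nrow(rec) == 1 && !is.na(rec$direction)) {
      c(rec$direction, setdiff(c("decrease", "increase"), rec$direction))
    } else {
      c("decrease", "increase")
    }
  })
  E_di <- purrr::map_dbl(pair, function(tg) {
    model$species$initial[model$species$id == tg]
  })
  combos <- tidyr::expand_grid(d1 = dir_prefs[[1]], d2 = dir_prefs[[2]])
  empty <- tibble(
    target_1 = pair[1], target_2 = pair[2], branch = "insensitive",
    synergistic = FALSE, ratio_1 = NA_real_, ratio_2 = NA_real_,
    direction_1 = NA_character_, direction_2 = NA_character_,
    E_h1 = NA_real_, E_h2 = NA_real_, effect = NA_real_
  )
  for (i in seq_len(nrow(combos))) {
    dirs <- c(combos$d1[i], combos$d2[i])
    effect_s <- function(s1, s2) {
      conc <- joint_concentrations(E_di, dirs, c(s1, s2))
      perturbed_effect(model, dplyr::bind_rows(
        perturbation(pair[1], conc[1]), perturbation(pair[2], conc[2])
      ), config)
    }
    f_full <- effect_s(1, 1)
    if (f_full >= thr) next
    # smallest common scalar meeting the criterion
    common <- bisect_between(function(s) effect_s(s, s), 1, f_full, 0, thr, tol)
    s1 <- common$conc
    s2 <- common$conc
    # per-axis refinement: shrink each dose while the criterion still holds
    r1 <- bisect_between(function(s) effect_s(s, s2), s1, common$effect, 0, thr, tol)
    s1 <- r1$conc
    r2 <- bisect_between(function(s) effect_s(s1, s), s2, r1$effect, 0, thr, tol)
    s2 <- r2$conc
    conc <- joint_concentrations(E_di, dirs, c(s1, s2))
    return(tibble(
      target_1 = pair[1], target_2 = pair[2], branch = "insensitive",
      synergistic = TRUE, ratio_1 = s1, ratio_2 = s2,
      direction_1 = dirs[1], direction_2 = dirs[2],
      E_h1 = conc[1], E_h2 = conc[2], effect = r2$effect
    ))
  }
  empty
}

#' Screen a sensitive + insensitive pair with alpha-assisted dose reduction
#'
#' Fixes the sensitive target at a reduced dose
#' \eqn{(\Delta E_j)^1 = \alpha (\Delta E_j)^2} — a fraction \eqn{\alpha} of
#' its single effective dose, in the same direction — and asks the
#' insensitive partner to cover the remaining effect via
#' [dose_for_effect()]. The pair is synergistic iff the partner's resulting
#' relative dose satisfies \eqn{\Delta E_i / E_{di} \le 1}.
#'
#' @param model A valid [network_model()].
#' @param sensitive_target,insensitive_target Target ids.
#' @param criterion A [state_criterion()].
#' @param config A [screen_config()]; `alpha` is taken from here.
#' @param singles Optional precomputed single-target records.
#' @return A one-row tibble: the pair, `branch = "mixed"`, `alpha`, the
#'   sensitive target's full and reduced relative doses, the insensitive
#'   partner's required relative dose, and `synergistic`.
#' @export
screen_mixed_pair <- function(model, sensitive_target, insensitive_target,
                              criterion, config = screen_config(),
                              singles = NULL) {
  stopifnot(inherits(criterion, "state_criterion"))
  singles <- singles %||% find_effective_dose(model, sensitive_target,
                                              criterion, config)
  rec_j <- dplyr::filter(singles, .data$target == sensitive_target)
  if (nrow(rec_j) != 1 || rec_j$classification == "infeasible") {
    abort(sprintf("sensitive target '%s' has no finite single effective dose",
                  sensitive_target),
          class = "synergyscreen_screen_error")
  }
  alpha <- config$alpha
  delta_reduced <- alpha * rec_j$delta_E
  E_hj <- rec_j$E_di + dir_sign(rec_j$direction) * delta_reduced
  partner <- perturbation(sensitive_target, E_hj)
  rec_i <- dose_for_effect(model, insensitive_target, partner, criterion,
                           config, direction = "both")
  tibble(
    target_1 = sensitive_target, target_2 = insensitive_target,
    branch = "mixed", alpha = alpha,
    sensitive_ratio_single = rec_j$ratio,
    sensitive_ratio_reduced = alpha * rec_j$ratio,
    sensitive_direction = rec_j$direction,
    insensitive_ratio = rec_i$ratio,
    insensitive_direction = rec_i$direction,
    E_h1 = E_hj, E_h2 = rec_i$E_hi,
    synergistic = isTRUE(rec_i$feasible && rec_i$ratio <= 1)
  )
}

#' Run the full three-branch combination screen
#'
#' Ranks and classifies every declared target ([rank_targets()]), then
#' screens all pairs: sensitive pairs by Loewe combination-index
#' isobolograms ([ci_isobologram()]), pairs of insensitive (or singly
#' infeasible) targets by joint-perturbation feasibility
#' ([screen_insensitive_pair()]), and mixed pairs by alpha-assisted dose
#' reduction ([screen_mixed_pair()]). Errors are isolated per pair.
#'
#' @param model A valid [network_model()].
#' @param criterion A [state_criterion()], or `NULL` to compute the disease
#'   baseline from the model.
#' @param config A [screen_config()].
#' @return An object of class `screen_report` with elements `targets` (the
#'   ranking tibble), `isobolograms` (named list), `verdicts` (one row per
#'   pair), `errors` and `total_synergistic`. See [tidy.screen_report()] and
#'   [glance.screen_report()].
#' @export
screen_all <- function(model, criterion = NULL, config = screen_config()) {
  stop_if_invalid(model)
  criterion <- criterion %||% disease_criterion(model, config$theta, config)
  ranks <- rank_targets(model, criterion, config)
  sens <- ranks$target[ranks$classification == "sensitive"]
  insens <- ranks$target[ranks$classification != "sensitive"]
  verdicts <- list()
  isobolograms <- list()
  errors <- list()
  note_error <- function(pair, branch, cond) {
    errors[[length(errors) + 1]] <<- tibble(
      target_1 = pair[1], target_2 = pair[2], branch = branch,
      message = conditionMessage(cond)
    )
  }
  if (length(sens) >= 2) {
    for (idx in utils::combn(sort(sens), 2, simplify = FALSE)) {
      tryCatch({
        iso <- ci_isobologram(model, idx, criterion, config, singles = ranks)
        isobolograms[[paste(idx, collapse = "-")]] <- iso
        verdicts[[length(verdicts) + 1]] <-
          dplyr::mutate(glance(iso), branch = "sensitive")
      }, error = function(e) note_error(idx, "sensitive", e))
    }
  }
  if (length(insens) >= 2) {
    for (idx in utils::combn(sort(insens), 2, simplify = FALSE)) {
      tryCatch({
        verdicts[[length(verdicts) + 1]] <-
          screen_insensitive_pair(model, idx, criterion, config, singles = ranks)
      }, error = function(e) note_error(idx, "insensitive", e))
    }
  }
  for (sj in sort(sens)) {
    for (ii in sort(insens)) {
      tryCatch({
        verdicts[[length(verdicts) + 1]] <-
          screen_mixed_pair(model, sj, ii, criterion, config, singles = ranks)
      }, error = function(e) note_error(c(sj, ii), "mixed", e))
    }
  }
  verdicts <- if (length(verdicts) > 0) {
    dplyr::relocate(dplyr::bind_rows(verdicts), "target_1", "target_2",
                    "branch", "synergistic")
  } else {
    tibble(target_1 = character(), target_2 = character(),
           branch = character(), synergistic = logical())
  }
  errors <- if (length(errors) > 0) dplyr::bind_rows(errors) else
    tibble(target_1 = character(), target_2 = character(),
           branch = character(), message = character())
  structure(list(
    targets = ranks, isobolograms = isobolograms, verdicts = verdicts,
    errors = errors, criterion = criterion, config = config,
    total_synergistic = sum(verdicts$synergistic %in% TRUE)
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<screen_report> %d targets (%d sensitive / %d insensitive / %d infeasible)\n",
    g$n_targets, g$n_sensitive, g$n_insensitive, g$n_infeasible
  ))
  cat(sprintf(
    "  synergistic pairs: %d sensitive + %d insensitive + %d mixed = %d total\n",
    g$synergistic_sensitive, g$synergistic_insensitive, g$synergistic_mixed,
    g$total_synergistic
  ))
  if (nrow(x$errors) > 0) cat(sprintf("  %d pair(s) errored\n", nrow(x$errors)))
  invisible(x)
}

#' Tidy a screen report into its per-pair verdicts
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return The verdict tibble, one row per screened pair.
#' @export
tidy.screen_report <- function(x, ...) x$verdicts

#' One-row summary of a screen report
#'
#' @param x A `screen_report`.
#' @param ... Unused.
#' @return A one-row tibble of target-class counts and per-branch synergistic
#'   pair counts.
#' @export
glance.screen_report <- function(x, ...) {
  cls <- x$targets$classification
  syn_by <- function(br) {
    sum(x$verdicts$synergistic[x$verdicts$branch == br] %in% TRUE)
  }
  tibble(
    n_targets = nrow(x$targets),
    n_sensitive = sum(cls == "sensitive"),
    n_insensitive = sum(cls == "insensitive"),
    n_infeasible = sum(cls == "infeasible"),
    synergistic_sensitive = syn_by("sensitive"),
    synergistic_insensitive = syn_by("insensitive"),
    synergistic_mixed = syn_by("mixed"),
    total_synergistic = x$total_synergistic
  )
}
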