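#' Build a reaction for a kinetic network
#'
#' A reaction couples a [kinetic_law()] to named species. Catalytic laws
#' (`michaelis_menten`, `competitive_inhibition`, `activation`) need a
#' `substrate` and an `enzyme` (the product may be `NULL` for a pure sink);
#' `irreversible_inactivation` and `transcription_upregulation` act on the
#' `enzyme` pool itself and take no substrate. Modifier species are required
#' exactly where the law reads them: `inhibitor` for inhibition/inactivation,
#' `activator` for activation, `transcription_signal` for up-regulation.
#'
#' @param id Unique reaction id.
#' @param law_kind Rate-law family (see [kinetic-laws]).
#' @param constants Named constants passed to [kinetic_law()].
#' @param substrate,product,enzyme Species ids (`product`/`substrate` may be
#'   `NULL` where the law allows).
#' @param inhibitor,activator,transcription_signal Modifier species ids.
#' @return An object of class `network_reaction`.
#' @export
reaction <- function(id, law_kind, constants, substrate = NULL, product = NULL,
                     enzyme = NULL, inhibitor = NULL, activator = NULL,
                     transcription_signal = NULL) {
  law <- kinetic_law(law_kind, constants)
  structure(list(
    id = as.character(id),
    law = law,
    substrate = substrate,
    product = product,
    enzyme = enzyme,
    modifiers = purrr::compact(list(
      inhibitor = inhibitor,
      activator = activator,
      transcription_signal = transcription_signal
    ))
  ), class = "network_reaction")
}

#' Build a kinetic network model
#'
#' @param species A data frame with columns `id` (character, unique),
#'   `initial` (non-negative concentration) and `role` (`"metabolite"` or
#'   `"enzyme_pool"`).
#' @param reactions A list of [reaction()] objects.
#' @param targets Character vector of enzyme-pool ids eligible as drug
#'   targets.
#' @param readout Species id whose cumulative production defines the network
#'   state.
#' @param horizon Simulation horizon in model time units (default 3600, i.e.
#'   one hour at 1-second resolution).
#' @return An object of class `network_model`.
#' @seealso [validate_network()], [simulate_network()], [read_network_model()]
#' @export
network_model <- function(species, reactions, targets, readout,
                          horizon = 3600) {
  species <- as_tibble(species)
  stopifnot(all(c("id", "initial", "role") %in% names(species)))
  species$id <- as.character(species$id)
  species$initial <- as.numeric(species$initial)
  species$role <- as.character(species$role)
  stopifnot(is.list(reactions))
  structure(list(
    species = species,
    reactions = reactions,
    targets = as.character(targets),
    readout = as.character(readout),
    horizon = as.numeric(horizon)
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model> %d species (%d enzyme pools), %d reactions, %d targets\n",
    nrow(x$species), sum(x$species$role == "enzyme_pool"),
    length(x$reactions), length(x$targets)
  ))
  cat(sprintf("  readout: %s   horizon: %g\n", x$readout, x$horizon))
  invisible(x)
}

#' Validate a network model
#'
#' Checks every structural invariant of a model and returns the violations as
#' data, never raising on invalid input: unique non-negative species, strictly
#' positive constants, resolvable substrate/product/enzyme/modifier
#' references, modifiers present exactly where the rate law requires them,
#' resolvable targets and readout, and at least one reaction touching the
#' readout.
#'
#' @param model A [network_model()].
#' @return A tibble with columns `where` (`"species"`, `"reaction"`,
#'   `"model"`), `id` and `message`; zero rows for a valid model.
#' @export
validate_network <- function(model) {
  v <- list()
  note <- function(where, id, message) {
    v[[length(v) + 1]] <<- tibble(where = where, id = id, message = message)
  }
  sp <- model$species
  dup <- sp$id[duplicated(sp$id)]
  for (d in unique(dup)) note("species", d, "duplicated species id")
  for (i in seq_len(nrow(sp))) {
    if (!is.finite(sp$initial[i]) || sp$initial[i] < 0) {
      note("species", sp$id[i], "initial concentration must be >= 0")
    }
    if (!sp$role[i] %in% c("metabolite", "enzyme_pool")) {
      note("species", sp$id[i], sprintf("unknown role '%s'", sp$role[i]))
    }
  }
  ids <- sp$id
  enzyme_ids <- sp$id[sp$role == "enzyme_pool"]
  resolve <- function(ref, rid, what) {
    if (!is.null(ref) && !ref %in% ids) {
      note("reaction", rid, sprintf("%s '%s' is not a declared species", what, ref))
      FALSE
    } else TRUE
  }
  rx_ids <- purrr::map_chr(model$reactions, "id")
  for (d in unique(rx_ids[duplicated(rx_ids)])) {
    note("reaction", d, "duplicated reaction id")
  }
  catalytic <- c("michaelis_menten", "competitive_inhibition", "activation")
  for (rx in model$reactions) {
    kind <- rx$law$law_kind
    resolve(rx$substrate, rx$id, "substrate")
    resolve(rx$product, rx$id, "product")
    resolve(rx$enzyme, rx$id, "enzyme")
    if (is.null(rx$enzyme)) {
      note("reaction", rx$id, "reaction has no enzyme")
    } else if (rx$enzyme %in% ids && !rx$enzyme %in% enzyme_ids) {
      note("reaction", rx$id, sprintf("enzyme '%s' is not an enzyme_pool", rx$enzyme))
    }
    if (kind %in% catalytic && is.null(rx$substrate)) {
      note("reaction", rx$id, sprintf("law '%s' requires a substrate", kind))
    }
    need <- law_modifier[[kind]]
    for (m in need) {
      if (is.null(rx$modifiers[[m]])) {
        note("reaction", rx$id, sprintf("law '%s' requires modifier '%s'", kind, m))
      }
    }
    for (m in names(rx$modifiers)) {
      if (!m %in% need) {
        note("reaction", rx$id, sprintf("modifier '%s' not read by law '%s'", m, kind))
      }
      resolve(rx$modifiers[[m]], rx$id, sprintf("modifier %s", m))
    }
  }
  if (!model$readout %in% ids) {
    note("model", model$readout, "readout is not a declared species")
  } else if (length(model$reactions) > 0) {
    touches <- purrr::some(model$reactions, function(rx) {
      identical(rx$substrate, model$readout) || identical(rx$product, model$readout) ||
        (identical(rx$enzyme, model$readout) &&
           rx$law$law_kind %in% c("irreversible_inactivation", "transcription_upregulation"))
    })
    if (!touches) note("model", model$readout, "no reaction produces or consumes the readout")
  }
  for (tg in model$targets) {
    if (!tg %in% ids) {
      note("model", tg, "target is not a declared species")
    } else if (!tg %in% enzyme_ids) {
      note("model", tg, "target is not an enzyme_pool")
    }
  }
  if (length(v) == 0) {
    tibble(where = character(), id = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

stop_if_invalid <- function(model) {
  viol <- validate_network(model)
  if (nrow(viol) > 0) {
    abort(paste0(
      "invalid network model:\n",
      paste(sprintf("- [%s %s] %s", viol$where, viol$id, viol$message),
            collapse = "\n")
    ), class = "synergyscreen_validation_error")
  }
  invisible(model)
}

#' Read / write a network model file
#'
#' Models are stored as YAML with top-level keys `species` (`id`, `initial`,
#' `role`), `reactions` (`id`, `law_kind`, `substrate`, `product`, `enzyme`,
#' `modifiers`, `constants`), `targets`, `readout` and `horizon_seconds`.
#' The shipped arachidonic-acid model and all generated fixtures use this
#' schema, so tests exercise the same I/O path as user models.
#'
#' @param path File path.
#' @return `read_network_model()` returns a validated [network_model()];
#'   `write_network_model()` returns `path` invisibly.
#' @export
read_network_model <- function(path) {
  doc <- yaml::read_yaml(path)
  model <- model_from_list(doc)
  viol <- validate_network(model)
  if (nrow(viol) > 0) {
    abort(paste0(
      sprintf("model file '%s' failed validation:\n", path),
      paste(sprintf("- [%s %s] %s", viol$where, viol$id, viol$message),
            collapse = "\n")
    ), class = "synergyscreen_load_error")
  }
  model
}

model_from_list <- function(doc) {
  sp <- purrr::map_dfr(doc$species, function(s) {
    tibble(id = as.character(s$id), initial = as.numeric(s$initial),
           role = as.character(s$role))
  })
  rx <- purrr::map(doc$reactions, function(r) {
    mods <- r$modifiers %||% list()
    reaction(
      id = r$id, law_kind = r$law_kind, constants = r$constants,
      substrate = r$substrate, product = r$product, enzyme = r$enzyme,
      inhibitor = mods$inhibitor, activator = mods$activator,
      transcription_signal = mods$transcription_signal
    )
  })
  network_model(sp, rx, targets = unlist(doc$targets),
                readout = doc$readout,
                horizon = doc$horizon_seconds %||% 3600)
}

#' @param model A [network_model()].
#' @rdname read_network_model
#' @export
write_network_model <- function(model, path) {
  doc <- list(
    species = purrr::pmap(model$species, function(id, initial, role) {
      list(id = id, initial = initial, role = role)
    }),
    reactions = purrr::map(model$reactions, function(rx) {
      out <- list(id = rx$id, law_kind = rx$law$law_kind)
      if (!is.null(rx$substrate)) out$substrate <- rx$substrate
      if (!is.null(rx$product)) out$product <- rx$product
      if (!is.null(rx$enzyme)) out$enzyme <- rx$enzyme
      if (length(rx$modifiers) > 0) out$modifiers <- rx$modifiers
      out$constants <- as.list(rx$law$constants)
      out
    }),
    targets = as.list(model$targets),
    readout = model$readout,
    horizon_seconds = model$horizon
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
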