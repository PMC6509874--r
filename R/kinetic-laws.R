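#' Kinetic rate-law families
#'
#' The rate-law vocabulary of the network engine. Five families cover the
#' enzyme chemistry the package models:
#'
#' * `michaelis_menten` — irreversible Michaelis–Menten catalysis,
#'   \eqn{v = K_{cat} [E_t] [S] / (K_m + [S])}.
#' * `competitive_inhibition` — Michaelis–Menten with a competitive reversible
#'   inhibitor \eqn{I}: \eqn{v = K_{cat}[E_t][S] / (K_m (1 + [I]/K_i) + [S])}.
#' * `irreversible_inactivation` — second-order decay of an enzyme pool by an
#'   irreversible inhibitor: \eqn{d[E]/dt = -K [E] [I]}.
#' * `activation` — Michaelis–Menten with an activator \eqn{A} scaling the
#'   turnover: \eqn{v = K_{cat} (1 + [A]/KI) [E_t][S] / (K_m + [S])}.
#' * `transcription_upregulation` — enzyme synthesis driven by a metabolite
#'   signal \eqn{g} through a squared (cooperative) saturation:
#'   \eqn{d[E]/dt = k_{max} [g]^2 / ([g]^2 + k_{half}^2)}.
#'
#' The catalytic families return a flux that the network assembler applies as
#' \eqn{-v} to the substrate and \eqn{+v} to the product; the two enzyme-pool
#' families return the pool's own decay (applied negatively) or synthesis rate
#' (applied positively).
#'
#' @name kinetic-laws
NULL

law_kinds <- c(
  "michaelis_menten", "competitive_inhibition", "irreversible_inactivation",
  "activation", "transcription_upregulation"
)

# exact constant set per law family
law_constants <- list(
  michaelis_menten          = c("K_cat", "K_m"),
  competitive_inhibition    = c("K_cat", "K_m", "K_i"),
  irreversible_inactivation = c("K"),
  activation                = c("K_cat", "K_m", "KI"),
  transcription_upregulation = c("k_max", "k_half")
)

# concentration roles each family reads
law_roles <- list(
  michaelis_menten          = c("S", "E_t"),
  competitive_inhibition    = c("S", "E_t", "I"),
  irreversible_inactivation = c("E", "I"),
  activation                = c("S", "E_t", "A"),
  transcription_upregulation = c("g")
)

# modifier species each family requires on its reaction
law_modifier <- list(
  michaelis_menten          = character(),
  competitive_inhibition    = "inhibitor",
  irreversible_inactivation = "inhibitor",
  activation                = "activator",
  transcription_upregulation = "transcription_signal"
)

#' Construct a kinetic law
#'
#' @param law_kind One of `"michaelis_menten"`, `"competitive_inhibition"`,
#'   `"irreversible_inactivation"`, `"activation"`,
#'   `"transcription_upregulation"`.
#' @param constants Named numeric vector (or list) holding exactly the
#'   constants the family requires (see [kinetic-laws]): `K_cat` and `K_m` for
#'   catalysis, plus `K_i` (competitive inhibition) or `KI` (activation); `K`
#'   for irreversible inactivation; `k_max` and `k_half` for transcriptional
#'   up-regulation. All constants must be strictly positive.
#'
#' @return An object of class `kinetic_law`.
#' @examples
#' kinetic_law("michaelis_menten", c(K_cat = 1, K_m = 0.5))
#' @export
kinetic_law <- function(law_kind, constants) {
  law_kind <- match.arg(law_kind, law_kinds)
  constants <- unlist(constants)
  required <- law_constants[[law_kind]]
  if (!setequal(names(constants), required)) {
    abort(sprintf(
      "law '%s' requires exactly the constants {%s}, got {%s}",
      law_kind, paste(required, collapse = ", "),
      paste(names(constants), collapse = ", ")
    ), class = "synergyscreen_validation_error")
  }
  if (any(!is.finite(constants)) || any(constants <= 0)) {
    abort(sprintf("all constants of law '%s' must be strictly positive", law_kind),
          class = "synergyscreen_validation_error")
  }
  structure(list(law_kind = law_kind, constants = constants[required]),
            class = "kinetic_law")
}

#' Evaluate a kinetic law at a set of concentrations
#'
#' Computes the instantaneous rate of a [kinetic_law()] given concentrations
#' keyed by kinetic role: `S` (substrate), `E_t` (total enzyme), `I`
#' (inhibitor), `A` (activator), `E` (decaying enzyme pool), `g`
#' (transcription signal). Only the roles the family reads need be present.
#'
#' The returned value is a magnitude (always \eqn{\ge 0} for non-negative
#' inputs); the sign with which it enters each species' balance is applied by
#' [assemble_rhs()].
#'
#' @param law A `kinetic_law`.
#' @param concentrations Named numeric vector of role concentrations.
#' @return The reaction velocity (concentration/time), a single number.
#' @examples
#' mm <- kinetic_law("michaelis_menten", c(K_cat = 2, K_m = 1))
#' kinetic_rate(mm, c(S = 1e9, E_t = 3)) # saturation: ~ K_cat * E_t
#' @export
kinetic_rate <- function(law, concentrations) {
  stopifnot(inherits(law, "kinetic_law"))
  roles <- law_roles[[law$law_kind]]
  missing_roles <- setdiff(roles, names(concentrations))
  if (length(missing_roles) > 0) {
    abort(sprintf("law '%s' is missing concentration role(s): %s",
                  law$law_kind, paste(missing_roles, collapse = ", ")),
          class = "synergyscreen_consistency_error")
  }
  cc <- concentrations
  k <- law$constants
  switch(law$law_kind,
    michaelis_menten =
      k[["K_cat"]] * cc[["E_t"]] * cc[["S"]] / (k[["K_m"]] + cc[["S"]]),
    competitive_inhibition =
      k[["K_cat"]] * cc[["E_t"]] * cc[["S"]] /
        (k[["K_m"]] * (1 + cc[["I"]] / k[["K_i"]]) + cc[["S"]]),
    irreversible_inactivation =
      k[["K"]] * cc[["E"]] * cc[["I"]],
    activation =
      k[["K_cat"]] * (1 + cc[["A"]] / k[["KI"]]) * cc[["E_t"]] * cc[["S"]] /
        (k[["K_m"]] + cc[["S"]]),
    transcription_upregulation =
      k[["k_max"]] * cc[["g"]]^2 / (cc[["g"]]^2 + k[["k_half"]]^2)
  )
}
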