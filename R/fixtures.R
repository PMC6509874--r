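#' Linear Michaelis–Menten cascade fixture
#'
#' Builds the chain \eqn{S_0 \to S_1 \to \dots \to S_n}, each step catalysed
#' by its own enzyme pool \eqn{E_k}, with readout \eqn{S_n} and every enzyme
#' a drug target. The dose–effect relationship of each enzyme is monotone by
#' construction, which makes the cascade the reference fixture for the
#' bisection searches.
#'
#' @param n Number of steps (\eqn{\ge 1}).
#' @param k_cat,k_m Kinetic constants, recycled across steps.
#' @param e0 Initial enzyme-pool concentrations, recycled.
#' @param s0 Initial concentration of the head substrate \eqn{S_0}.
#' @param horizon Simulation horizon.
#' @return A valid [network_model()].
#' @export
make_cascade <- function(n, k_cat = 1, k_m = 1, e0 = 1, s0 = 10,
                         horizon = 10) {
  stopifnot(n >= 1)
  k_cat <- rep_len(k_cat, n)
  k_m <- rep_len(k_m, n)
  e0 <- rep_len(e0, n)
  mets <- paste0("S", 0:n)
  enzs <- paste0("E", seq_len(n))
  species <- dplyr::bind_rows(
    tibble(id = mets, initial = c(s0, rep(0, n)), role = "metabolite"),
    tibble(id = enzs, initial = e0, role = "enzyme_pool")
  )
  reactions <- purrr::map(seq_len(n), function(k) {
    reaction(sprintf("r%d", k), "michaelis_menten",
             c(K_cat = k_cat[k], K_m = k_m[k]),
             substrate = mets[k], product = mets[k + 1], enzyme = enzs[k])
  })
  network_model(species, reactions, targets = enzs, readout = mets[n + 1],
                horizon = horizon)
}

#' Additive-pair fixture: exact Loewe additivity by construction
#'
#' Two declared targets, `EP1` and `EP2`, are pools of the *same* catalytic
#' activity acting on one shared substrate, so their fluxes sum and the
#' network dynamics depend on the pool total \eqn{T = EP1 + EP2} only. Any
#' dose split of the pair is therefore dose-equivalent to a single agent and
#' every isobologram point has \eqn{CI = 1} exactly (Loewe
#' self-consistency).
#'
#' To make each pool feasible *alone* in the decrease direction at the 10%
#' criterion, the readout is amplified downstream through two squared
#' transcriptional stages (pool product \eqn{g_1} induces an intermediate
#' enzyme, whose product \eqn{g_2} induces the readout-producing enzyme,
#' both far below half-saturation), so the cumulative output scales as
#' \eqn{T^4}: a tenfold effect drop needs only a
#' \eqn{1 - 0.1^{1/4} \approx 44%} drop of the total pool, i.e. a relative
#' single dose of about 0.88 per target.
#'
#' With unequal pool sizes (`e1 != e2`) the same construction yields a clean
#' mixed-pair scenario: the smaller pool cannot reach the criterion alone
#' (its full knockout leaves the total above the effective level) while the
#' larger one can, and the required joint doses follow the closed form
#' \eqn{T^* = (e_1 + e_2) \theta^{1/4}}.
#'
#' @param e1,e2 Initial concentrations of the two target pools (default 1
#'   and 1).
#' @return A valid [network_model()] with targets `EP1`, `EP2` and readout
#'   `OUT`.
#' @export
make_additive_pair_model <- function(e1 = 1, e2 = 1) {
  species <- dplyr::bind_rows(
    tibble(id = c("SUB_A", "SUB_B", "SUB_C"), initial = 1e6, role = "metabolite"),
    tibble(id = c("G1", "G2", "OUT"), initial = 0, role = "metabolite"),
    tibble(id = c("EP1", "EP2"), initial = c(e1, e2), role = "enzyme_pool"),
    tibble(id = c("EB", "ER"), initial = 0, role = "enzyme_pool")
  )
  reactions <- list(
    reaction("pool1", "michaelis_menten", c(K_cat = 0.1, K_m = 1),
             substrate = "SUB_A", product = "G1", enzyme = "EP1"),
    reaction("pool2", "michaelis_menten", c(K_cat = 0.1, K_m = 1),
             substrate = "SUB_A", product = "G1", enzyme = "EP2"),
    reaction("induce_EB", "transcription_upregulation",
             c(k_max = 50, k_half = 10), enzyme = "EB",
             transcription_signal = "G1"),
    reaction("amplify", "michaelis_menten", c(K_cat = 50, K_m = 1),
             substrate = "SUB_B", product = "G2", enzyme = "EB"),
    reaction("induce_ER", "transcription_upregulation",
             c(k_max = 1000, k_half = 10), enzyme = "ER",
             transcription_signal = "G2"),
    reaction("produce", "michaelis_menten", c(K_cat = 100, K_m = 1),
             substrate = "SUB_C", product = "OUT", enzyme = "ER")
  )
  network_model(species, reactions, targets = c("EP1", "EP2"),
                readout = "OUT", horizon = 1)
}

#' Insensitive-pair fixture: only the joint perturbation works
#'
#' Two saturated, parallel production routes feed the readout, each carrying
#' half the flux. Knocking either enzyme out completely still leaves 50% of
#' baseline output (far above the 10% criterion) and increasing either only
#' raises the output, so no single-target perturbation is feasible; jointly
#' reducing both by 90% meets the criterion with both relative doses
#' \eqn{\le 1}. Raising `theta` above 0.5 makes each target feasible alone.
#'
#' @return A valid [network_model()] with targets `EA`, `EB` and readout
#'   `OUT`.
#' @export
make_insensitive_pair_model <- function() {
  species <- dplyr::bind_rows(
    tibble(id = c("S1", "S2"), initial = 1e6, role = "metabolite"),
    tibble(id = "OUT", initial = 0, role = "metabolite"),
    tibble(id = c("EA", "EB"), initial = 1, role = "enzyme_pool")
  )
  reactions <- list(
    reaction("route_a", "michaelis_menten", c(K_cat = 0.01, K_m = 1),
             substrate = "S1", product = "OUT", enzyme = "EA"),
    reaction("route_b", "michaelis_menten", c(K_cat = 0.01, K_m = 1),
             substrate = "S2", product = "OUT", enzyme = "EB")
  )
  network_model(species, reactions, targets = c("EA", "EB"),
                readout = "OUT", horizon = 10)
}

#' Seeded random reaction-network fixture
#'
#' Generates a random directed acyclic Michaelis–Menten network: metabolites
#' \eqn{M_1, \dots, M_n} where each \eqn{M_k} (\eqn{k \ge 2}) is produced
#' from a uniformly chosen earlier metabolite by its own enzyme, optionally
#' with a competitive inhibitor drawn from the earlier metabolites. The
#' readout is \eqn{M_n} and every enzyme is a target. All randomness flows
#' from `seed` (no global RNG state is touched), so the same arguments
#' always yield an identical model.
#'
#' @param n_species Number of metabolites (\eqn{\ge 2}).
#' @param seed Integer seed.
#' @param p_inhibition Probability that a reaction carries a competitive
#'   inhibitor.
#' @param horizon Simulation horizon.
#' @return A schema-valid [network_model()].
#' @export
random_network <- function(n_species, seed, p_inhibition = 0.3,
                           horizon = 10) {
  stopifnot(n_species >= 2)
  withr::with_seed(as.integer(seed), {
    mets <- paste0("M", seq_len(n_species))
    enzs <- paste0("E", 2:n_species)
    species <- dplyr::bind_rows(
      tibble(id = mets,
             initial = c(stats::runif(1, 5, 50), rep(0, n_species - 1)),
             role = "metabolite"),
      tibble(id = enzs, initial = stats::runif(n_species - 1, 0.5, 2),
             role = "enzyme_pool")
    )
    reactions <- purrr::map(2:n_species, function(k) {
      src <- mets[sample.int(k - 1, 1)]
      use_inh <- stats::runif(1) < p_inhibition && k > 2
      if (use_inh) {
        inh <- mets[sample.int(k - 1, 1)]
        reaction(sprintf("r%d", k), "competitive_inhibition",
                 c(K_cat = stats::runif(1, 0.5, 2),
                   K_m = stats::runif(1, 0.5, 5),
                   K_i = stats::runif(1, 0.5, 5)),
                 substrate = src, product = mets[k],
                 enzyme = enzs[k - 1], inhibitor = inh)
      } else {
        reaction(sprintf("r%d", k), "michaelis_menten",
                 c(K_cat = stats::runif(1, 0.5, 2),
                   K_m = stats::runif(1, 0.5, 5)),
                 substrate = src, product = mets[k], enzyme = enzs[k - 1])
      }
    })
    network_model(species, reactions, targets = enzs,
                  readout = mets[n_species], horizon = horizon)
  })
}
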