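# Shared tiny models and a faster default config for tests.

# Single Michaelis-Menten reaction S -> P catalysed by E.
single_mm_model <- function(k_cat = 1, k_m = 1, e0 = 1, s0 = 10,
                            horizon = 20) {
  network_model(
    species = tibble::tibble(
      id = c("S", "P", "E"), initial = c(s0, 0, e0),
      role = c("metabolite", "metabolite", "enzyme_pool")
    ),
    reactions = list(
      reaction("r1", "michaelis_menten", c(K_cat = k_cat, K_m = k_m),
               substrate = "S", product = "P", enzyme = "E")
    ),
    targets = "E", readout = "P", horizon = horizon
  )
}

# Chain S -> M -> P with separate enzymes and distinct constants.
two_step_model <- function(horizon = 10) {
  network_model(
    species = tibble::tibble(
      id = c("S", "M", "P", "E1", "E2"),
      initial = c(10, 0.5, 0, 1, 0.8),
      role = c("metabolite", "metabolite", "metabolite",
               "enzyme_pool", "enzyme_pool")
    ),
    reactions = list(
      reaction("r1", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "S", product = "M", enzyme = "E1"),
      reaction("r2", "michaelis_menten", c(K_cat = 0.7, K_m = 2),
               substrate = "M", product = "P", enzyme = "E2")
    ),
    targets = c("E1", "E2"), readout = "P", horizon = horizon
  )
}

# Readout is itself consumed: S -> R (E1), R -> W (E2).
consumed_readout_model <- function(horizon = 10) {
  network_model(
    species = tibble::tibble(
      id = c("S", "R", "W", "E1", "E2"),
      initial = c(10, 0, 0, 1, 0.5),
      role = c("metabolite", "metabolite", "metabolite",
               "enzyme_pool", "enzyme_pool")
    ),
    reactions = list(
      reaction("produce", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "S", product = "R", enzyme = "E1"),
      reaction("degrade", "michaelis_menten", c(K_cat = 0.8, K_m = 2),
               substrate = "R", product = "W", enzyme = "E2")
    ),
    targets = c("E1", "E2"), readout = "R", horizon = horizon
  )
}

# Cascade plus a dead-end branch from an independent substrate pool whose
# enzyme EX cannot influence the readout.
parallel_branch_model <- function() {
  network_model(
    species = tibble::tibble(
      id = c("S", "P", "X0", "X1", "E1", "EX"),
      initial = c(10, 0, 10, 0, 1, 1),
      role = c("metabolite", "metabolite", "metabolite", "metabolite",
               "enzyme_pool", "enzyme_pool")
    ),
    reactions = list(
      reaction("main", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "S", product = "P", enzyme = "E1"),
      reaction("branch", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "X0", product = "X1", enzyme = "EX")
    ),
    targets = c("E1", "EX"), readout = "P", horizon = 10
  )
}

# Coarser saved grid for speed; engine tolerances unchanged.
fast_config <- function(...) screen_config(n_save = 51, ...)

# Dense grid-scan oracle for the effective concentration of one target:
# scans `n_grid` concentrations between lo and hi, brackets the threshold
# crossing of the monotone effect curve and linearly interpolates.
grid_scan_dose <- function(model, target, threshold, lo, hi, n_grid = 1000,
                           partner = NULL, config = fast_config()) {
  grid <- seq(lo, hi, length.out = n_grid)
  eff <- vapply(grid, function(conc) {
    pert <- dplyr::bind_rows(partner, perturbation(target, conc))
    cumulative_output(simulate_network(model, pert, config))
  }, numeric(1))
  below <- eff < threshold
  if (!any(below)) return(NA_real_)
  if (all(below)) return(grid[1])
  # index of the crossing between feasible and infeasible neighbours
  flip <- which(below[-1] != below[-n_grid])[1]
  x1 <- grid[flip]; x2 <- grid[flip + 1]
  y1 <- eff[flip]; y2 <- eff[flip + 1]
  x1 + (threshold - y1) * (x2 - x1) / (y2 - y1)
}
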