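test_that("kinetic_law enforces exact constant sets and positivity", {
  expect_s3_class(kinetic_law("michaelis_menten", c(K_cat = 1, K_m = 1)),
                  "kinetic_law")
  expect_error(kinetic_law("michaelis_menten", c(K_cat = 1)),
               class = "synergyscreen_validation_error")
  expect_error(kinetic_law("michaelis_menten", c(K_cat = 1, K_m = 1, K_i = 1)),
               class = "synergyscreen_validation_error")
  expect_error(kinetic_law("michaelis_menten", c(K_cat = 1, K_m = -1)),
               class = "synergyscreen_validation_error")
  expect_error(kinetic_law("activation", c(K_cat = 1, K_m = 1, KI = 0)),
               class = "synergyscreen_validation_error")
})

test_that("rate laws match their limiting and reduction behaviour", {
  mm <- kinetic_law("michaelis_menten", c(K_cat = 2, K_m = 1.5))
  # saturation plateau: [S] -> Inf gives K_cat * E_t
  expect_equal(kinetic_rate(mm, c(S = 1e12, E_t = 3)), 2 * 3,
               tolerance = 1e-9)
  # competitive inhibition with [I] = 0 reduces to plain Michaelis-Menten
  ci <- kinetic_law("competitive_inhibition",
                    c(K_cat = 2, K_m = 1.5, K_i = 0.7))
  for (s in c(0.1, 1, 10)) {
    expect_identical(kinetic_rate(ci, c(S = s, E_t = 3, I = 0)),
                     kinetic_rate(mm, c(S = s, E_t = 3)))
  }
  # activation with [A] = 0 reduces to plain Michaelis-Menten
  act <- kinetic_law("activation", c(K_cat = 2, K_m = 1.5, KI = 0.7))
  expect_identical(kinetic_rate(act, c(S = 1, E_t = 3, A = 0)),
                   kinetic_rate(mm, c(S = 1, E_t = 3)))
  # transcription up-regulation at [g] = k_half sits at half its maximum
  tx <- kinetic_law("transcription_upregulation", c(k_max = 4, k_half = 2.5))
  expect_equal(kinetic_rate(tx, c(g = 2.5)), 4 / 2,
               tolerance = 1e-12)
  # irreversible inactivation is bilinear in enzyme and inhibitor
  inact <- kinetic_law("irreversible_inactivation", c(K = 0.3))
  expect_equal(kinetic_rate(inact, c(E = 2, I = 5)), 0.3 * 2 * 5)
})

test_that("kinetic_rate reports missing concentration roles", {
  mm <- kinetic_law("michaelis_menten", c(K_cat = 1, K_m = 1))
  expect_error(kinetic_rate(mm, c(S = 1)),
               class = "synergyscreen_consistency_error")
})

test_that("rates are non-negative and monotone in their drivers", {
  mm <- kinetic_law("michaelis_menten", c(K_cat = 1, K_m = 2))
  ci <- kinetic_law("competitive_inhibition", c(K_cat = 1, K_m = 2, K_i = 1))
  act <- kinetic_law("activation", c(K_cat = 1, K_m = 2, KI = 1))
  tx <- kinetic_law("transcription_upregulation", c(k_max = 1, k_half = 1))
  s_grid <- c(0, 0.5, 1, 5, 50)
  e_grid <- c(0, 0.5, 1, 2)
  for (s in s_grid) {
    v_e <- vapply(e_grid, function(e) kinetic_rate(mm, c(S = s, E_t = e)),
                  numeric(1))
    expect_true(all(v_e >= 0))
    expect_true(all(diff(v_e) >= 0)) # monotone in enzyme
  }
  v_i <- vapply(c(0, 1, 5, 20), function(i) {
    kinetic_rate(ci, c(S = 1, E_t = 1, I = i))
  }, numeric(1))
  expect_true(all(diff(v_i) <= 0)) # anti-monotone in inhibitor
  v_a <- vapply(c(0, 1, 5, 20), function(a) {
    kinetic_rate(act, c(S = 1, E_t = 1, A = a))
  }, numeric(1))
  expect_true(all(diff(v_a) >= 0)) # monotone in activator
  v_g <- vapply(c(0, 0.5, 1, 4), function(g) kinetic_rate(tx, c(g = g)),
                numeric(1))
  expect_true(all(diff(v_g) >= 0)) # monotone in transcription signal
})

test_that("assemble_rhs applies signed contributions with 1:1 stoichiometry", {
  # zero reactions: identically zero derivative
  empty <- network_model(
    species = tibble::tibble(id = c("A", "B"), initial = c(1, 2),
                             role = "metabolite"),
    reactions = list(), targets = character(), readout = "A", horizon = 1
  )
  expect_equal(assemble_rhs(empty)(c(5, 7)), c(A = 0, B = 0))

  # single reaction: substrate and product balance, enzyme conserved
  m <- single_mm_model()
  rhs <- assemble_rhs(m)
  for (s in c(0.2, 1, 7)) {
    d <- rhs(c(s, 0.3, 1))
    expect_equal(unname(d[["S"]] + d[["P"]]), 0)
    expect_equal(unname(d[["E"]]), 0)
    expect_lt(d[["S"]], 0)
  }

  # two-step chain: d[M]/dt equals v1 - v2 from independent rate calls
  m2 <- two_step_model()
  rhs2 <- assemble_rhs(m2)
  state <- c(S = 4, M = 1.2, P = 0.1, E1 = 1, E2 = 0.8)
  v1 <- kinetic_rate(kinetic_law("michaelis_menten", c(K_cat = 1, K_m = 1)),
                     c(S = 4, E_t = 1))
  v2 <- kinetic_rate(kinetic_law("michaelis_menten", c(K_cat = 0.7, K_m = 2)),
                     c(S = 1.2, E_t = 0.8))
  d <- rhs2(state)
  expect_equal(unname(d[["M"]]), v1 - v2, tolerance = 1e-12)
  expect_equal(unname(d[["S"]]), -v1, tolerance = 1e-12)
  expect_equal(unname(d[["P"]]), v2, tolerance = 1e-12)
})

test_that("enzyme-pool laws act on the pool itself", {
  m <- network_model(
    species = tibble::tibble(
      id = c("S", "P", "E", "I", "G"),
      initial = c(5, 0, 1, 2, 3),
      role = c("metabolite", "metabolite", "enzyme_pool", "metabolite",
               "metabolite")
    ),
    reactions = list(
      reaction("cat", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "S", product = "P", enzyme = "E"),
      reaction("decay", "irreversible_inactivation", c(K = 0.1),
               enzyme = "E", inhibitor = "I"),
      reaction("induce", "transcription_upregulation",
               c(k_max = 2, k_half = 3), enzyme = "E",
               transcription_signal = "G")
    ),
    targets = "E", readout = "P", horizon = 1
  )
  d <- assemble_rhs(m)(c(5, 0, 1, 2, 3))
  # dE/dt = -K*E*I + k_max*g^2/(g^2+k_half^2) = -0.2 + 1
  expect_equal(unname(d[["E"]]), -0.1 * 1 * 2 + 2 * 9 / (9 + 9),
               tolerance = 1e-12)
  expect_equal(unname(d[["I"]]), 0) # inhibitor itself not consumed
})

test_that("validate_network returns violations as data", {
  expect_identical(nrow(validate_network(two_step_model())), 0L)

  bad <- network_model(
    species = tibble::tibble(id = c("S", "P", "E"), initial = c(1, 0, -1),
                             role = c("metabolite", "metabolite", "enzyme_pool")),
    reactions = list(
      reaction("r1", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "X", product = "P", enzyme = "E"),
      reaction("r2", "competitive_inhibition", c(K_cat = 1, K_m = 1, K_i = 1),
               substrate = "S", product = "P", enzyme = "E")
    ),
    targets = c("E", "NOPE"), readout = "P", horizon = 1
  )
  v <- validate_network(bad)
  expect_gt(nrow(v), 0)
  # undeclared substrate named with its reaction
  expect_true(any(v$id == "r1" & grepl("'X'", v$message)))
  # competitive inhibition without an inhibitor modifier
  expect_true(any(v$id == "r2" & grepl("inhibitor", v$message)))
  # negative initial concentration
  expect_true(any(v$where == "species" & v$id == "E"))
  # unresolvable target
  expect_true(any(v$where == "model" & v$id == "NOPE"))
  # readout with no touching reaction
  lonely <- network_model(
    species = tibble::tibble(id = c("S", "P", "Q", "E"),
                             initial = c(1, 0, 0, 1),
                             role = c("metabolite", "metabolite", "metabolite",
                                      "enzyme_pool")),
    reactions = list(reaction("r1", "michaelis_menten",
                              c(K_cat = 1, K_m = 1),
                              substrate = "S", product = "P", enzyme = "E")),
    targets = "E", readout = "Q", horizon = 1
  )
  vq <- validate_network(lonely)
  expect_true(any(vq$id == "Q" & grepl("readout", vq$message)))
})

test_that("model YAML round-trips losslessly", {
  m <- two_step_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_model(m, path)
  m2 <- read_network_model(path)
  expect_equal(m2$species, m$species)
  expect_equal(m2$targets, m$targets)
  expect_equal(m2$readout, m$readout)
  expect_equal(m2$horizon, m$horizon)
  expect_equal(length(m2$reactions), length(m$reactions))
  for (i in seq_along(m$reactions)) {
    expect_equal(m2$reactions[[i]]$law$constants, m$reactions[[i]]$law$constants)
    expect_identical(m2$reactions[[i]]$substrate, m$reactions[[i]]$substrate)
  }
  # a file violating the schema is refused with the violations listed
  bad_doc <- yaml::read_yaml(path)
  bad_doc$readout <- "NOT_THERE"
  bad_path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad_doc, bad_path)
  expect_error(read_network_model(bad_path),
               class = "synergyscreen_load_error")
})
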