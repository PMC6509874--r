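test_that("grading follows the CI bins, left-closed and right-open", {
  tab <- ci_grading_table()
  expect_identical(tab$lower[-1], tab$upper[-nrow(tab)]) # partition of (0, Inf)
  g <- grade_ci(c(0.05, 1.0, 1.45))
  expect_identical(g$description,
                   c("very strong synergism", "nearly additive", "antagonism"))
  expect_identical(g$symbols, c("+ + + + +", "+ -", "- - -"))
  # boundary values fall into the right-hand bin
  expect_identical(grade_ci(0.90)$description, "nearly additive")
  expect_identical(grade_ci(1.10)$description, "slight antagonism")
  expect_identical(grade_ci(10)$description, "very strong antagonism")
  expect_error(grade_ci(0))
})

test_that("dose_for_effect reduces to the single-target search without a partner", {
  m <- make_cascade(2)
  cfg <- fast_config()
  crit <- disease_criterion(m, 0.10, cfg)
  single <- find_effective_dose(m, "E1", crit, cfg)
  combo <- dose_for_effect(m, "E1", NULL, crit, cfg)
  expect_equal(combo$delta_E, single$delta_E, tolerance = 1e-9)
  expect_identical(combo$direction, single$direction)
})

test_that("a partner already at its full effective dose needs zero extra dose", {
  m <- make_cascade(2)
  cfg <- fast_config()
  crit <- disease_criterion(m, 0.10, cfg)
  rec2 <- find_effective_dose(m, "E2", crit, cfg)
  res <- dose_for_effect(m, "E1", perturbation("E2", rec2$E_hi), crit, cfg)
  expect_true(res$feasible)
  expect_identical(res$delta_E, 0)
})

test_that("dose_for_effect with a half-dosed partner matches the grid oracle", {
  m <- make_cascade(2)
  cfg <- fast_config()
  crit <- disease_criterion(m, 0.10, cfg)
  rec1 <- find_effective_dose(m, "E1", crit, cfg)
  half <- rec1$E_di - 0.5 * rec1$delta_E # E1 at half its effective dose
  partner <- perturbation("E1", half)
  res <- dose_for_effect(m, "E2", partner, crit, cfg, direction = "decrease")
  oracle_conc <- grid_scan_dose(m, "E2", crit$threshold, lo = 0, hi = 1,
                                n_grid = 1500, partner = partner, config = cfg)
  expect_equal(res$E_hi, oracle_conc, tolerance = 1e-3)
})

test_that("the additive-pair fixture is Loewe self-consistent (CI = 1 everywhere)", {
  ap <- make_additive_pair_model()
  cfg <- screen_config()
  crit <- disease_criterion(ap, 0.10, cfg)
  iso <- ci_isobologram(ap, c("EP1", "EP2"), crit, cfg)
  expect_identical(nrow(iso$points), 9L)
  expect_true(all(abs(iso$points$ci - 1) <= 2 * cfg$effect_tolerance))
  expect_identical(iso$category, "additive")
  # every isobologram point re-simulated meets the criterion within tolerance
  for (i in seq_len(nrow(iso$points))) {
    pert <- dplyr::bind_rows(perturbation("EP1", iso$points$E_h1[i]),
                             perturbation("EP2", iso$points$E_h2[i]))
    eff <- cumulative_output(simulate_network(ap, pert, cfg))
    expect_lt(eff, crit$threshold)
    expect_lte((crit$threshold - eff) / crit$threshold, cfg$effect_tolerance)
  }
})

test_that("isobolograms are role-symmetric", {
  ap <- make_additive_pair_model()
  cfg <- screen_config()
  crit <- disease_criterion(ap, 0.10, cfg)
  ab <- ci_isobologram(ap, c("EP1", "EP2"), crit, cfg)
  ba <- ci_isobologram(ap, c("EP2", "EP1"), crit, cfg)
  expect_equal(ab$ci_min, ba$ci_min, tolerance = 2 * cfg$effect_tolerance)
  expect_equal(ab$ci_max, ba$ci_max, tolerance = 2 * cfg$effect_tolerance)

  m <- make_cascade(2)
  crit2 <- disease_criterion(m, 0.10, cfg)
  ab2 <- ci_isobologram(m, c("E1", "E2"), crit2, cfg)
  ba2 <- ci_isobologram(m, c("E2", "E1"), crit2, cfg)
  expect_equal(ab2$ci_min, ba2$ci_min, tolerance = 2 * cfg$effect_tolerance)
  expect_equal(ab2$ci_max, ba2$ci_max, tolerance = 2 * cfg$effect_tolerance)
})

test_that("insensitive pairs are screened by joint feasibility", {
  ip <- make_insensitive_pair_model()
  cfg <- fast_config()
  crit <- disease_criterion(ip, 0.10, cfg)
  v <- screen_insensitive_pair(ip, c("EA", "EB"), crit, cfg)
  expect_true(v$synergistic)
  expect_lte(v$ratio_1, 1)
  expect_lte(v$ratio_2, 1)
  # closed form: parallel saturated routes of equal capacity need a joint
  # 90% knockdown to reach 10% of baseline
  expect_equal(v$ratio_1, 0.9, tolerance = 5e-3)
  expect_equal(v$ratio_2, 0.9, tolerance = 5e-3)
  # the found joint point really is normal
  pert <- dplyr::bind_rows(perturbation("EA", v$E_h1),
                           perturbation("EB", v$E_h2))
  expect_true(is_normal(ip, pert, crit, cfg))

  # two targets on disjoint dead-end branches cannot move the readout even
  # jointly
  dead <- network_model(
    species = tibble::tibble(
      id = c("S", "P", "X0", "X1", "Y0", "Y1", "EP", "EX", "EY"),
      initial = c(10, 0, 10, 0, 10, 0, 1, 1, 1),
      role = c(rep("metabolite", 6), rep("enzyme_pool", 3))
    ),
    reactions = list(
      reaction("main", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "S", product = "P", enzyme = "EP"),
      reaction("dead_x", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "X0", product = "X1", enzyme = "EX"),
      reaction("dead_y", "michaelis_menten", c(K_cat = 1, K_m = 1),
               substrate = "Y0", product = "Y1", enzyme = "EY")
    ),
    targets = c("EX", "EY"), readout = "P", horizon = 10
  )
  crit_dead <- disease_criterion(dead, 0.10, cfg)
  v2 <- screen_insensitive_pair(dead, c("EX", "EY"), crit_dead, cfg)
  expect_false(v2$synergistic)
})

test_that("mixed pairs follow the alpha-assisted dose reduction rule", {
  # asymmetric additive pools: EP1 (large) is sensitive, EP2 (small) cannot
  # reach the criterion alone; effect scales as (EP1+EP2)^4, so the joint
  # doses have a closed form
  ap <- make_additive_pair_model(e1 = 1.8, e2 = 0.2)
  cfg <- screen_config()
  crit <- disease_criterion(ap, 0.10, cfg)
  r1 <- find_effective_dose(ap, "EP1", crit, cfg)
  r2 <- find_effective_dose(ap, "EP2", crit, cfg)
  expect_identical(r1$classification, "sensitive")
  expect_identical(r2$classification, "infeasible")

  v <- screen_mixed_pair(ap, "EP1", "EP2", crit, cfg)
  expect_true(v$synergistic)
  # closed form: T* = 2 * 0.1^(1/4); EP2 must cover T0 - alpha*deltaE1 - T*
  t_star <- 2 * 0.1^0.25
  delta1 <- 2 - t_star
  expected_ratio2 <- (2 - 0.8 * delta1 - t_star) / 0.2
  expect_equal(v$insensitive_ratio, expected_ratio2, tolerance = 0.02)
  expect_equal(v$sensitive_ratio_reduced, 0.8 * r1$ratio, tolerance = 1e-9)

  # at a much smaller alpha the small pool cannot cover the remainder
  v_small <- screen_mixed_pair(ap, "EP1", "EP2", crit,
                               screen_config(alpha = 0.35))
  expect_false(v_small$synergistic)

  # monotone in alpha: synergistic at 0.8 stays synergistic at 0.9
  v_big <- screen_mixed_pair(ap, "EP1", "EP2", crit, screen_config(alpha = 0.9))
  expect_true(v_big$synergistic)
  expect_lt(v_big$insensitive_ratio, v$insensitive_ratio)
})

test_that("screen_all composes the three branches and counts synergy", {
  ap <- make_additive_pair_model(e1 = 1.8, e2 = 0.2)
  cfg <- screen_config()
  report <- screen_all(ap, NULL, cfg)
  expect_s3_class(report, "screen_report")
  g <- glance(report)
  expect_identical(g$n_targets, 2L)
  expect_identical(g$n_sensitive, 1L)
  # no sensitive or insensitive pairs exist; one mixed pair, synergistic
  expect_identical(g$synergistic_sensitive, 0L)
  expect_identical(g$synergistic_mixed, 1L)
  expect_identical(g$total_synergistic, 1L)
  # the report equals the individually invoked branch call
  crit <- report$criterion
  v <- screen_mixed_pair(ap, "EP1", "EP2", crit, cfg, singles = report$targets)
  expect_equal(tidy(report)[names(v)], v)

  # insensitive fixture: one insensitive-branch pair, synergistic
  ip <- make_insensitive_pair_model()
  rep2 <- screen_all(ip, NULL, fast_config())
  g2 <- glance(rep2)
  expect_identical(g2$n_sensitive, 0L)
  expect_identical(g2$synergistic_insensitive, 1L)
  expect_identical(g2$total_synergistic, 1L)
})

test_that("single-target models yield empty pair sections", {
  m <- make_cascade(1)
  rep1 <- screen_all(m, NULL, fast_config())
  expect_identical(nrow(tidy(rep1)), 0L)
  expect_identical(rep1$total_synergistic, 0L)
})

test_that("verdict and isobologram tidiers expose the expected columns", {
  ap <- make_additive_pair_model()
  cfg <- screen_config()
  crit <- disease_criterion(ap, 0.10, cfg)
  iso <- ci_isobologram(ap, c("EP1", "EP2"), crit, cfg)
  expect_true(all(c("f1", "f2", "ci") %in% names(tidy(iso))))
  gl <- glance(iso)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$ci_min <= gl$representative_ci &&
              gl$representative_ci <= gl$ci_max)
  p <- autoplot(iso)
  expect_s3_class(p, "ggplot")
})
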