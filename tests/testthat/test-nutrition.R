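test_that("literature demands convert to mmol/gDW/h as printed", {
  out <- literature_to_mmol(essential_aa_demands)
  got <- setNames(round(out$literature_mmol, 4), out$nutrient)
  expect_equal(got[["arginine"]], 0.2078)
  expect_equal(got[["lysine"]], 0.1601)
  expect_equal(got[["valine"]], 0.1284)
  min_out <- literature_to_mmol(mineral_demands)
  got_min <- setNames(min_out$literature_mmol, min_out$nutrient)
  expect_equal(round(got_min[["calcium"]], 4), 0.2897)    # via CaCO3 carrier
  expect_equal(round(got_min[["zinc"]], 4), 3e-04)        # elemental, mg/kg
  expect_error(literature_to_mmol(
    tibble::tibble(nutrient = "x", value = 1, unit = "furlongs",
                   carrier_molar_mass = 10)), "unknown demand unit")
})

test_that("unit conversion is linear in value and inverse in molar mass", {
  base <- tibble::tibble(nutrient = "n", value = 2, unit = "percent_of_feed",
                         carrier_molar_mass = 100)
  v1 <- literature_to_mmol(base)$literature_mmol
  v2 <- literature_to_mmol(mutate(base, value = 6))$literature_mmol
  v3 <- literature_to_mmol(mutate(base, carrier_molar_mass = 300))$literature_mmol
  expect_equal(v2, 3 * v1)
  expect_equal(v3, v1 / 3)
  # g/kg and mg/kg consistency: 1 g/kg == 1000 mg/kg
  g <- literature_to_mmol(mutate(base, value = 1, unit = "g_per_kg"))
  mg <- literature_to_mmol(mutate(base, value = 1000, unit = "mg_per_kg"))
  expect_equal(g$literature_mmol, mg$literature_mmol)
})

test_that("deposition rates reproduce the integer-percent convention", {
  expect_equal(round(100 * deposition_rate(0.0664, 0.1601)), 41)
  expect_equal(round(100 * deposition_rate(0.0071, 0.0089)), 80)
  expect_equal(deposition_rate(0.5, 0.5), 1)
  expect_true(is.na(deposition_rate(5, 0)))   # undefined literature demand
})

test_that("simulated requirements equal biomass coefficients on toys", {
  g <- make_toy_gem(synthetic_spec(seed = 6, n_essential_nutrients = 3))
  req <- simulate_requirements(g$model, biomass_rate = 1)
  truth <- g$truth$requirements
  for (i in seq_len(nrow(truth))) {
    got <- req$simulated_mmol[req$exchange == truth$exchange[i]]
    expect_equal(got, truth$requirement[i], tolerance = 1e-6,
                 info = truth$nutrient[i])
  }
  # requirement scales with the fixed biomass rate
  req2 <- simulate_requirements(g$model, biomass_rate = 2)
  ess1 <- truth$exchange[truth$class == "essential"][1]
  expect_equal(req2$simulated_mmol[req2$exchange == ess1],
               2 * req$simulated_mmol[req$exchange == ess1],
               tolerance = 1e-6)
})

test_that("synthesizable nutrients with closed import need no uptake", {
  g <- make_toy_gem(synthetic_spec(seed = 6, n_synthesizable_nutrients = 2))
  req <- simulate_requirements(g$model)
  syn <- req[grepl("^EX_syn", req$exchange), ]
  expect_true(all(abs(syn$simulated_mmol) < 1e-8))
})

test_that("net exporters are reported negative and flagged as accumulation", {
  # the required precursor q is coupled to a byproduct p made in excess
  m <- gem(reactions = reaction_tbl(
    c("EX_a", "T_a", "SRC", "T_p", "EX_p", "BM", "DM_b"),
    c("a[e] <=> ", "a[e] <=> a[c]", "a[c] => q[c] + 3 p[c]",
      "p[c] => p[e]", "p[e] => ", "q[c] + p[c] => biomass[c]",
      "biomass[c] => "),
    lower_bound = c(-5, -1000, 0, 0, 0, 0, 0),
    kind = c(NA, NA, NA, NA, NA, "biomass", "demand")), objective = "BM")
  req <- simulate_requirements(m, biomass_rate = 1)
  p_row <- req[req$exchange == "EX_p", ]
  expect_lt(p_row$simulated_mmol, 0)
  expect_true(p_row$accumulation)
})

test_that("specific growth rate formulas match the printed worked range", {
  out <- sgr(0.1203)
  expect_equal(round(out$sgr_max, 2), 1.24)
  expect_equal(out$sgr_min, 0.75, tolerance = 0.011)
  expect_equal(sgr(0)$sgr_min, 0)
  expect_equal(sgr(0)$sgr_max, 0)
})

test_that("sgr is increasing, concave, and ordered", {
  x <- c(0.05, 0.1, 0.2, 0.4)
  out <- sgr(x)
  expect_true(all(diff(out$sgr_min) > 0))
  expect_true(all(out$sgr_min <= out$sgr_max))
  # doubling x less than doubles SGR (concavity of log)
  expect_lt(sgr(0.2)$sgr_max, 2 * sgr(0.1)$sgr_max)
})

test_that("growth under a literature feed is Liebig-limited", {
  g <- make_toy_gem(synthetic_spec(seed = 9, n_essential_nutrients = 2,
                                   n_synthesizable_nutrients = 0,
                                   maintenance_atp = 0))
  truth <- g$truth$requirements
  ess <- truth[truth$class == "essential", ]
  demands <- tibble::tibble(
    nutrient = ess$nutrient,
    value = c(0.5, 100),            # first nutrient is strongly limiting
    unit = "g_per_kg",
    carrier_molar_mass = c(1, 1),
    exchange = ess$exchange)
  res <- growth_under_feed(g$model, demands)
  supply <- literature_to_mmol(demands)$literature_mmol
  expect_equal(res$rate, min(supply / ess$requirement), tolerance = 1e-6)
  # doubling the limiting supply doubles growth (still below the other cap)
  demands2 <- mutate(demands, value = c(1, 100))
  expect_equal(growth_under_feed(g$model, demands2)$rate, 2 * res$rate,
               tolerance = 1e-6)
  # ample supplies: growth rises until the transport capacity (1000)
  # becomes the binding constraint
  demands3 <- mutate(demands, value = c(1e5, 1e5))
  expect_equal(growth_under_feed(g$model, demands3)$rate,
               min(1000 / ess$requirement), tolerance = 1e-6)
  # absorbed never exceeds offered
  expect_true(all(res$uptake$unabsorbed >= -1e-8))
})
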