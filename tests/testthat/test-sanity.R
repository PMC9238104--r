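test_that("a mass-balanced toy has no leaks", {
  g <- make_toy_gem(synthetic_spec(seed = 1))
  expect_true(leak_test_closed(g$model)$passed)
  expect_true(leak_test_demands(g$model)$passed)
})

test_that("the polymer pair leaks glucose and closing it heals the model", {
  m <- polymer_leak_gem()
  leak <- leak_test_closed(m)
  expect_false(leak$passed)
  expect_true("glc[e]" %in% leak$witnesses[[1]]$metabolite)
  # demand-level leaks are also present (internal water generation)
  expect_false(leak_test_demands(m)$passed)
  # closing the implicated pair removes every leak
  healed <- gem_set_bounds(m, c("R02110", "R02109"), lb = 0, ub = 0)
  expect_true(leak_test_closed(healed)$passed)
})

test_that("energy and matter checks behave on the glycolysis core", {
  g <- make_toy_gem(synthetic_spec(seed = 2))
  res <- energy_matter_checks(g$model)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$passed, na.rm = TRUE))
  # fermentative core yields exactly 2 ATP per glucose: under the cap,
  # and a positive witness flux
  yield <- res$witnesses[[which(res$name == "atp_yield_from_glucose")]]
  expect_equal(yield$flux, 2, tolerance = 1e-8)
  expect_error(energy_matter_checks(g$model, roles = list(water = "h2o[c]")),
               "missing role")
})

test_that("a planted water-splitting energy cycle fails the water check", {
  g <- make_toy_gem(synthetic_spec(seed = 3))
  # bogus: water alone regenerates ATP from ADP + Pi
  bogus <- gem_add_reactions(g$model, reaction_tbl(
    "BOGUS", "adp[c] + pi[c] + h2o[c] => atp[c] + 2 h2o[c]"))
  res <- energy_matter_checks(bogus)
  expect_false(res$passed[res$name == "energy_from_water"])
})

test_that("checks whose role metabolites are absent are skipped with notice", {
  m <- chain_gem()
  res <- energy_matter_checks(m)
  expect_true(all(is.na(res$passed)))
  expect_match(res$note[1], "skipped")
})

test_that("structural checks catch clones, empty columns and bad demands", {
  m <- gem(reactions = reaction_tbl(
    c("R1", "CLONE", "DM"),
    c("a[c] => b[c]", "a[c] => b[c]", "b[c] => "),
    kind = c(NA, NA, "demand")))
  res <- structural_checks(m)
  expect_false(res$passed[res$name == "duplicated_reactions"])
  expect_setequal(res$witnesses[[1]]$id, c("R1", "CLONE"))
  expect_true(res$passed[res$name == "empty_columns"])
  expect_true(res$passed[res$name == "demand_bounds"])

  m2 <- gem_set_bounds(m, "DM", lb = -1)
  res2 <- structural_checks(m2)
  expect_false(res2$passed[res2$name == "demand_bounds"])

  m3 <- gem(metabolite_tbl("a[c]"),
            tibble::add_row(reaction_tbl("R1", "a[c] => "),
                            id = "EMPTY", name = "EMPTY",
                            stoichiometry = list(setNames(numeric(0),
                                                          character(0))),
                            lower_bound = 0, upper_bound = 0,
                            reversible = FALSE,
                            genes = list(character(0)),
                            ko_ids = list(character(0))))
  res3 <- structural_checks(m3)
  expect_false(res3$passed[res3$name == "empty_columns"])
})

test_that("the full suite returns ten checks in fixed order", {
  g <- make_toy_gem(synthetic_spec(seed = 5))
  rep <- sanity_suite(g$model)
  expect_equal(nrow(rep), 10L)
  expect_equal(rep$name, c(
    "leak_closed", "leak_demands", "energy_from_water",
    "matter_from_reversed_atp_demand", "proton_demand_closed",
    "atp_yield_from_glucose", "duplicated_reactions", "empty_columns",
    "demand_bounds", "single_gene_deletion_runs"))
  expect_true(all(rep$passed, na.rm = TRUE))
  expect_equal(sum(is.na(rep$passed)), 0L)
  # deterministic: rerun gives identical report
  rep2 <- sanity_suite(g$model)
  expect_identical(tidy(rep), tidy(rep2))
})

test_that("a model without genes skips the deletion smoke test", {
  rep <- sanity_suite(chain_gem())
  expect_true(is.na(rep$passed[rep$name == "single_gene_deletion_runs"]))
})

test_that("balanced generated models never fail the conservation checks", {
  for (s in c(4, 8, 15)) {
    g <- make_toy_gem(synthetic_spec(seed = s,
                                     n_essential_nutrients = 1 + s %% 3,
                                     maintenance_atp = 2))
    rep <- sanity_suite(g$model)
    expect_true(all(rep$passed, na.rm = TRUE), info = paste("seed", s))
  }
  # with the polymer motif the closed-model leak test must fail
  gl <- make_toy_gem(synthetic_spec(seed = 4, include_polymer_leak = TRUE))
  repl <- sanity_suite(gl$model)
  expect_false(repl$passed[repl$name == "leak_closed"])
})
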