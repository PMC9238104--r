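test_that("fba solves the hand-checkable uptake chain", {
  m <- chain_gem(uptake = 5)
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  # all exchanges closed in a mass-balanced toy: optimum 0
  closed <- m
  closed$reactions$lower_bound[closed$reactions$kind == "exchange"] <- 0
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)
})

test_that("infeasible bound combinations are reported, not silently zeroed", {
  m <- gem(reactions = reaction_tbl(
    c("R1", "R2"), c("a[c] => b[c]", "b[c] => a[c]"),
    lower_bound = c(1, 0), upper_bound = c(1000, 0)))
  expect_equal(fba(m, "R1")$status, "infeasible")
  expect_true(is.na(fba(m, "R1")$objective_value))
})

test_that("optimal solutions satisfy steady state and bounds", {
  for (s in 1:5) {
    g <- make_toy_gem(synthetic_spec(seed = s, n_essential_nutrients = 3))
    sol <- fba(g$model)
    expect_equal(sol$status, "optimal")
    S <- stoichiometric_matrix(g$model)
    expect_lt(max(abs(S %*% sol$fluxes$flux)), 1e-6)
    expect_true(all(sol$fluxes$flux >= g$model$reactions$lower_bound - 1e-9))
    expect_true(all(sol$fluxes$flux <= g$model$reactions$upper_bound + 1e-9))
  }
})

test_that("objective value is invariant to reaction and metabolite order", {
  g <- make_toy_gem(synthetic_spec(seed = 7))
  ref <- fba(g$model)$objective_value
  perm <- g$model
  set.seed(1)
  perm$reactions <- perm$reactions[sample(nrow(perm$reactions)), ]
  perm$metabolites <- perm$metabolites[sample(nrow(perm$metabolites)), ]
  expect_equal(fba(perm)$objective_value, ref, tolerance = 1e-9)
})

test_that("fba agrees with an independent LP implementation", {
  checked <- 0
  for (s in 1:20) {
    g <- make_toy_gem(synthetic_spec(
      seed = s, n_essential_nutrients = 1 + s %% 3,
      n_synthesizable_nutrients = s %% 2, maintenance_atp = 2 * (s %% 2)))
    mine <- fba(g$model)$objective_value
    # closed-form optimum from the generator: always checked
    expect_equal(mine, g$truth$biomass_optimum, tolerance = 1e-6)
    oracle <- pracma_fba_oracle(g$model, "BIOMASS")
    if (!is.null(oracle)) {
      checked <- checked + 1
      expect_equal(mine, oracle, tolerance = 1e-6)
    }
  }
  expect_gte(checked, 10)  # the oracle converges on most instances
})

test_that("bound policies assign class bounds with override priority", {
  g <- make_toy_gem(synthetic_spec(seed = 3))
  m <- g$model
  pol <- bounds_policy(overrides = list(GLYC = c(0, 7)))
  classes <- c("glc[e]" = "trace", "ess1[e]" = "semi_essential")
  m2 <- apply_policy(m, pol, classes)
  rx <- m2$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_glc"], -1)       # trace
  expect_equal(rx$lower_bound[rx$id == "EX_ess1"], -3)      # semi-essential
  expect_equal(rx$upper_bound[rx$id == "GLYC"], 7)          # override wins
  # internal reversible reaction gets (-1000, 1000)
  expect_equal(rx$lower_bound[rx$id == "WATER_DISS"], -1000)
  expect_error(apply_policy(m, pol, c("glc[e]" = "mystery")), "mystery")
})

test_that("single-gene deletion disables only fully-deleted reactions", {
  m <- gem(reactions = reaction_tbl(
    c("EX_a", "T1", "T2", "BM"),
    c("a[e] <=> ", "a[e] => a[c]", "a[e] => a[c]", "a[c] => "),
    lower_bound = c(-5, 0, 0, 0),
    genes = list(character(0), "g1", "g2", "g3"),
    kind = c(NA, NA, NA, "biomass")), objective = "BM")
  res <- single_gene_deletion(m)
  expect_equal(nrow(res), 3L)
  vals <- setNames(res$objective_value, res$gene)
  expect_equal(vals[["g1"]], 5)   # parallel path survives
  expect_equal(vals[["g2"]], 5)
  expect_equal(vals[["g3"]], 0)   # sole biomass route
  # a multi-gene reaction survives single deletions
  m2 <- m
  m2$reactions$genes[[4]] <- c("g3", "g4")
  res2 <- single_gene_deletion(m2)
  expect_true(all(res2$objective_value == 5))
})

test_that("flux comparison finds proportional changes along the active chain", {
  m <- chain_gem(uptake = 10)
  # a dead-end side branch that never carries flux
  m <- gem_add_reactions(m, reaction_tbl("DEAD", "z1[c] => z2[c]"))
  fc <- flux_compare(m, "BM", rate_low = 1, rate_high = 2)
  expect_setequal(fc$changed$id, c("EX_a", "T_a", "BM"))
  expect_equal(fc$changed$delta, rep(1, 3), tolerance = 1e-8)
  expect_false("DEAD" %in% fc$changed$id)
  # sorted by delta descending
  expect_true(all(diff(fc$changed$delta) <= 1e-12))
  expect_error(flux_compare(m, "BM", 1, 1e6), "rate_high")
})

test_that("flux comparison matches a brute-force pair of parsimonious solutions", {
  # branched network: two routes to biomass with different lengths; the
  # parsimonious solution uses the short one
  m <- gem(reactions = reaction_tbl(
    c("EX_a", "T_a", "SHORT", "LONG1", "LONG2", "BM"),
    c("a[e] <=> ", "a[e] <=> a[c]", "a[c] => p[c]",
      "a[c] => q[c]", "q[c] => p[c]", "p[c] => "),
    lower_bound = c(-10, -1000, 0, 0, 0, 0),
    kind = c(NA, NA, NA, NA, NA, "biomass")), objective = "BM")
  fc <- flux_compare(m, "BM", 1, 2)
  lo <- pfba(m, "BM", 1)
  hi <- pfba(m, "BM", 2)
  manual <- abs(hi$fluxes$flux - lo$fluxes$flux)
  expect_setequal(fc$changed$id,
                  m$reactions$id[manual > 1e-6])
  # the long route stays off in both parsimonious solutions
  expect_equal(lo$fluxes$flux[lo$fluxes$id == "LONG1"], 0, tolerance = 1e-9)
})
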