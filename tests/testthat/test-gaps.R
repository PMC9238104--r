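test_that("connectivity counts weakly connected components over metabolites", {
  m <- gem(reactions = reaction_tbl(c("R1", "R2"),
                                    c("a[c] => b[c]", "c0[c] => d[c]")))
  rep1 <- connectivity(m)
  expect_equal(rep1$n_wcc, 2L)
  # adding a bridging reaction merges the components
  m2 <- gem_add_reactions(m, reaction_tbl("R3", "b[c] => c0[c]"))
  expect_equal(connectivity(m2)$n_wcc, 1L)
  # components partition the metabolite set
  expect_setequal(unlist(rep1$components), m$metabolites$id)
})

test_that("generated islands are recovered as extra components", {
  g <- make_toy_gem(synthetic_spec(seed = 7, n_islands = 3))
  expect_equal(connectivity(g$model)$n_wcc, g$truth$n_wcc)
  expect_equal(g$truth$n_wcc, 4L)
})

test_that("flux-based producibility honours uptake bounds", {
  # metabolite with no producing reaction
  m <- gem(reactions = reaction_tbl("R1", "a[c] => b[c]"))
  p <- is_producible(m, "a[c]")
  expect_false(p$producible)
  expect_equal(p$max_flux, 0, tolerance = 1e-9)
  # uptake-limited drain: EX lb -5 bounds the maximum
  chain <- chain_gem(uptake = 5)
  p2 <- is_producible(chain, "a[c]")
  expect_true(p2$producible)
  expect_equal(p2$max_flux, 5, tolerance = 1e-8)
})

test_that("repaired sulfur fixture yields the expected cysteine flux", {
  m <- sulfur_gem(repaired = TRUE, cys_import = TRUE)
  p <- is_producible(m, "cys[c]")
  # 5 from the sulfate route plus 3 from the semi-essential import
  expect_equal(p$max_flux, 8, tolerance = 1e-8)
  # without the repair reactions only the import remains
  p2 <- is_producible(sulfur_gem(repaired = FALSE), "cys[c]")
  expect_equal(p2$max_flux, 3, tolerance = 1e-8)
})

test_that("breakpoint backtracking locates the orphaned precursor", {
  # linear chain with a missing source
  m <- gem(reactions = reaction_tbl(c("R1", "R2"),
                                    c("a[c] => b[c]", "b[c] => c0[c]")))
  bp <- find_breakpoints(m, "c0[c]")
  expect_true(any(bp$metabolite == "a[c]" & bp$reason == "orphan"))
  # sulfur route with the sulfite-producing step deleted
  m2 <- sulfur_gem(repaired = TRUE, cys_import = FALSE)
  m2 <- gem_drop_reactions(m2, "APS_RED")
  bp2 <- find_breakpoints(m2, "cys[c]")
  expect_true(any(bp2$metabolite == "so3[c]" & bp2$reason == "orphan"))
  # producible target: empty result with a notice
  expect_message(bp3 <- find_breakpoints(chain_gem(), "a[c]"),
                 "producible")
  expect_equal(nrow(bp3), 0L)
})

test_that("gapfill recovers planted gaps exactly", {
  g <- make_toy_gem(synthetic_spec(seed = 11, n_essential_nutrients = 2))
  planted <- plant_gaps(g, n = 1, seed = 3)
  expect_equal(fba(planted$model)$objective_value, 0, tolerance = 1e-9)
  res <- gapfill(planted$model, planted$pool, planted$targets,
                 scale = "pathway")
  expect_setequal(res$added_reactions, planted$removed)
  expect_equal(length(res$unrestored), 0L)
  expect_gt(fba(res$model)$objective_value, 0)
})

test_that("double gaps on disjoint routes are recovered at pathway scale", {
  g <- make_toy_gem(synthetic_spec(seed = 13, n_essential_nutrients = 3))
  planted <- plant_gaps(g, n = 2, seed = 5)
  res <- gapfill(planted$model, planted$pool, planted$targets,
                 scale = "pathway")
  expect_setequal(res$added_reactions, planted$removed)
  expect_equal(fba(res$model)$objective_value, g$truth$biomass_optimum,
               tolerance = 1e-6)
})

test_that("a two-step gap on one route needs set size two", {
  m <- gem(reactions = reaction_tbl(
    c("EX_a", "T_a", "S1", "S2", "S3"),
    c("a[e] <=> ", "a[e] <=> a[c]", "a[c] => b[c]", "b[c] => c0[c]",
      "c0[c] => d[c]"),
    lower_bound = c(-5, -1000, 0, 0, 0), pathway = "chain"))
  pool <- as_pool(tibble::tibble(
    reaction_id = c("S2", "S3"),
    equation = c("b[c] => c0[c]", "c0[c] => d[c]"),
    pathway = "chain", subsystem = NA))
  gapped <- gem_drop_reactions(m, c("S2", "S3"))
  res <- gapfill(gapped, pool, "d[c]", scale = "global")
  expect_setequal(res$added_reactions, c("S2", "S3"))
})

test_that("unrestorable targets are reported, not thrown", {
  m <- gem(reactions = reaction_tbl("R1", "a[c] => b[c]"))
  pool <- as_pool(tibble::tibble(reaction_id = "X1",
                                 equation = "p[c] => q[c]",
                                 pathway = NA, subsystem = NA))
  res <- gapfill(m, pool, "a[c]", scale = "global")
  expect_equal(res$unrestored, "a[c]")
  expect_equal(length(res$added_reactions), 0L)
})

test_that("gap filling never increases the number of components", {
  for (s in c(2, 9, 21)) {
    g <- make_toy_gem(synthetic_spec(seed = s, n_essential_nutrients = 2,
                                     n_islands = s %% 2))
    planted <- plant_gaps(g, n = 1, seed = s)
    before <- connectivity(planted$model)$n_wcc
    res <- gapfill(planted$model, planted$pool, planted$targets,
                   scale = "pathway")
    expect_lte(connectivity(res$model)$n_wcc, before)
  }
})

test_that("every added reaction is necessary (ablation)", {
  g <- make_toy_gem(synthetic_spec(seed = 17, n_essential_nutrients = 3))
  planted <- plant_gaps(g, n = 2, seed = 2)
  res <- gapfill(planted$model, planted$pool, planted$targets,
                 scale = "pathway")
  for (id in res$added_reactions) {
    ablated <- gem_drop_reactions(res$model, id)
    still <- producibility(ablated, planted$targets)
    expect_false(all(still$producible))
  }
})

test_that("LP producibility agrees with graph reachability on unit networks", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 6
    ids <- paste0("m", 1:n, "[c]")
    rxns <- reaction_tbl(
      c("EX_s", "T_s", paste0("R", 1:6)),
      c("s[e] <=> ", "s[e] => m1[c]",
        replicate(6, paste0(sample(ids, 1), " => ", sample(ids, 1)))),
      lower_bound = c(-5, 0, rep(0, 6)))
    ok <- !map_lgl(rxns$stoichiometry, function(st) length(st) < 2)
    rxns <- rxns[ok | rxns$id %in% c("EX_s", "T_s"), ]
    m <- gem(reactions = rxns)
    for (target in intersect(ids, m$metabolites$id)) {
      lp <- is_producible(m, target)$producible
      expect_equal(lp, reachability_oracle(m, target),
                   info = paste("rep", rep, "target", target))
    }
  }
})
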