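toy_pool <- function() {
  as_pool(tibble::tibble(
    reaction_id = paste0("R", 1:4),
    equation = c("a[c] => b[c]", "b[c] => c0[c]", "c0[c] => d[c]",
                 "d[c] => a[c]"),
    ko_ids = c("K00001", "K00002", "K00003", "K00004"),
    pathway = "toy", subsystem = "toy"))
}

test_that("draft reconstruction keeps exactly the KO-matched reactions", {
  ko <- tibble::tibble(unigene_id = c("u1", "u2", "u3"),
                       ko_id = c("K00001", "K00003", "K00003"))
  draft <- build_draft(ko, toy_pool())
  expect_setequal(draft$reactions$id, c("R1", "R3"))
  genes <- setNames(draft$reactions$genes, draft$reactions$id)
  expect_equal(genes[["R1"]], "u1")
  expect_setequal(genes[["R3"]], c("u2", "u3"))
  expect_true(all(draft$metabolites$compartment == "c"))

  # KO absent from pool: empty draft with warning
  expect_warning(
    empty <- build_draft(tibble::tibble(unigene_id = "u9", ko_id = "K99999"),
                         toy_pool()),
    "empty draft")
  expect_equal(nrow(empty$reactions), 0L)
})

test_that("draft reconstruction is monotone in the KO table", {
  pool <- toy_pool()
  ko1 <- tibble::tibble(unigene_id = "u1", ko_id = "K00002")
  ko2 <- bind_rows(ko1, tibble::tibble(unigene_id = c("u2", "u3"),
                                       ko_id = c("K00001", "K00004")))
  d1 <- build_draft(ko1, pool)
  d2 <- build_draft(ko2, pool)
  expect_true(all(d1$reactions$id %in% d2$reactions$id))
})

test_that("draft from a generated KO table reproduces the covered subset", {
  g <- make_toy_gem(synthetic_spec(seed = 1))
  pool <- gem_to_pool(g$model)
  ko <- make_ko_table(g$model, dropout = 0.3, seed = 5)
  draft <- build_draft(ko, pool)
  expect_setequal(draft$reactions$id, attr(ko, "covered"))
  # planted gene lists come back exactly
  for (id in draft$reactions$id) {
    expect_setequal(draft$reactions$genes[[match(id, draft$reactions$id)]],
                    g$model$reactions$genes[[match(id, g$model$reactions$id)]])
  }
  # dropout 0 covers every KO-bearing metabolic reaction
  full <- build_draft(make_ko_table(g$model, dropout = 0), pool)
  expect_setequal(full$reactions$id, pool$reaction_id)
})

test_that("element balance checking counts atoms and flags polymers", {
  m <- gem(metabolite_tbl(c("glc[c]", "lac[c]", "poly[c]"),
                          formula = c("C6H12O6", "C3H6O3", "UNKNOWN")),
           reaction_tbl(c("SPLIT", "BAD", "POLY"),
                        c("glc[c] => 2 lac[c]", "glc[c] => lac[c]",
                          "glc[c] => poly[c]")))
  rep <- check_balance(m)
  verdicts <- setNames(rep$verdict, rep$id)
  expect_equal(verdicts[["SPLIT"]], "balanced")
  expect_equal(verdicts[["BAD"]], "unbalanced")
  expect_equal(rep$deltas[[which(rep$id == "BAD")]],
               c(C = -3, H = -6, O = -3))
  expect_equal(verdicts[["POLY"]], "unknown")
})

test_that("redundancy pruning removes lumped, duplicate and flagged reactions", {
  m <- gem(reactions = reaction_tbl(
    c("STEP1", "STEP2", "LUMP", "DUP"),
    c("a[c] => b[c]", "b[c] => c0[c]", "a[c] => c0[c]", "b[c] => c0[c]")))
  out <- prune_redundant(m)
  # duplicates keep the lexicographically smallest id (DUP < STEP2)
  expect_setequal(out$removed$id, c("LUMP", "STEP2"))
  expect_setequal(out$model$reactions$id, c("STEP1", "DUP"))

  # flagged pool entries
  m2 <- gem(reactions = reaction_tbl(c("R1", "G1"),
                                     c("a[c] => b[c]", "x[c] => y[c]")))
  pool <- as_pool(tibble::tibble(reaction_id = "G1", equation = "x[c] => y[c]",
                                 flags = "general"))
  out2 <- prune_redundant(m2, pool)
  expect_equal(out2$removed$id, "G1")

  # no redundancy: identity
  out3 <- prune_redundant(out$model)
  expect_equal(nrow(out3$removed), 0L)
  expect_equal(out3$model$reactions$id, out$model$reactions$id)
})

test_that("pruning preserves producibility of producible metabolites", {
  rxns <- reaction_tbl(
    c("EX_a", "T_a", "STEP1", "STEP2", "LUMP"),
    c("a[e] <=> ", "a[e] <=> a[c]", "a[c] => b[c]", "b[c] => c0[c]",
      "a[c] => c0[c]"),
    lower_bound = c(-5, -1000, 0, 0, 0))
  m <- gem(reactions = rxns)
  before <- producibility(m, c("b[c]", "c0[c]"))
  out <- prune_redundant(m)
  after <- producibility(out$model, c("b[c]", "c0[c]"))
  expect_true(all(after$producible[before$producible]))
})

test_that("chirality standardization merges aliases and prunes duplicates", {
  m <- gem(reactions = reaction_tbl(
    c("R1", "R2"),
    c("dglc[c] => f6p[c]", "glc[c] => f6p[c]")))
  out <- standardize_chirality(m, c("dglc[c]" = "glc[c]"))
  expect_equal(nrow(out$model$reactions), 1L)
  expect_false("dglc[c]" %in% out$model$metabolites$id)
  expect_equal(out$removed$reason, "duplicate")
})

test_that("transfer reactions add one exchange and one transport per nutrient", {
  m <- gem(reactions = reaction_tbl("SRC", "x[c] => nut1[c]"))
  m2 <- add_transfer_reactions(
    m, tibble::tibble(metabolite = "nut1[c]", importable = TRUE))
  expect_equal(nrow(m2$reactions) - nrow(m$reactions), 2L)
  expect_equal(nrow(m2$metabolites) - nrow(m$metabolites), 1L)
  expect_equal(m2$reactions$kind[m2$reactions$id == "EX_nut1"], "exchange")
  expect_equal(m2$reactions$kind[m2$reactions$id == "T_nut1"], "transport")

  # non-importable: irreversible outward
  m3 <- add_transfer_reactions(
    m, tibble::tibble(metabolite = "nut1[c]", importable = FALSE))
  ex <- m3$reactions[m3$reactions$id == "EX_nut1", ]
  expect_equal(ex$lower_bound, 0)
  expect_error(add_transfer_reactions(
    m, tibble::tibble(metabolite = "ghost[c]", importable = TRUE)),
    "ghost")
})

test_that("80 nutrients produce 160 transfer reactions", {
  ids <- paste0("n", 1:80, "[c]")
  m <- gem(metabolite_tbl(c("x[c]", ids)),
           reaction_tbl(paste0("SRC", 1:80), paste0("x[c] => ", ids)))
  m2 <- add_transfer_reactions(
    m, tibble::tibble(metabolite = ids, importable = rep(c(TRUE, FALSE), 40)))
  expect_equal(nrow(m2$reactions) - nrow(m$reactions), 160L)
  expect_equal(sum(m2$reactions$kind == "exchange"), 80L)
  expect_equal(sum(m2$reactions$kind == "transport"), 80L)
  # every nutrient has exactly one exchange and one transport
  for (id in c("n1", "n80")) {
    expect_equal(sum(m2$reactions$id == paste0("EX_", id)), 1L)
    expect_equal(sum(m2$reactions$id == paste0("T_", id)), 1L)
  }
})

test_that("missing pathway/subsystem annotation is filled from pool or default", {
  m <- gem(reactions = reaction_tbl(
    c("R1", "R2", "R3"),
    c("a[c] => b[c]", "b[c] => c0[c]", "c0[c] => a[c]"),
    pathway = c(NA, NA, "known"), subsystem = c(NA, NA, "known")))
  pool <- as_pool(tibble::tibble(reaction_id = "R1",
                                 equation = "a[c] => b[c]",
                                 pathway = "glycolysis",
                                 subsystem = "carbohydrate"))
  out <- annotate_missing(m, pool)
  expect_equal(out$n_filled, 2L)
  rx <- out$model$reactions
  expect_equal(rx$pathway[rx$id == "R1"], "glycolysis")
  expect_equal(rx$pathway[rx$id == "R2"], "metabolic pathway")
  expect_equal(rx$subsystem[rx$id == "R2"], "metabolic pathway")
  expect_equal(rx$pathway[rx$id == "R3"], "known")
  # fully annotated: nothing to do
  out2 <- annotate_missing(out$model, pool)
  expect_equal(out2$n_filled, 0L)
})
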