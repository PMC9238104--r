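#' Declare metabolite roles for the sanity checks
#'
#' The energy/matter checks need to know which species play the textbook
#' roles. Defaults match the ids produced by [make_toy_gem()].
#'
#' @param water,atp,adp,pi,h,glucose Cytosolic metabolite ids.
#' @return Named list of roles.
#' @export
gem_roles <- function(water = "h2o[c]", atp = "atp[c]", adp = "adp[c]",
                      pi = "pi[c]", h = "h[c]", glucose = "glc[c]") {
  list(water = water, atp = atp, adp = adp, pi = pi, h = h,
       glucose = glucose)
}

sanity_row <- function(name, passed, witnesses = NULL, note = NA_character_) {
  tibble(name = name, passed = passed,
         witnesses = list(witnesses %||%
                            tibble(id = character(0), flux = numeric(0))),
         note = note)
}

close_exchanges <- function(model) {
  ex <- model$reactions$id[model$reactions$kind == "exchange"]
  if (length(ex)) model <- gem_set_bounds(model, ex, lb = 0)
  model
}

## maximize each exchange's export in `model`; return exchanges with
## positive optimum
exchange_leaks <- function(model, eps) {
  ex <- exchange_table(model)
  leaks <- list()
  for (i in seq_len(nrow(ex))) {
    sol <- fba(model, ex$id[i], "max")
    if (sol$status == "optimal" && sol$objective_value > eps)
      leaks[[length(leaks) + 1]] <- tibble(id = ex$id[i],
                                           metabolite = ex$metabolite[i],
                                           flux = sol$objective_value)
  }
  bind_rows(leaks)
}

#' Leak test on the closed model
#'
#' Closes every exchange (lb = 0) and maximizes each exchange's export in
#' turn. Any positive optimum means the network creates an exchanged
#' metabolite from nothing -- typically caused by combinations of
#' reactions that are individually balanced but jointly inconsistent,
#' such as polymer interconversions with mismatched repeat counts.
#'
#' @param model A `gem`.
#' @param eps Leak threshold (mmol/gDW/h).
#' @return A one-row sanity tibble (`name`, `passed`, `witnesses`, `note`).
#' @export
leak_test_closed <- function(model, eps = 1e-6) {
  leaks <- exchange_leaks(close_exchanges(model), eps)
  sanity_row("leak_closed", nrow(leaks) == 0L, leaks)
}

#' Leak test with per-metabolite demands
#'
#' On the closed model, adds a demand for every metabolite and maximizes
#' it; metabolites with a positive optimum are producible from nothing.
#'
#' @inheritParams leak_test_closed
#' @return A one-row sanity tibble.
#' @export
leak_test_demands <- function(model, eps = 1e-6) {
  closed <- close_exchanges(model)
  leaks <- list()
  for (met in closed$metabolites$id) {
    wd <- with_target_drain(closed, met)
    sol <- fba(wd$model, wd$objective, "max")
    if (sol$status == "optimal" && sol$objective_value > eps)
      leaks[[length(leaks) + 1]] <- tibble(id = met,
                                           flux = sol$objective_value)
  }
  leaks <- bind_rows(leaks)
  sanity_row("leak_demands", NROW(leaks) == 0L, leaks)
}

## add (or reuse) the ATP hydrolysis demand; returns list(model, id) or NULL
with_atp_demand <- function(model, roles) {
  need <- c(roles$atp, roles$h2o %||% roles$water, roles$adp, roles$pi)
  if (!all(need %in% model$metabolites$id)) return(NULL)
  st <- setNames(c(-1, -1, 1, 1), need)
  if (!is.null(roles$h) && roles$h %in% model$metabolites$id)
    st[roles$h] <- 1
  id <- "DM_atp_hydrolysis"
  if (!id %in% model$reactions$id) {
    rxn <- reaction_tbl(id, format_equation(st, FALSE), kind = "demand")
    model <- gem_add_reactions(model, rxn)
  }
  list(model = model, id = id)
}

#' Energy and matter generation checks
#'
#' Four classic checks on a closed model: (a) no ATP production from
#' water alone; (b) no matter export when the ATP hydrolysis demand is
#' allowed to run backwards; (c) no flux through a cytosolic proton
#' demand; (d) ATP yield from 1 mmol/gDW/h of glucose does not exceed a
#' plausibility cap (default 40 ATP per glucose). Checks whose role
#' metabolites are absent from the model are skipped with a notice
#' (`passed = NA`).
#'
#' @param model A `gem`.
#' @param roles A [gem_roles()] list; an error names any undeclared role.
#' @param atp_yield_cap Maximum plausible ATP per glucose.
#' @param eps Flux tolerance.
#' @return A four-row sanity tibble.
#' @export
energy_matter_checks <- function(model, roles = gem_roles(),
                                 atp_yield_cap = 40, eps = 1e-6) {
  for (r in c("water", "atp", "adp", "pi", "glucose"))
    if (is.null(roles[[r]])) abort(paste0("missing role declaration: ", r))
  closed <- close_exchanges(model)
  atp <- with_atp_demand(closed, roles)
  skip <- function(name) sanity_row(name, NA,
                                    note = "role metabolites absent; skipped")

  ## energy from water: only water uptake open, maximize ATP hydrolysis
  r_water <- if (is.null(atp)) skip("energy_from_water") else {
    m <- atp$model
    wex <- find_exchange_for(m, roles$water)
    if (!is.na(wex)) m <- gem_set_bounds(m, wex, lb = -1000)
    sol <- fba(m, atp$id, "max")
    sanity_row("energy_from_water",
               sol$status == "optimal" && sol$objective_value <= eps,
               tibble(id = atp$id, flux = sol$objective_value))
  }

  ## matter from reversed ATP demand: demand lb = -1000, every exchange
  ## must still be unable to export
  r_matter <- if (is.null(atp)) skip("matter_from_reversed_atp_demand") else {
    m <- gem_set_bounds(atp$model, atp$id, lb = -1000)
    leaks <- exchange_leaks(m, eps)
    sanity_row("matter_from_reversed_atp_demand", nrow(leaks) == 0L, leaks)
  }

  ## proton demand in the closed model
  r_h <- if (is.null(roles$h) || !roles$h %in% model$metabolites$id)
    skip("proton_demand_closed")
  else {
    wd <- with_target_drain(closed, roles$h)
    sol <- fba(wd$model, wd$objective, "max")
    sanity_row("proton_demand_closed",
               sol$status == "optimal" && sol$objective_value <= eps,
               tibble(id = roles$h, flux = sol$objective_value))
  }

  ## ATP yield from glucose
  gex <- find_exchange_for(model, roles$glucose)
  r_glc <- if (is.null(atp) || is.na(gex)) skip("atp_yield_from_glucose")
  else {
    m <- gem_set_bounds(atp$model, gex, lb = -1)
    sol <- fba(m, atp$id, "max")
    sanity_row("atp_yield_from_glucose",
               sol$status == "optimal" && sol$objective_value <= atp_yield_cap,
               tibble(id = atp$id, flux = sol$objective_value))
  }

  bind_rows(r_water, r_matter, r_h, r_glc)
}

## the exchange reaction draining the extracellular twin of a cytosolic id
find_exchange_for <- function(model, met_c) {
  met_e <- paste0(met_base(met_c), "[e]")
  ex <- exchange_table(model)
  hit <- ex$id[ex$metabolite == met_e]
  if (length(hit)) hit[1] else NA_character_
}

#' Structural checks: duplicates, empty columns, demand bounds
#'
#' (a) no two reactions with identical stoichiometry; (b) no reaction
#' with an empty (all-zero) stoichiometric-matrix column; (c) every
#' demand reaction has lb >= 0.
#'
#' @param model A `gem`.
#' @return A three-row sanity tibble.
#' @export
structural_checks <- function(model) {
  keys <- map_chr(model$reactions$stoichiometry, stoich_key)
  dup_ids <- model$reactions$id[keys %in% keys[duplicated(keys)] & keys != ""]
  r_dup <- sanity_row("duplicated_reactions", length(dup_ids) == 0L,
                      tibble(id = dup_ids, flux = NA_real_))
  empty_ids <- model$reactions$id[map_int(model$reactions$stoichiometry,
                                          length) == 0L]
  r_empty <- sanity_row("empty_columns", length(empty_ids) == 0L,
                        tibble(id = empty_ids, flux = NA_real_))
  dm <- model$reactions[model$reactions$kind == "demand", , drop = FALSE]
  bad <- dm$id[dm$lower_bound < 0]
  r_dm <- sanity_row("demand_bounds", length(bad) == 0L,
                     tibble(id = bad,
                            flux = dm$lower_bound[dm$lower_bound < 0]))
  bind_rows(r_dup, r_empty, r_dm)
}

#' Run the full model sanity suite
#'
#' Executes the ten basic-property checks in fixed order: the two leak
#' tests, the four energy/matter checks, the three structural checks, and
#' a single-gene-deletion smoke test. Each row records pass/fail (or `NA`
#' when skipped) plus the flux witnesses implicating specific reactions
#' or metabolites.
#'
#' @inheritParams energy_matter_checks
#' @return A `sanity_report` tibble of 10 rows.
#' @export
sanity_suite <- function(model, roles = gem_roles(), atp_yield_cap = 40,
                         eps = 1e-6) {
  guard <- function(expr, name) {
    tryCatch(expr, error = function(e)
      sanity_row(name, FALSE, note = conditionMessage(e)))
  }
  sgd <- if (length(unlist(model$reactions$genes)) == 0L)
    sanity_row("single_gene_deletion_runs", NA, note = "model has no genes")
  else guard({
    res <- single_gene_deletion(model, model$objective_id %||%
                                  model$reactions$id[1])
    sanity_row("single_gene_deletion_runs",
               all(res$status %in% c("optimal", "infeasible")),
               tibble(id = res$gene, flux = res$objective_value))
  }, "single_gene_deletion_runs")
  out <- bind_rows(
    guard(leak_test_closed(model, eps), "leak_closed"),
    guard(leak_test_demands(model, eps), "leak_demands"),
    guard(energy_matter_checks(model, roles, atp_yield_cap, eps),
          "energy_matter"),
    guard(structural_checks(model), "structural"),
    sgd)
  class(out) <- c("sanity_report", class(out))
  out
}

#' @export
print.sanity_report <- function(x, ...) {
  cat("<sanity_report>\n")
  for (i in seq_len(nrow(x))) {
    status <- if (is.na(x$passed[i])) "SKIP"
              else if (x$passed[i]) "pass" else "FAIL"
    extra <- if (!is.na(x$passed[i]) && !x$passed[i] &&
                 nrow(x$witnesses[[i]]))
      paste0(" [", paste(head(x$witnesses[[i]]$id, 5), collapse = ", "), "]")
    else ""
    cat(sprintf("  %-32s %s%s\n", x$name[i], status, extra))
  }
  invisible(x)
}
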