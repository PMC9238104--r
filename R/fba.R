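## Internal LP layer -------------------------------------------------------
##
## FBA problems here are small and dense (toy through mesoscale networks)
## with all-finite bounds, which also rules out unbounded problems. The
## heavy lifting is done by the bounded-variable simplex in lp-solver.R.

solve_lp <- function(obj, S, lb, ub, sense = c("max", "min")) {
  sense <- match.arg(sense)
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n, all(lb <= ub))
  res <- lp_solve_bounded(obj, S, rep(0, nrow(S)), lb, ub,
                          maximize = sense == "max")
  v <- if (res$status == "optimal") res$x else rep(NA_real_, n)
  list(status = res$status,
       objective_value = if (res$status == "optimal") res$objective
                         else NA_real_,
       v = v)
}

new_flux_solution <- function(model, objective, sense, sol) {
  structure(list(status = sol$status, objective_value = sol$objective_value,
                 objective = objective, sense = sense,
                 fluxes = tibble(id = model$reactions$id, flux = sol$v,
                                 kind = model$reactions$kind)),
            class = "flux_solution")
}

#' Flux balance analysis
#'
#' Solves the steady-state linear program: optimize the objective
#' reaction's flux subject to S v = 0 and the model's flux bounds
#' (mmol/gDW/h; the biomass reaction's flux is read as gDW/h).
#'
#' @param model A `gem`.
#' @param objective Reaction id to optimize; defaults to the model's
#'   stored objective.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_solution`: status (`optimal`/`infeasible`/`failed`),
#'   objective value, and a tidy flux table accessible via [tidy()].
#' @examples
#' m <- gem(reactions = reaction_tbl(
#'   c("EX_a", "T_a", "DM_a"),
#'   c("a[e] <=> ", "a[e] <=> a[c]", "a[c] => "),
#'   lower_bound = c(-5, -1000, 0)))
#' fba(m, objective = "DM_a")$objective_value # 5: uptake-limited
#' @export
fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  objective <- objective %||% model$objective_id
  if (is.null(objective)) abort("no objective reaction given or stored")
  j <- rxn_index(model, objective)
  S <- stoichiometric_matrix(model)
  obj <- numeric(ncol(S)); obj[j] <- 1
  sol <- solve_lp(obj, S, model$reactions$lower_bound,
                  model$reactions$upper_bound, sense)
  new_flux_solution(model, objective, sense, sol)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", x$objective, paste0("(", x$sense, ")"),
      " value:", format(x$objective_value), "\n")
  invisible(x)
}

#' Parsimonious FBA at a fixed objective rate
#'
#' Fixes the objective reaction's flux and returns the flux distribution
#' of minimal total absolute flux (sum |v|). Used wherever a unique,
#' comparable flux vector is needed, since raw FBA optima are degenerate.
#'
#' @inheritParams fba
#' @param rate The value to which the objective flux is fixed
#'   (lower = upper bound).
#' @return A `flux_solution`; `objective_value` is the fixed rate and an
#'   extra field `total_flux` holds the minimized sum of absolute fluxes.
#' @export
pfba <- function(model, objective = NULL, rate) {
  objective <- objective %||% model$objective_id
  model <- gem_set_bounds(model, objective, lb = rate, ub = rate)
  S <- stoichiometric_matrix(model)
  n <- ncol(S)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  ## split v = p - q with p, q >= 0 and bounds chosen so p - q spans
  ## exactly [lb, ub]; minimizing 1'(p + q) then minimizes sum |v|
  p_lo <- pmax(lb, 0); p_hi <- pmax(ub, 0)
  q_lo <- pmax(-ub, 0); q_hi <- pmax(-lb, 0)
  res <- lp_solve_bounded(rep(1, 2 * n), cbind(S, -S), rep(0, nrow(S)),
                          c(p_lo, q_lo), c(p_hi, q_hi), maximize = FALSE)
  status <- res$status
  v <- if (status == "optimal")
    res$x[seq_len(n)] - res$x[n + seq_len(n)]
  else rep(NA_real_, n)
  out <- new_flux_solution(model, objective, "min_total_flux",
                           list(status = status,
                                objective_value = if (status == "optimal") rate else NA_real_,
                                v = v))
  out$total_flux <- if (status == "optimal") sum(abs(v)) else NA_real_
  out
}

## Bound policies ----------------------------------------------------------

#' Flux bound policy
#'
#' The standard bound classes used when converting a curated network into
#' a simulating model: reversible internal reactions (-1000, 1000),
#' irreversible (0, 1000); exchange/transport of nutrients the organism
#' can synthesize itself (0, 1000) (no import allowed); feed nutrients
#' (-5, 1000); trace elements (-1, 1000); semi-essential nutrients
#' (synthesizable but insufficiently, e.g. cysteine and tyrosine)
#' (-3, 1000). Per-reaction overrides win over class bounds.
#'
#' @param synthesizable,feed,trace,semi_essential Length-2 numeric bounds
#'   per nutrient class (mmol/gDW/h).
#' @param reversible,irreversible Bounds for internal reactions.
#' @param overrides Named list: reaction id -> c(lb, ub).
#' @return A `bounds_policy` object.
#' @export
bounds_policy <- function(reversible = c(-1000, 1000),
                          irreversible = c(0, 1000),
                          synthesizable = c(0, 1000),
                          feed = c(-5, 1000),
                          trace = c(-1, 1000),
                          semi_essential = c(-3, 1000),
                          overrides = list()) {
  pol <- list(reversible = reversible, irreversible = irreversible,
              synthesizable = synthesizable, feed = feed, trace = trace,
              semi_essential = semi_essential, overrides = overrides)
  for (b in pol[setdiff(names(pol), "overrides")])
    stopifnot(length(b) == 2L, b[1] <= b[2])
  for (b in overrides) stopifnot(length(b) == 2L, b[1] <= b[2])
  structure(pol, class = "bounds_policy")
}

#' Apply a bound policy to a model
#'
#' Internal (metabolic) reactions get the reversible/irreversible bounds
#' according to their `reversible` flag. Exchange and transport reactions
#' of classed nutrients get the class bounds; `nutrient_classes` maps the
#' *extracellular* metabolite id (or its base name) to one of
#' `"synthesizable"`, `"feed"`, `"trace"`, `"semi_essential"`. Overrides
#' are applied last.
#'
#' @param model A `gem`.
#' @param policy A [bounds_policy()].
#' @param nutrient_classes Named character vector, e.g.
#'   `c("glc[e]" = "feed", "zn[e]" = "trace")`.
#' @return The model with updated bounds.
#' @export
apply_policy <- function(model, policy = bounds_policy(),
                         nutrient_classes = NULL) {
  stopifnot(inherits(policy, "bounds_policy"))
  classes <- c("synthesizable", "feed", "trace", "semi_essential")
  if (!is.null(nutrient_classes)) {
    bad <- setdiff(unique(nutrient_classes), classes)
    if (length(bad))
      abort(paste0("unknown nutrient class label(s): ",
                   paste(bad, collapse = ", ")))
  }
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    kind <- rx$kind[i]
    if (kind %in% c("metabolic", "demand", "biomass")) {
      b <- if (rx$reversible[i]) policy$reversible else policy$irreversible
      if (kind %in% c("demand", "biomass")) b <- policy$irreversible
      rx$lower_bound[i] <- b[1]; rx$upper_bound[i] <- b[2]
    } else {
      ## boundary reaction: class by the extracellular species it moves
    emet <- names(rx$stoichiometry[[i]])
      emet <- emet[met_compartment(emet) == "e"]
      key <- c(emet, met_base(emet))
      cls <- nutrient_classes[key]
      cls <- cls[!is.na(cls)]
      b <- if (length(cls)) policy[[cls[1]]]
           else if (rx$reversible[i]) policy$reversible else policy$irreversible
      rx$lower_bound[i] <- b[1]; rx$upper_bound[i] <- b[2]
    }
  }
  for (id in names(policy$overrides)) {
    j <- rxn_index(model, id)
    rx$lower_bound[j] <- policy$overrides[[id]][1]
    rx$upper_bound[j] <- policy$overrides[[id]][2]
  }
  rx$reversible <- rx$lower_bound < 0
  model$reactions <- rx
  model
}

## Gene deletion and flux comparison ---------------------------------------

#' Single-gene deletion scan
#'
#' For each gene in the model, closes (lb = ub = 0) every reaction whose
#' entire gene list is removed by the deletion -- with flat gene lists a
#' single deletion only disables reactions associated to exactly that one
#' gene -- and re-optimizes the objective.
#'
#' @inheritParams fba
#' @return Tibble with columns `gene`, `status`, `objective_value`.
#' @export
single_gene_deletion <- function(model, objective = NULL) {
  objective <- objective %||% model$objective_id
  genes <- sort(unique(unlist(model$reactions$genes)))
  if (length(genes) == 0L)
    return(tibble(gene = character(0), status = character(0),
                  objective_value = numeric(0)))
  rows <- map(genes, function(g) {
    hit <- map_lgl(model$reactions$genes,
                   function(gl) length(gl) > 0 && all(gl %in% g))
    m <- model
    if (any(hit)) m <- gem_set_bounds(m, m$reactions$id[hit], lb = 0, ub = 0)
    sol <- fba(m, objective)
    tibble(gene = g, status = sol$status,
           objective_value = sol$objective_value)
  })
  bind_rows(rows)
}

#' Compare flux distributions between two growth rates
#'
#' Fixes the objective (biomass) flux at a low and a high rate, computes
#' the parsimonious flux distribution at each (so the comparison is
#' well-defined despite degenerate FBA optima), and lists the reactions
#' whose flux changes by more than `threshold`, sorted by |delta|
#' descending, together with their pathway and subsystem.
#'
#' @inheritParams fba
#' @param rate_low,rate_high The two objective rates (gDW/h for biomass).
#' @param threshold Minimum |flux change| to report (mmol/gDW/h).
#' @return A `flux_compare` object; [tidy()] returns the change table.
#' @export
flux_compare <- function(model, objective = NULL, rate_low, rate_high,
                         threshold = 1e-6) {
  objective <- objective %||% model$objective_id
  lo <- pfba(model, objective, rate_low)
  if (lo$status != "optimal")
    abort(paste0("model infeasible at rate_low = ", rate_low))
  hi <- pfba(model, objective, rate_high)
  if (hi$status != "optimal")
    abort(paste0("model infeasible at rate_high = ", rate_high))
  changed <- tibble(id = model$reactions$id,
                    pathway = model$reactions$pathway,
                    subsystem = model$reactions$subsystem,
                    kind = model$reactions$kind,
                    flux_low = lo$fluxes$flux, flux_high = hi$fluxes$flux,
                    delta = abs(hi$fluxes$flux - lo$fluxes$flux))
  changed <- arrange(filter(changed, .data$delta > threshold),
                     desc(.data$delta))
  structure(list(changed = changed, threshold = threshold,
                 rate_low = rate_low, rate_high = rate_high,
                 objective = objective),
            class = "flux_compare")
}

#' @export
print.flux_compare <- function(x, ...) {
  cat("<flux_compare> ", nrow(x$changed), " reactions changed by > ",
      x$threshold, " between rates ", x$rate_low, " and ", x$rate_high,
      "\n", sep = "")
  invisible(x)
}
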