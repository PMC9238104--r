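#' Weakly connected components of the metabolite-reaction graph
#'
#' Builds the bipartite graph in which a metabolite and a reaction are
#' joined whenever the metabolite has a nonzero coefficient in the
#' reaction, and reports its weakly connected components over the
#' metabolites. The number of components is a standard proxy for how
#' fragmented (gappy) a reconstruction still is.
#'
#' @param model A `gem`.
#' @return A `connectivity_report`: `n_wcc` and `components`, a list of
#'   metabolite-id sets ordered by smallest member id. [tidy()] gives a
#'   (component, metabolite) tibble.
#' @export
connectivity <- function(model) {
  mets <- model$metabolites$id
  rxns <- paste0("rxn::", model$reactions$id)
  edges <- unlist(map(seq_len(nrow(model$reactions)), function(j) {
    st <- names(model$reactions$stoichiometry[[j]])
    if (length(st) == 0L) return(NULL)
    rbind(rxns[j], st)
  }))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(mets) + length(rxns),
                            name = c(mets, rxns))
  if (length(edges)) g <- igraph::add_edges(g, match(edges, c(mets, rxns)))
  comp <- igraph::components(g)
  membership <- comp$membership[seq_along(mets)]
  components <- split(mets, membership)
  components <- map(components, sort)
  components <- components[map_int(components, length) > 0]
  components <- components[order(map_chr(components, 1))]
  names(components) <- NULL
  structure(list(n_wcc = length(components), components = components),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("<connectivity_report>", x$n_wcc, "weakly connected component(s)\n")
  invisible(x)
}

## ensure the model has a drain for `target`; returns list(model, objective)
with_target_drain <- function(model, target) {
  if (!target %in% model$metabolites$id)
    abort(paste0("target metabolite not in model: ", target))
  ex <- model$reactions[model$reactions$kind %in% c("exchange", "demand"), ,
                        drop = FALSE]
  hit <- map_lgl(ex$stoichiometry,
                 function(st) length(st) == 1L && names(st) == target &&
                   st < 0)
  if (any(hit)) return(list(model = model, objective = ex$id[which(hit)[1]]))
  dm <- reaction_tbl(paste0("DM_", met_base(target), "_tmp"),
                     paste0(target, " => "), kind = "demand")
  list(model = gem_add_reactions(model, dm), objective = dm$id)
}

#' Can the network produce a metabolite?
#'
#' Flux-based producibility: maximizes the drain (exchange or temporary
#' demand) of the target under the model's current bounds -- so cofactor
#' coupling and reversibility are honored, unlike simple graph
#' reachability. A metabolite counts as producible when the maximal drain
#' flux exceeds `eps`.
#'
#' @param model A `gem`.
#' @param target Metabolite id.
#' @param medium Optional [bounds_policy()] (with `nutrient_classes`
#'   passed through `...`) applied before solving; `NULL` keeps current
#'   bounds.
#' @param eps Producibility threshold (mmol/gDW/h).
#' @param ... Passed to [apply_policy()] when `medium` is given.
#' @return List with `producible` (logical) and `max_flux`.
#' @export
is_producible <- function(model, target, medium = NULL, eps = 1e-6, ...) {
  if (!is.null(medium)) model <- apply_policy(model, medium, ...)
  wd <- with_target_drain(model, target)
  sol <- fba(wd$model, wd$objective, "max")
  if (sol$status != "optimal")
    abort(paste0("solver status '", sol$status, "' while testing ", target))
  list(producible = sol$objective_value > eps,
       max_flux = sol$objective_value)
}

#' Producibility of many targets
#'
#' @inheritParams is_producible
#' @param targets Character vector of metabolite ids.
#' @return Tibble with `metabolite`, `producible`, `max_flux`.
#' @export
producibility <- function(model, targets, medium = NULL, eps = 1e-6, ...) {
  if (!is.null(medium)) model <- apply_policy(model, medium, ...)
  bind_rows(map(targets, function(t) {
    p <- is_producible(model, t, eps = eps)
    tibble(metabolite = t, producible = p$producible, max_flux = p$max_flux)
  }))
}

## reactions able to produce `met` under current bounds, with direction
producing_directions <- function(model, met) {
  out <- list()
  for (j in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[j]]
    if (!met %in% names(st)) next
    coef <- st[[met]]
    if (coef > 0 && model$reactions$upper_bound[j] > 0)
      out[[length(out) + 1]] <- list(j = j, dir = +1)
    if (coef < 0 && model$reactions$lower_bound[j] < 0)
      out[[length(out) + 1]] <- list(j = j, dir = -1)
  }
  out
}

#' Backtrack the synthesis route of a blocked metabolite
#'
#' Starting from a non-producible target, walks breadth-first backwards
#' over the reactions able to produce each metabolite and reports the
#' upstream species where synthesis breaks down: metabolites with no
#' producing reaction at all (`orphan`) or whose producers are all
#' blocked further upstream (`blocked`). This mirrors the manual
#' breakpoint search used when repairing amino-acid synthesis routes.
#'
#' @inheritParams is_producible
#' @param max_depth Maximum backtracking depth.
#' @return Tibble `metabolite`, `reason` (`orphan`/`blocked`), `depth`,
#'   in deterministic breadth-first order. Producible targets yield an
#'   empty tibble with a message.
#' @export
find_breakpoints <- function(model, target, max_depth = 10, eps = 1e-6) {
  empty <- tibble(metabolite = character(0), reason = character(0),
                  depth = integer(0))
  if (is_producible(model, target, eps = eps)$producible) {
    message("target ", target, " is already producible; nothing to backtrack")
    return(empty)
  }
  seen <- character(0)
  frontier <- target
  depth <- 0L
  out <- empty
  while (length(frontier) && depth <= max_depth) {
    frontier <- sort(setdiff(frontier, seen))
    seen <- c(seen, frontier)
    nxt <- character(0)
    for (met in frontier) {
      if (is_producible(model, met, eps = eps)$producible) next
      prods <- producing_directions(model, met)
      if (length(prods) == 0L) {
        out <- bind_rows(out, tibble(metabolite = met, reason = "orphan",
                                     depth = depth))
      } else {
        if (met != target)
          out <- bind_rows(out, tibble(metabolite = met, reason = "blocked",
                                       depth = depth))
        for (p in prods) {
          st <- model$reactions$stoichiometry[[p$j]]
          substrates <- names(st)[sign(st) * p$dir < 0]
          nxt <- union(nxt, substrates)
        }
      }
    }
    frontier <- nxt
    depth <- depth + 1L
  }
  out
}

#' Fill network gaps from a universal reaction pool
#'
#' For each non-producible target, greedily adds the smallest candidate
#' reaction set (iterative deepening over set sizes 1 then 2, lexicographic
#' id order for determinism) from the pool that makes the target
#' producible. At `scale = "pathway"` the candidates are restricted to
#' pool reactions sharing a pathway with some reaction already in the
#' model; `scale = "global"` uses the whole pool. Because added reactions
#' always admit zero flux, producibility of previously producible
#' metabolites is preserved.
#'
#' @param model A `gem`.
#' @param pool A [as_pool()] table.
#' @param targets Metabolite ids to restore.
#' @param scale `"pathway"` or `"global"`.
#' @param max_additions Largest candidate set size tried per target.
#' @param eps Producibility threshold.
#' @return A `gapfill_result`: the augmented `model`, `added_reactions`,
#'   `restored`, `unrestored`, and `scale`. [tidy()] gives a per-target
#'   table.
#' @export
gapfill <- function(model, pool, targets, scale = c("pathway", "global"),
                    max_additions = 2, eps = 1e-6) {
  scale <- match.arg(scale)
  pool <- as_pool(pool)
  candidates <- pool$reaction_id[!pool$reaction_id %in% model$reactions$id]
  if (scale == "pathway") {
    known <- unique(model$reactions$pathway)
    known <- known[!is.na(known)]
    keep <- pool$pathway[match(candidates, pool$reaction_id)] %in% known
    candidates <- candidates[keep]
  }
  candidates <- sort(candidates)
  added <- character(0); restored <- character(0); unrestored <- character(0)
  per_target <- list()
  for (target in targets) {
    if (is_producible(model, target, eps = eps)$producible) {
      per_target[[target]] <- character(0)
      restored <- c(restored, target)
      next
    }
    found <- NULL
    avail <- setdiff(candidates, model$reactions$id)
    for (k in seq_len(max_additions)) {
      if (length(avail) < k) break
      sets <- combn(avail, k, simplify = FALSE)
      for (set in sets) {
        trial <- gem_add_reactions(model, pool_reactions(pool, set))
        if (is_producible(trial, target, eps = eps)$producible) {
          found <- set; model <- trial; break
        }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      unrestored <- c(unrestored, target)
      per_target[[target]] <- NA_character_
    } else {
      added <- c(added, found)
      restored <- c(restored, target)
      per_target[[target]] <- found
    }
  }
  structure(list(model = model, added_reactions = added,
                 restored_targets = restored, unrestored = unrestored,
                 per_target = per_target, scale = scale),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result> scale:", x$scale, "\n  added:",
      if (length(x$added_reactions)) paste(x$added_reactions, collapse = ", ")
      else "<none>",
      "\n  restored:", length(x$restored_targets),
      " unrestored:", length(x$unrestored), "\n")
  invisible(x)
}
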