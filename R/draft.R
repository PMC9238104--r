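#' Build a draft model by KEGG-Orthology bridge matching
#'
#' Matches the KO ids of a unigene->KO annotation table against the KO ids
#' of a universal reaction pool and keeps exactly the pool reactions with
#' a shared KO. Each kept reaction's gene list is the set of unigenes
#' annotated to any shared KO. All metabolites of the draft are placed in
#' the cytosol; compartments only appear later when transfer reactions
#' are added.
#'
#' @param ko_table Data frame with columns `unigene_id`, `ko_id` (exact
#'   `"Kxxxxx"` string matching; pairs need not be unique on either side).
#' @param pool A [as_pool()] table.
#' @return A `gem`. An empty KO intersection gives a valid empty model
#'   with a warning.
#' @export
build_draft <- function(ko_table, pool) {
  pool <- as_pool(pool)
  ko_table <- distinct(as_tibble(ko_table)[, c("unigene_id", "ko_id")])
  kos <- unique(ko_table$ko_id)
  keep <- map_lgl(pool$ko_ids, function(k) length(intersect(k, kos)) > 0)
  if (!any(keep)) {
    warn("no pool reaction shares a KO with the annotation table; empty draft")
    return(gem())
  }
  rows <- pool[keep, , drop = FALSE]
  genes <- map(rows$ko_ids, function(k) {
    sort(unique(ko_table$unigene_id[ko_table$ko_id %in% k]))
  })
  rxns <- reaction_tbl(id = rows$reaction_id, equation = rows$equation,
                       genes = genes, ko_ids = rows$ko_ids,
                       pathway = rows$pathway, subsystem = rows$subsystem)
  bad <- map_lgl(rxns$stoichiometry,
                 function(st) any(met_compartment(names(st)) != "c"))
  if (any(bad))
    abort("draft reconstruction expects all pool metabolites in compartment c")
  gem(reactions = rxns)
}

## ---- element and charge balance ----

#' Parse an elemental formula into element counts
#'
#' @param formula Formula string such as `"C6H12O6"`. Anything that is not
#'   a plain element-count sequence (polymer notation, `"UNKNOWN"`, `n`
#'   subscripts) returns `NULL`, marking the composition indeterminate.
#' @return Named integer vector of element counts, or `NULL`.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || formula == "" || formula == "UNKNOWN") return(NULL)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) return(NULL)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(sub("^[A-Za-z]+", "", toks))
  ct[is.na(ct)] <- 1L
  counts <- tapply(ct, el, sum)
  setNames(as.integer(counts), names(counts))
}

#' Check element and charge conservation of reactions
#'
#' Computes the net element counts (products minus substrates, weighted by
#' stoichiometry) and net charge for each reaction. Any metabolite with an
#' `UNKNOWN` formula -- typically polymeric species with an indeterminate
#' repeat count -- makes the verdict `unknown` rather than a failure,
#' matching how such species evade balancing yet cause network-level
#' leaks. Charge deltas are reported only where all charges are known.
#'
#' @param model A `gem`.
#' @param ids Reaction ids to check (default: all).
#' @return A tibble `id`, `verdict` (`balanced`/`unbalanced`/`unknown`),
#'   `deltas` (list-column of named element counts), `charge_delta`.
#' @export
check_balance <- function(model, ids = model$reactions$id) {
  forms <- setNames(model$metabolites$formula, model$metabolites$id)
  charges <- setNames(model$metabolites$charge, model$metabolites$id)
  rows <- map(ids, function(id) {
    st <- model$reactions$stoichiometry[[rxn_index(model, id)]]
    parsed <- map(names(st), function(m) parse_formula(forms[[m]]))
    if (any(map_lgl(parsed, is.null)))
      return(tibble(id = id, verdict = "unknown",
                    deltas = list(setNames(numeric(0), character(0))),
                    charge_delta = NA_real_))
    delta <- numeric(0)
    for (k in seq_along(st)) {
      cnt <- parsed[[k]] * st[k]
      for (e in names(cnt)) delta[e] <- (delta[e] %|0|% 0) + cnt[[e]]
    }
    delta <- delta[abs(delta) > 1e-9]
    ch <- charges[names(st)]
    charge_delta <- if (anyNA(ch)) NA_real_ else sum(ch * st)
    balanced <- length(delta) == 0L &&
      (is.na(charge_delta) || abs(charge_delta) < 1e-9)
    tibble(id = id, verdict = if (balanced) "balanced" else "unbalanced",
           deltas = list(delta), charge_delta = charge_delta)
  })
  bind_rows(rows)
}

`%|0|%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

## ---- redundancy pruning ----

stoich_key <- function(st) {
  st <- st[order(names(st))]
  paste(names(st), format(unname(st), trim = TRUE, digits = 12),
        sep = ":", collapse = ";")
}

#' Remove redundant reactions
#'
#' Three redundancy classes are pruned, mirroring manual network
#' curation: (i) reactions flagged `general` or `incomplete` in the pool
#' metadata; (ii) multi-step (lumped) reactions whose net stoichiometry
#' equals the sum of one or two retained elementary steps; (iii) exact
#' duplicate stoichiometries, keeping the lexicographically smallest id.
#'
#' @param model A `gem`.
#' @param pool Optional [as_pool()] table supplying curation flags.
#' @return List with the pruned `model` and a `removed` tibble
#'   (`id`, `reason`).
#' @export
prune_redundant <- function(model, pool = NULL) {
  removed <- tibble(id = character(0), reason = character(0))
  if (!is.null(pool)) {
    pool <- as_pool(pool)
    flagged <- pool$reaction_id[map_lgl(pool$flags, function(f)
      any(c("general", "incomplete") %in% f))]
    hit <- intersect(model$reactions$id, flagged)
    if (length(hit)) {
      model <- gem_drop_reactions(model, hit)
      removed <- bind_rows(removed, tibble(id = hit, reason = "flagged"))
    }
  }
  ## duplicates first, so lumped-step detection works on unique columns
  keys <- map_chr(model$reactions$stoichiometry, stoich_key)
  ord <- order(keys, model$reactions$id)
  dup <- ord[duplicated(keys[ord])]
  if (length(dup)) {
    ids <- model$reactions$id[dup]
    model <- gem_drop_reactions(model, ids)
    removed <- bind_rows(removed, tibble(id = ids, reason = "duplicate"))
  }
  ## lumped multi-step reactions: net stoichiometry equal to the sum of a
  ## pair of other retained reactions (the common A->C vs A->B, B->C case)
  repeat {
    ids <- sort(model$reactions$id)
    st <- setNames(model$reactions$stoichiometry[rxn_index(model, ids)], ids)
    lumped <- NULL
    for (cand in ids) {
      others <- setdiff(ids, cand)
      if (length(others) < 2) next
      prs <- combn(others, 2, simplify = FALSE)
      for (p in prs) {
        net <- c(st[[p[1]]], st[[p[2]]])
        net <- tapply(net, names(net), sum)
        net <- net[abs(net) > 1e-9]
        if (length(net) == length(st[[cand]]) &&
            setequal(names(net), names(st[[cand]])) &&
            all(abs(net[names(st[[cand]])] - st[[cand]]) < 1e-9)) {
          lumped <- cand; break
        }
      }
      if (!is.null(lumped)) break
    }
    if (is.null(lumped)) break
    model <- gem_drop_reactions(model, lumped)
    removed <- bind_rows(removed, tibble(id = lumped, reason = "lumped"))
  }
  list(model = model, removed = removed)
}

#' Standardize metabolite ids with unclear chirality
#'
#' Applies an alias -> canonical id map to every metabolite and
#' stoichiometry entry (e.g. collapsing unspecified-chirality duplicates
#' onto one canonical species), then reuses [prune_redundant()] to drop
#' any duplicate reactions the merge created.
#'
#' @param model A `gem`.
#' @param alias_map Named character vector `c(alias_id = canonical_id)`.
#' @return List with `model` and `removed` (duplicates pruned after
#'   renaming).
#' @export
standardize_chirality <- function(model, alias_map) {
  rename <- function(ids) ifelse(ids %in% names(alias_map),
                                 alias_map[ids], ids)
  model$metabolites$id <- unname(rename(model$metabolites$id))
  model$metabolites <- distinct(model$metabolites, .data$id, .keep_all = TRUE)
  model$metabolites$compartment <- met_compartment(model$metabolites$id)
  model$reactions$stoichiometry <- map(model$reactions$stoichiometry,
    function(st) {
      names(st) <- unname(rename(names(st)))
      if (anyDuplicated(names(st))) {
        st <- tapply(st, names(st), sum)
        st <- setNames(as.numeric(st), names(st))
        st <- st[st != 0]
      }
      st
    })
  validate_gem(model)
  prune_redundant(model)
}

## ---- transfer reactions and annotation ----

#' Add exchange and transport reactions for nutrients
#'
#' For each nutrient (a cytosolic metabolite), creates its extracellular
#' twin plus one transport reaction (`T_<name>`: e <-> c) and one exchange
#' reaction (`EX_<name>`). Importable nutrients get reversible transfer
#' reactions; non-importable ones (nutrients the organism synthesizes
#' itself, so they must not be obtainable from the feed) get lb = 0,
#' i.e. irreversible outward.
#'
#' @param model A `gem`.
#' @param nutrients Data frame with columns `metabolite` (cytosolic id)
#'   and `importable` (logical).
#' @return The augmented `gem`.
#' @export
add_transfer_reactions <- function(model, nutrients) {
  nutrients <- as_tibble(nutrients)
  missing <- setdiff(nutrients$metabolite, model$metabolites$id)
  if (length(missing))
    abort(paste0("nutrient metabolite(s) absent from model: ",
                 paste(missing, collapse = ", ")))
  comp <- model$metabolites$compartment[match(nutrients$metabolite,
                                              model$metabolites$id)]
  if (any(comp != "c"))
    abort("nutrients must be cytosolic metabolites")
  for (i in seq_len(nrow(nutrients))) {
    met_c <- nutrients$metabolite[i]
    base <- met_base(met_c)
    met_e <- paste0(base, "[e]")
    imp <- isTRUE(nutrients$importable[i])
    src <- model$metabolites[model$metabolites$id == met_c, ]
    new_met <- metabolite_tbl(met_e, name = src$name, formula = src$formula,
                              charge = src$charge)
    ## importable: reversible e <-> c plus reversible exchange;
    ## non-importable: both irreversible outward (c -> e -> out), lb = 0
    rxns <- reaction_tbl(
      id = c(paste0("T_", base), paste0("EX_", base)),
      equation = c(if (imp) paste0(met_e, " <=> ", met_c)
                   else paste0(met_c, " => ", met_e),
                   paste0(met_e, if (imp) " <=> " else " => ")),
      lower_bound = if (imp) c(-1000, -1000) else c(0, 0),
      upper_bound = c(1000, 1000))
    model <- gem_add_reactions(model, rxns, metabolites = new_met)
  }
  model
}

#' Fill in missing pathway and subsystem annotation
#'
#' Reactions lacking a pathway or subsystem inherit them from the pool
#' where available; anything still unannotated is classified into the
#' generic "metabolic pathway".
#'
#' @param model A `gem`.
#' @param pool A [as_pool()] table.
#' @return List with `model` and `n_filled`, the number of reactions whose
#'   annotation was completed.
#' @export
annotate_missing <- function(model, pool = NULL) {
  rx <- model$reactions
  blank <- function(x) is.na(x) | x == ""
  needs <- blank(rx$pathway) | blank(rx$subsystem)
  n_filled <- 0L
  for (i in which(needs)) {
    filled <- FALSE
    if (!is.null(pool)) {
      j <- match(rx$id[i], pool$reaction_id)
      if (!is.na(j)) {
        if (blank(rx$pathway[i]) && !blank(pool$pathway[j])) {
          rx$pathway[i] <- pool$pathway[j]; filled <- TRUE
        }
        if (blank(rx$subsystem[i]) && !blank(pool$subsystem[j])) {
          rx$subsystem[i] <- pool$subsystem[j]; filled <- TRUE
        }
      }
    }
    if (blank(rx$pathway[i])) { rx$pathway[i] <- "metabolic pathway"; filled <- TRUE }
    if (blank(rx$subsystem[i])) { rx$subsystem[i] <- "metabolic pathway"; filled <- TRUE }
    n_filled <- n_filled + filled
  }
  model$reactions <- rx
  list(model = model, n_filled = n_filled)
}
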