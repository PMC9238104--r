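#' Parse a reaction equation string
#'
#' Equations use compartment-suffixed metabolite ids and an arrow that
#' encodes reversibility: `"glc[e] <=> glc[c]"` (reversible) or
#' `"2 atp[c] + glc[c] => g6p[c]"` (irreversible; `->` is accepted).
#' One side may be empty, as in boundary reactions (`"glc[e] <=> "`).
#'
#' @param equation A single equation string.
#' @return A list with `stoichiometry` (named numeric; negative = consumed)
#'   and `reversible` (logical).
#' @examples
#' parse_equation("glc[c] => 2 pyr[c]")
#' @export
parse_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>"
    else if (grepl("=>", equation, fixed = TRUE)) "=>"
    else if (grepl("->", equation, fixed = TRUE)) "->"
    else abort(paste0("no reaction arrow ('<=>', '=>' or '->') in equation: ",
                      equation))
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L)
    abort(paste0("malformed equation (multiple arrows): ", equation))

  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    terms <- terms[terms != ""]
    out <- numeric(length(terms))
    ids <- character(length(terms))
    for (i in seq_along(terms)) {
      m <- regmatches(terms[i],
                      regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S+)$",
                              terms[i]))[[1]]
      if (length(m) == 0L)
        abort(paste0("malformed stoichiometry term '", terms[i],
                     "' in equation: ", equation))
      coef <- if (m[2] == "") 1 else as.numeric(trimws(m[2]))
      out[i] <- sign * coef
      ids[i] <- m[3]
    }
    setNames(out, ids)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  ## same species on both sides: net it out
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)
    st <- setNames(as.numeric(st), names(st))
  }
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<=>")
}

#' Format a stoichiometry mapping back into an equation string
#'
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param reversible Logical; selects `<=>` or `=>`.
#' @return Equation string; inverse of [parse_equation()].
#' @export
format_equation <- function(stoichiometry, reversible) {
  fmt <- function(v) {
    if (length(v) == 0L) return("")
    coefs <- ifelse(abs(v) == 1, "", paste0(format(abs(v), trim = TRUE,
                                                   scientific = FALSE), " "))
    paste0(coefs, names(v), collapse = " + ")
  }
  lhs <- fmt(stoichiometry[stoichiometry < 0])
  rhs <- fmt(stoichiometry[stoichiometry > 0])
  paste(lhs, if (reversible) "<=>" else "=>", rhs)
}

met_compartment <- function(id) {
  ifelse(grepl("\\[e\\]$", id), "e", ifelse(grepl("\\[c\\]$", id), "c",
                                            NA_character_))
}

met_base <- function(id) sub("\\[[ce]\\]$", "", id)

#' Build a metabolite table
#'
#' @param id Metabolite ids carrying a compartment suffix (`"glc[c]"`,
#'   `"glc[e]"`). The suffix must agree with `compartment`.
#' @param name,formula,charge,compartment Optional annotation vectors;
#'   `formula = "UNKNOWN"` marks species whose elemental composition is
#'   indeterminate (e.g. polymers with an unspecified repeat count) and
#'   `charge = NA` an unknown charge. `compartment` defaults to the id
#'   suffix.
#' @return A tibble with columns `id`, `name`, `formula`, `charge`,
#'   `compartment`.
#' @export
metabolite_tbl <- function(id, name = met_base(id), formula = "UNKNOWN",
                           charge = NA_integer_, compartment = met_compartment(id)) {
  tibble(id = as.character(id), name = as.character(name),
         formula = as.character(formula),
         charge = as.integer(charge),
         compartment = as.character(compartment))
}

#' Build a reaction table from equation strings
#'
#' @param id Reaction ids.
#' @param equation Equation strings understood by [parse_equation()].
#' @param lower_bound,upper_bound Flux bounds in mmol/gDW/h. Defaults follow
#'   the usual convention: reversible reactions (-1000, 1000), irreversible
#'   (0, 1000).
#' @param genes,ko_ids Lists (or `"|"`-separated strings) of gene /
#'   KEGG Orthology ids per reaction.
#' @param name,pathway,subsystem,kind Optional annotations. `kind` is one of
#'   `metabolic`, `transport`, `exchange`, `demand`, `biomass`, or `NA` to
#'   classify from compartments later.
#' @return Tibble with one row per reaction; `stoichiometry` is a
#'   list-column of named numeric vectors.
#' @examples
#' reaction_tbl(c("R1", "R2"), c("glc[e] <=> glc[c]", "glc[c] => 2 pyr[c]"))
#' @export
reaction_tbl <- function(id, equation, lower_bound = NULL, upper_bound = NULL,
                         genes = NULL, ko_ids = NULL, name = id,
                         pathway = NA_character_, subsystem = NA_character_,
                         kind = NA_character_) {
  parsed <- map(equation, parse_equation)
  rev <- map_lgl(parsed, "reversible")
  lb <- lower_bound %||% ifelse(rev, -1000, 0)
  ub <- upper_bound %||% rep(1000, length(id))
  as_id_list <- function(x, n) {
    if (is.null(x)) return(rep(list(character(0)), n))
    if (is.character(x)) x <- strsplit(x, "|", fixed = TRUE)
    map(x, function(g) as.character(g[!is.na(g) & g != ""]))
  }
  tibble(
    id = as.character(id), name = as.character(name),
    stoichiometry = map(parsed, "stoichiometry"),
    lower_bound = as.numeric(lb), upper_bound = as.numeric(ub),
    reversible = rev,
    genes = as_id_list(genes, length(id)),
    ko_ids = as_id_list(ko_ids, length(id)),
    pathway = as.character(pathway), subsystem = as.character(subsystem),
    kind = as.character(kind)
  )
}

#' Assemble (and validate) a genome-scale metabolic model
#'
#' A `gem` is a list of two tidy tables plus an objective selector. It is
#' the central container of the package: every reconstruction, gap-filling
#' and simulation verb takes one and returns one.
#'
#' @param metabolites Tibble as produced by [metabolite_tbl()]. May be
#'   omitted (`NULL`) to derive a skeleton table from the reaction
#'   stoichiometries (all formulas `UNKNOWN`).
#' @param reactions Tibble as produced by [reaction_tbl()].
#' @param objective Reaction id of the objective (usually the biomass
#'   reaction), or `NULL`.
#' @return An object of class `gem`.
#' @export
gem <- function(metabolites = NULL, reactions = reaction_tbl(character(0), character(0)),
                objective = NULL) {
  if (is.null(metabolites)) {
    ids <- sort(unique(unlist(map(reactions$stoichiometry, names))))
    metabolites <- metabolite_tbl(ids)
  }
  model <- structure(list(metabolites = as_tibble(metabolites),
                          reactions = as_tibble(reactions),
                          objective_id = objective),
                     class = "gem")
  validate_gem(model)
  model$reactions$kind <- classify_reactions(model)
  model
}

#' Validate a gem's structural invariants
#'
#' Checks id uniqueness, compartment codes, bound ordering, and that every
#' metabolite referenced by a reaction exists. Called by [gem()] and the
#' loaders; exported so refined models can be re-checked after manual
#' surgery.
#'
#' @param model A `gem`.
#' @return The model, invisibly unchanged, or an error.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id))
    abort(paste0("duplicate metabolite id(s): ",
                 paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  if (anyDuplicated(rxns$id))
    abort(paste0("duplicate reaction id(s): ",
                 paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  bad_comp <- !mets$compartment %in% c("c", "e")
  if (any(bad_comp))
    abort(paste0("compartment must be 'c' (cytosol) or 'e' (extracellular); bad: ",
                 paste(mets$id[bad_comp], collapse = ", ")))
  suffix <- met_compartment(mets$id)
  if (any(!is.na(suffix) & suffix != mets$compartment))
    abort("metabolite id compartment suffix disagrees with compartment field")
  refs <- unique(unlist(map(rxns$stoichiometry, names)))
  missing <- setdiff(refs, mets$id)
  if (length(missing))
    abort(paste0("reaction(s) reference unknown metabolite(s): ",
                 paste(missing, collapse = ", ")))
  if (any(rxns$lower_bound > rxns$upper_bound))
    abort(paste0("lower_bound > upper_bound for: ",
                 paste(rxns$id[rxns$lower_bound > rxns$upper_bound],
                       collapse = ", ")))
  if (!is.null(model$objective_id) &&
      !model$objective_id %in% rxns$id)
    abort(paste0("objective reaction not in model: ", model$objective_id))
  invisible(model)
}

#' Classify reactions by the compartments they touch
#'
#' Rules: all metabolites cytosolic -> `metabolic`; all extracellular ->
#' `exchange`; a mixture -> `transport`. Reactions already flagged
#' `biomass` or `demand` keep their flag.
#'
#' @param model A `gem`.
#' @return Character vector of kinds, one per reaction, in model order.
#' @export
classify_reactions <- function(model) {
  comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  map_chr(seq_len(nrow(model$reactions)), function(i) {
    kind <- model$reactions$kind[i]
    if (!is.na(kind) && kind %in% c("biomass", "demand")) return(kind)
    ids <- names(model$reactions$stoichiometry[[i]])
    if (length(ids) == 0L) return("metabolic")
    cs <- unique(comp[ids])
    if (all(cs == "c")) "metabolic" else if (all(cs == "e")) "exchange"
    else "transport"
  })
}

#' The stoichiometric matrix of a model
#'
#' @param model A `gem`.
#' @return A dense numeric matrix S of shape (metabolites x reactions) with
#'   dimnames; `S[i, j]` is the coefficient of metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites); n <- nrow(model$reactions)
  S <- matrix(0, m, n, dimnames = list(model$metabolites$id,
                                       model$reactions$id))
  for (j in seq_len(n)) {
    st <- model$reactions$stoichiometry[[j]]
    if (length(st)) S[names(st), j] <- S[names(st), j] + st
  }
  S
}

#' @export
print.gem <- function(x, ...) {
  cat("<gem> ", nrow(x$metabolites), " metabolites x ",
      nrow(x$reactions), " reactions\n", sep = "")
  kinds <- table(x$reactions$kind)
  if (length(kinds))
    cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
        "\n")
  cat("  objective:", x$objective_id %||% "<none>", "\n")
  invisible(x)
}

#' @export
dim.gem <- function(x) c(nrow(x$metabolites), nrow(x$reactions))

## ---- small internal helpers used across modules ----

rxn_index <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (anyNA(i)) abort(paste0("reaction(s) not in model: ",
                             paste(id[is.na(i)], collapse = ", ")))
  i
}

#' Model surgery: set bounds, add or drop reactions
#'
#' Small verbs used throughout refinement and simulation. `gem_set_bounds`
#' updates flux bounds (and the derived `reversible` flag);
#' `gem_add_reactions` appends reaction rows, creating any metabolites
#' they reference (with `UNKNOWN` formula) unless supplied explicitly;
#' `gem_drop_reactions` removes reactions by id (clearing the objective if
#' it is dropped).
#'
#' @param model A `gem`.
#' @param id Reaction id(s).
#' @param lb,ub Optional new bound vectors (recycled).
#' @return The modified `gem`.
#' @export
gem_set_bounds <- function(model, id, lb = NULL, ub = NULL) {
  i <- rxn_index(model, id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model$reactions$reversible[i] <- model$reactions$lower_bound[i] < 0
  model
}

#' @rdname gem_set_bounds
#' @param rxns A [reaction_tbl()] of rows to append.
#' @param metabolites Optional [metabolite_tbl()] for new species.
#' @export
gem_add_reactions <- function(model, rxns, metabolites = NULL) {
  new_ids <- setdiff(unique(unlist(map(rxns$stoichiometry, names))),
                     model$metabolites$id)
  if (!is.null(metabolites)) {
    metabolites <- metabolites[metabolites$id %in% new_ids, , drop = FALSE]
    new_ids <- setdiff(new_ids, metabolites$id)
    model$metabolites <- bind_rows(model$metabolites, metabolites)
  }
  if (length(new_ids))
    model$metabolites <- bind_rows(model$metabolites, metabolite_tbl(new_ids))
  model$reactions <- bind_rows(model$reactions, rxns)
  model$reactions$kind <- classify_reactions(model)
  validate_gem(model)
  model
}

#' @rdname gem_set_bounds
#' @export
gem_drop_reactions <- function(model, id) {
  model$reactions <- model$reactions[!model$reactions$id %in% id, , drop = FALSE]
  if (!is.null(model$objective_id) && model$objective_id %in% id)
    model$objective_id <- NULL
  model
}

## exchange reactions together with the single extracellular species each
## one touches
exchange_table <- function(model) {
  ex <- model$reactions[model$reactions$kind == "exchange", , drop = FALSE]
  tibble(id = ex$id,
         metabolite = map_chr(ex$stoichiometry, function(st) {
           if (length(st) != 1L)
             abort(paste0("exchange reaction with ", length(st),
                          " metabolites"))
           names(st)
         }),
         lower_bound = ex$lower_bound, upper_bound = ex$upper_bound)
}
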