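## run code under a local, restored RNG state so one seed fixes everything
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic toy network
#'
#' Describes the study conditions a generated model emulates: a balanced
#' central-carbon core (glucose uptake, fermentative ATP production,
#' lactate overflow), essential nutrients with import-only routes, nutrients
#' synthesizable from glucose carbon, optional planted gaps, disconnected
#' islands and a polymer-leak motif. One seed fixes all randomness.
#'
#' @param n_core_metabolites Extra intermediate metabolites inserted into
#'   the essential-nutrient activation chains (distributed round-robin).
#' @param n_essential_nutrients Nutrients obtainable only by import.
#' @param n_synthesizable_nutrients Nutrients made internally from glucose.
#' @param n_planted_gaps Gaps to plant later via [plant_gaps()] (recorded,
#'   not applied here).
#' @param n_islands Extra disconnected two-metabolite components.
#' @param include_polymer_leak Add the polymer interconversion motif whose
#'   mismatched repeat counts make the closed model leak.
#' @param maintenance_atp Maintenance ATP coefficient of the biomass
#'   reaction (mmol/gDW).
#' @param seed Integer seed fixing all stochastic choices.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_core_metabolites = 2, n_essential_nutrients = 2,
                           n_synthesizable_nutrients = 1, n_planted_gaps = 0,
                           n_islands = 0, include_polymer_leak = FALSE,
                           maintenance_atp = 2, seed = 1) {
  spec <- list(n_core_metabolites = n_core_metabolites,
               n_essential_nutrients = n_essential_nutrients,
               n_synthesizable_nutrients = n_synthesizable_nutrients,
               n_planted_gaps = n_planted_gaps, n_islands = n_islands,
               include_polymer_leak = include_polymer_leak,
               maintenance_atp = maintenance_atp, seed = seed)
  counts <- unlist(spec[c("n_core_metabolites", "n_essential_nutrients",
                          "n_synthesizable_nutrients", "n_planted_gaps",
                          "n_islands")])
  if (any(counts < 0) || maintenance_atp < 0)
    abort("all synthetic_spec counts must be >= 0")
  structure(spec, class = "synthetic_spec")
}

#' Generate a toy metabolic model with recorded ground truth
#'
#' Builds a balanced network around a glucose/ATP core: every essential
#' nutrient has an import-only route (exchange, transport, activation
#' chain), every synthesizable nutrient an internal source from glucose
#' carbon, and a biomass reaction consumes the activated precursors plus
#' maintenance ATP. Feed-class uptake is bounded at 5 mmol/gDW/h, so the
#' analytic biomass optimum is the Liebig-style minimum of
#' `uptake_i / coefficient_i` over essential nutrients and of the shared
#' glucose budget `5 / (maintenance/2 + sum of synthesizable
#' coefficients)`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `model` (a `gem`, biomass objective attached, bound
#'   policy applied) and `truth`: the analytic biomass optimum, expected
#'   per-nutrient requirements at biomass rate 1, expected number of
#'   weakly connected components, removable gap-site reactions per
#'   essential route, and the decoy pool used by [plant_gaps()].
#' @export
make_toy_gem <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    nE <- spec$n_essential_nutrients
    nS <- spec$n_synthesizable_nutrients
    m <- spec$maintenance_atp
    if (nE == 0 && nS == 0 && m == 0)
      abort("biomass needs at least one precursor: set nutrients or maintenance")

    mets <- bind_rows(
      metabolite_tbl(c("glc[e]", "glc[c]"), name = "glucose",
                     formula = "C6H12O6"),
      metabolite_tbl(c("h2o[e]", "h2o[c]"), name = "water", formula = "H2O"),
      metabolite_tbl("atp[c]", name = "ATP", formula = "C10H16N5O13P3"),
      metabolite_tbl("adp[c]", name = "ADP", formula = "C10H15N5O10P2"),
      metabolite_tbl("pi[c]", name = "phosphate", formula = "H3O4P"),
      metabolite_tbl(c("lac[e]", "lac[c]"), name = "lactate",
                     formula = "C3H6O3"),
      metabolite_tbl(c("h[e]", "h[c]"), name = "proton", formula = "H"),
      metabolite_tbl("oh[c]", name = "hydroxide", formula = "OH"))

    ko_counter <- 0L; gene_counter <- 0L
    next_ko <- function() { ko_counter <<- ko_counter + 1L
      sprintf("K%05d", ko_counter) }
    next_genes <- function() {
      k <- sample(1:2, 1)
      gene_counter <<- gene_counter + k
      sprintf("UG%04d", seq_len(k) + gene_counter - k)
    }

    core_genes <- rep(list(character(0)), 10)
    core_kos <- rep(list(character(0)), 10)
    core_genes[[3]] <- next_genes(); core_kos[[3]] <- next_ko()   # GLYC
    core_genes[[8]] <- next_genes(); core_kos[[8]] <- next_ko()   # WATER_DISS
    core <- reaction_tbl(
      id = c("EX_glc", "T_glc", "GLYC", "EX_h2o", "T_h2o",
             "T_lac", "EX_lac", "WATER_DISS", "T_h", "EX_h"),
      genes = core_genes, ko_ids = core_kos,
      equation = c(
        "glc[e] <=> ", "glc[e] <=> glc[c]",
        "glc[c] + 2 adp[c] + 2 pi[c] => 2 lac[c] + 2 atp[c] + 2 h2o[c]",
        "h2o[e] <=> ", "h2o[e] <=> h2o[c]",
        "lac[c] => lac[e]", "lac[e] => ",
        "h2o[c] <=> h[c] + oh[c]",
        "h[c] => h[e]", "h[e] => "),
      pathway = c("glucose uptake", "glucose uptake", "central carbon",
                  "water transport", "water transport", "central carbon",
                  "central carbon", "water transport", "proton export",
                  "proton export"),
      subsystem = "carbohydrate metabolism")

    rxns <- core
    biomass_terms <- numeric(0)
    requirements <- tibble(nutrient = character(0), exchange = character(0),
                           requirement = numeric(0),
                           class = character(0))
    route_reactions <- list()

    ## essential nutrients: import-only chains with >= 1 activation step
    extra <- if (nE > 0) tabulate((seq_len(spec$n_core_metabolites) - 1L) %% nE + 1L,
                                  nbins = nE) else integer(0)
    for (i in seq_len(nE)) {
      base <- paste0("ess", i)
      formula <- sprintf("C%dH%dNO%d", 3 + i %% 4, 5 + 2 * (i %% 4), 2 + i %% 3)
      chain <- c(paste0(base, "[c]"),
                 if (extra[i] > 0) paste0(base, "_m", seq_len(extra[i]), "[c]"),
                 paste0(base, "act[c]"))
      mets <- bind_rows(mets,
        metabolite_tbl(paste0(base, "[e]"), name = base, formula = formula),
        metabolite_tbl(chain, name = base, formula = formula))
      step_ids <- paste0("ACT_", base,
                         if (length(chain) > 2) paste0("_", seq_len(length(chain) - 1))
                         else "")
      route <- reaction_tbl(
        id = c(paste0("EX_", base), paste0("T_", base), step_ids),
        equation = c(paste0(base, "[e] <=> "),
                     paste0(base, "[e] <=> ", base, "[c]"),
                     paste0(chain[-length(chain)], " => ", chain[-1])),
        genes = c(list(character(0), next_genes()),
                  map(step_ids, function(...) next_genes())),
        ko_ids = c(list(character(0), list(next_ko())[[1]]),
                   map(step_ids, function(...) next_ko())),
        pathway = paste0(base, " biosynthesis"),
        subsystem = "amino acid metabolism")
      rxns <- bind_rows(rxns, route)
      b <- round(stats::runif(1, 0.5, 2), 3)
      biomass_terms[paste0(base, "act[c]")] <- -b
      requirements <- bind_rows(requirements,
        tibble(nutrient = base, exchange = paste0("EX_", base),
               requirement = b, class = "essential"))
      route_reactions[[base]] <- c(paste0("T_", base), step_ids)
    }

    ## synthesizable nutrients: internal source from glucose carbon,
    ## export-only transfer reactions (cannot be obtained from the feed)
    for (j in seq_len(nS)) {
      base <- paste0("syn", j)
      mets <- bind_rows(mets,
        metabolite_tbl(paste0(base, c("[c]", "[e]")), name = base,
                       formula = "C6H12O6"))
      rxns <- bind_rows(rxns, reaction_tbl(
        id = c(paste0("SYNTH_", base), paste0("T_", base), paste0("EX_", base)),
        equation = c(paste0("glc[c] => ", base, "[c]"),
                     paste0(base, "[c] => ", base, "[e]"),
                     paste0(base, "[e] => ")),
        genes = c(list(next_genes()), list(character(0)), list(character(0))),
        ko_ids = c(list(next_ko()), list(character(0)), list(character(0))),
        pathway = paste0(base, " synthesis"),
        subsystem = "carbohydrate metabolism"))
      cj <- round(stats::runif(1, 0.1, 0.8), 3)
      biomass_terms[paste0(base, "[c]")] <- -cj
      requirements <- bind_rows(requirements,
        tibble(nutrient = base, exchange = paste0("EX_", base),
               requirement = 0, class = "synthesizable"))
    }

    ## disconnected islands
    for (k in seq_len(spec$n_islands)) {
      a <- paste0("iso", k, "a[c]"); b2 <- paste0("iso", k, "b[c]")
      mets <- bind_rows(mets, metabolite_tbl(c(a, b2)))
      rxns <- bind_rows(rxns, reaction_tbl(paste0("ISO_", k),
        paste0(a, " => ", b2), genes = list(next_genes()),
        ko_ids = list(next_ko()), pathway = paste0("island ", k),
        subsystem = "orphan"))
    }

    ## polymer-leak motif: interconversion of two polymeric species with
    ## mismatched repeat counts plus a water-releasing pseudo-cycle
    if (spec$include_polymer_leak) {
      mets <- bind_rows(mets,
        metabolite_tbl(c("starch[c]", "amylose[c]", "wgenA[c]", "wgenB[c]"),
                       name = c("(C12H20O10)n", "(C6H10O5)n",
                                "polymer remnant A", "polymer remnant B"),
                       formula = "UNKNOWN"))
      rxns <- bind_rows(rxns, polymer_pair_reactions())
    }

    ## biomass + maintenance ATP hydrolysis
    if (m > 0)
      biomass_terms[c("atp[c]", "h2o[c]", "adp[c]", "pi[c]")] <-
        c(-m, -m, m, m)
    biomass_terms["biomass[c]"] <- 1
    mets <- bind_rows(mets, metabolite_tbl("biomass[c]", name = "biomass"))
    biomass <- reaction_tbl("BIOMASS", format_equation(biomass_terms, FALSE),
                            kind = "biomass")
    dm <- reaction_tbl("DM_biomass", "biomass[c] => ", kind = "demand")
    rxns <- bind_rows(rxns, biomass, dm)

    model <- gem(mets, rxns, objective = "BIOMASS")
    ess_e <- if (nE > 0) paste0("ess", seq_len(nE), "[e]") else character(0)
    syn_e <- if (nS > 0) paste0("syn", seq_len(nS), "[e]") else character(0)
    classes <- c("glc[e]" = "feed", "h2o[e]" = "feed",
                 setNames(rep("feed", nE), ess_e),
                 setNames(rep("synthesizable", nS + 2),
                          c(syn_e, "lac[e]", "h[e]")))
    pol <- bounds_policy(overrides = list("EX_h2o" = c(-1000, 1000),
                                          "BIOMASS" = c(0, 1000)))
    model <- apply_policy(model, pol, classes)

    ess <- requirements[requirements$class == "essential", , drop = FALSE]
    syn_load <- if (nS > 0)
      sum(-biomass_terms[paste0("syn", seq_len(nS), "[c]")]) else 0
    glc_per_biomass <- m / 2 + (if (nS > 0) syn_load else 0)
    limits <- c(if (nE > 0) 5 / ess$requirement,
                if (glc_per_biomass > 0) 5 / glc_per_biomass,
                1000)
    requirements <- bind_rows(requirements,
      tibble(nutrient = "glc", exchange = "EX_glc",
             requirement = glc_per_biomass, class = "carbon_source"))

    ## without synthesizable nutrients or maintenance ATP the biomass
    ## reaction shares no species with the glucose core, adding one WCC
    split_core <- nS == 0 && m == 0
    precursors <- setdiff(names(biomass_terms)[biomass_terms < 0],
                          c("atp[c]", "h2o[c]"))
    truth <- list(
      biomass_optimum = min(limits),
      requirements = requirements,
      n_wcc = 1L + spec$n_islands + as.integer(split_core),
      producible = c(precursors, "biomass[c]", if (m > 0) "lac[c]"),
      route_reactions = route_reactions,
      nutrient_classes = classes,
      policy = pol,
      spec = spec)
    list(model = model, truth = truth)
  })
}

polymer_pair_reactions <- function() {
  reaction_tbl(
    id = c("R02110", "R02109", "WGEN1", "WGEN2"),
    equation = c("starch[c] <=> amylose[c]",
                 "amylose[c] + h2o[c] <=> starch[c] + glc[c]",
                 "wgenA[c] <=> wgenB[c] + h2o[c]",
                 "wgenB[c] <=> wgenA[c]"),
    pathway = "starch and sucrose metabolism",
    subsystem = "carbohydrate metabolism")
}

#' A minimal polymer-leak fixture
#'
#' A small synthetic network reproducing the classic leak pattern: two
#' polymeric species with an indeterminate repeat count (`UNKNOWN`
#' formulas) interconvert 1:1 while one direction also releases glucose,
#' so the closed model creates glucose from nothing once water is
#' available internally. Closing the two polymer reactions
#' (lb = ub = 0) removes every leak.
#'
#' @return A `gem` with a single glucose exchange.
#' @export
polymer_leak_gem <- function() {
  mets <- bind_rows(
    metabolite_tbl(c("glc[e]", "glc[c]"), name = "glucose",
                   formula = "C6H12O6"),
    metabolite_tbl("h2o[c]", name = "water", formula = "H2O"),
    metabolite_tbl(c("starch[c]", "amylose[c]", "wgenA[c]", "wgenB[c]"),
                   name = c("(C12H20O10)n", "(C6H10O5)n",
                            "polymer remnant A", "polymer remnant B"),
                   formula = "UNKNOWN"))
  rxns <- bind_rows(
    reaction_tbl(c("EX_glc", "T_glc"),
                 c("glc[e] <=> ", "glc[e] <=> glc[c]"),
                 pathway = "glucose uptake",
                 subsystem = "carbohydrate metabolism"),
    polymer_pair_reactions())
  gem(mets, rxns)
}

#' Plant gaps on biomass-essential routes
#'
#' Removes `n` reactions, each from a different essential-nutrient route,
#' and places them (plus decoys) in a companion pool. Because every
#' essential precursor enters the biomass reaction, the gapped model's
#' biomass optimum drops to zero until the gaps are refilled.
#'
#' @param generated The list returned by [make_toy_gem()].
#' @param n Number of gaps (at most the number of essential routes).
#' @param seed Seed for the gap-site choice.
#' @return List with `model` (gapped), `pool` (an [as_pool()] table of the
#'   removed reactions plus decoy entries), `removed` (ids),
#'   `targets` (the biomass precursors blocked by each gap) and `truth`
#'   carried over.
#' @export
plant_gaps <- function(generated, n, seed = 1) {
  model <- generated$model; truth <- generated$truth
  routes <- truth$route_reactions
  if (n > length(routes))
    abort(paste0("cannot plant ", n, " gaps: only ", length(routes),
                 " essential routes"))
  with_seed(seed, {
    picked_routes <- sample(names(routes), n)
    removed <- map_chr(picked_routes, function(r) {
      cand <- sort(routes[[r]])
      cand[sample(length(cand), 1)]
    })
    rows <- model$reactions[rxn_index(model, removed), , drop = FALSE]
    pool_rows <- tibble(
      reaction_id = rows$id,
      equation = map2_chr(rows$stoichiometry, rows$reversible,
                          format_equation),
      ko_ids = rows$ko_ids, pathway = rows$pathway,
      subsystem = rows$subsystem)
    decoys <- tibble(
      reaction_id = paste0("DECOY_", 1:3),
      equation = c("dec1[c] => dec2[c]", "dec2[c] => dec3[c]",
                   "dec3[c] <=> dec1[c]"),
      ko_ids = list(character(0), character(0), character(0)),
      pathway = "decoy pathway", subsystem = "decoy")
    model <- gem_drop_reactions(model, removed)
    targets <- paste0(picked_routes, "act[c]")
    list(model = model, pool = as_pool(bind_rows(pool_rows, decoys)),
         removed = sort(removed), targets = targets, truth = truth)
  })
}

#' Derive a universal pool from a model's metabolic reactions
#'
#' Serializes the cytosolic (metabolic) reactions of a model into the
#' tabular pool format, carrying KO ids and annotation -- the companion
#' input that [build_draft()] matches a KO table against.
#'
#' @param model A `gem`.
#' @return An [as_pool()] table.
#' @export
gem_to_pool <- function(model) {
  rows <- model$reactions[model$reactions$kind == "metabolic", , drop = FALSE]
  as_pool(tibble(
    reaction_id = rows$id,
    equation = map2_chr(rows$stoichiometry, rows$reversible, format_equation),
    ko_ids = rows$ko_ids, pathway = rows$pathway,
    subsystem = rows$subsystem))
}

#' Emit a unigene-to-KO annotation table covering part of a model
#'
#' Writes one (unigene, KO) row per gene of each covered reaction; a
#' `dropout` fraction of the KO-bearing reactions is left uncovered, so
#' [build_draft()] on the result reproduces exactly the covered subset.
#' The covered reaction ids are recorded in the `covered` attribute.
#'
#' @param model A `gem` whose reactions carry genes and KO ids.
#' @param dropout Fraction in `[0, 1)` of KO-bearing reactions to omit.
#' @param seed Seed for the dropout choice.
#' @return A tibble `unigene_id`, `ko_id` with attribute `covered`.
#' @export
make_ko_table <- function(model, dropout = 0, seed = 1) {
  stopifnot(dropout >= 0, dropout < 1)
  has_ko <- map_lgl(model$reactions$ko_ids, function(k) length(k) > 0) &
    model$reactions$kind == "metabolic"
  ids <- model$reactions$id[has_ko]
  with_seed(seed, {
    n_drop <- floor(dropout * length(ids))
    dropped <- if (n_drop > 0) sample(ids, n_drop) else character(0)
    covered <- setdiff(ids, dropped)
    rows <- map(covered, function(id) {
      i <- rxn_index(model, id)
      genes <- model$reactions$genes[[i]]
      if (length(genes) == 0L) genes <- paste0("UGX_", id)
      tidyr::expand_grid(unigene_id = genes,
                         ko_id = model$reactions$ko_ids[[i]])
    })
    out <- distinct(bind_rows(rows))
    attr(out, "covered") <- sort(covered)
    out
  })
}

#' Generate a random biomass composition for a model
#'
#' Draws positive contents for the model's biomass precursors so that the
#' non-water mass is at most `(1 - water_fraction) * 100` g per 100 g
#' fresh weight, assigns composition classes and samples molar masses
#' from the shipped constants table.
#'
#' @param model A `gem` with a biomass reaction (its negative terms,
#'   minus maintenance species, define the components), or any model --
#'   without a biomass reaction an empty table is returned.
#' @param water_fraction Water fraction of fresh weight.
#' @param seed Seed.
#' @return A [biomass_composition()] tibble.
#' @export
make_composition <- function(model, water_fraction = 0.516, seed = 1) {
  bm <- which(model$reactions$kind == "biomass")
  comps <- character(0)
  if (length(bm)) {
    st <- model$reactions$stoichiometry[[bm[1]]]
    comps <- setdiff(names(st)[st < 0],
                     c("atp[c]", "h2o[c]", "adp[c]", "pi[c]"))
  }
  if (length(comps) == 0L)
    return(biomass_composition(
      tibble(component = character(0), class = character(0),
             content = numeric(0), molar_mass = numeric(0)),
      water_fraction))
  with_seed(seed, {
    raw <- stats::runif(length(comps), 0.5, 1)
    content <- raw / sum(raw) * (1 - water_fraction) * 100 *
      stats::runif(1, 0.8, 1)
    biomass_composition(tibble(
      component = comps,
      class = sample(c("amino_acid", "fatty_acid", "mineral", "saccharide"),
                     length(comps), replace = TRUE),
      content = content,
      molar_mass = sample(molar_mass_table$molar_mass, length(comps),
                          replace = TRUE)),
      water_fraction)
  })
}
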