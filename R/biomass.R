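#' Convert a measured content into a biomass coefficient
#'
#' Measured composition is reported in g per 100 g fresh weight; biomass
#' coefficients are mmol per g dry weight. The dry-weight basis is
#' obtained by removing the water fraction, and the molar conversion uses
#' the molar mass of the measured form:
#' `(content / 100) / (1 - water_fraction) / molar_mass * 1000`
#' (i.e. mg per gDW divided by mg per mmol).
#'
#' @param content g per 100 g fresh weight (>= 0).
#' @param molar_mass g/mol of the measured form (> 0).
#' @param water_fraction Fraction of fresh weight that is water, in
#'   `[0, 1)`; juvenile crab hepatopancreas is about 0.516.
#' @return Coefficient in mmol/gDW.
#' @examples
#' content_to_coefficient(4.84, 100, 0.516) # 1 mmol/gDW
#' @export
content_to_coefficient <- function(content, molar_mass, water_fraction) {
  stopifnot(all(content >= 0), all(molar_mass > 0))
  if (any(water_fraction >= 1) || any(water_fraction < 0))
    abort("water_fraction must lie in [0, 1)")
  (content / 100) / (1 - water_fraction) / molar_mass * 1000
}

#' Assemble a biomass composition table
#'
#' @param components Data frame with columns `component` (metabolite id of
#'   the precursor in the model), `class` (`amino_acid`, `fatty_acid`,
#'   `mineral`, `saccharide`, `other`), `content` (g per 100 g fresh
#'   weight) and `molar_mass` (g/mol of the measured form).
#' @param water_fraction Fraction of fresh weight that is water.
#' @return A `biomass_composition` tibble (the input, validated, with the
#'   water fraction attached as an attribute).
#' @export
biomass_composition <- function(components, water_fraction = 0.516) {
  x <- as_tibble(components)
  need <- c("component", "class", "content", "molar_mass")
  if (!all(need %in% names(x)))
    abort(paste0("composition needs columns: ", paste(need, collapse = ", ")))
  stopifnot(all(x$content >= 0), all(x$molar_mass > 0))
  if (water_fraction <= 0 || water_fraction >= 1)
    abort("water_fraction must lie in (0, 1)")
  bad <- !x$class %in% c("amino_acid", "fatty_acid", "mineral", "saccharide",
                         "other")
  if (any(bad))
    abort(paste0("unknown composition class: ",
                 paste(unique(x$class[bad]), collapse = ", ")))
  attr(x, "water_fraction") <- water_fraction
  class(x) <- c("biomass_composition", class(x))
  x
}

#' Build the biomass reaction from a composition table
#'
#' Each precursor is consumed at the coefficient given by
#' [content_to_coefficient()]; maintenance ATP is consumed with hydrolysis
#' stoichiometry (ATP + H2O -> ADP + Pi); and exactly 1 g dry weight of
#' the biomass pseudo-metabolite is produced.
#'
#' @param composition A [biomass_composition()].
#' @param maintenance_atp Maintenance ATP coefficient in mmol/gDW
#'   (0 disables the maintenance terms).
#' @param id Reaction id for the biomass reaction.
#' @param biomass_met Id of the produced biomass pseudo-metabolite.
#' @param atp,h2o,adp,pi Metabolite ids used for the maintenance terms.
#' @return A list: `coefficients` (tibble `component`, `coefficient` in
#'   mmol/gDW), `maintenance` (named vector), and `reaction` (a
#'   [reaction_tbl()] row ready for [attach_objective()]).
#' @export
build_biomass <- function(composition, maintenance_atp = 30,
                          id = "BIOMASS", biomass_met = "biomass[c]",
                          atp = "atp[c]", h2o = "h2o[c]", adp = "adp[c]",
                          pi = "pi[c]") {
  stopifnot(inherits(composition, "biomass_composition"))
  w <- attr(composition, "water_fraction")
  coef <- content_to_coefficient(composition$content,
                                 composition$molar_mass, w)
  st <- setNames(-coef, composition$component)
  st <- st[st != 0]
  maintenance <- numeric(0)
  if (maintenance_atp > 0) {
    maintenance <- setNames(c(-maintenance_atp, -maintenance_atp,
                              maintenance_atp, maintenance_atp),
                            c(atp, h2o, adp, pi))
    for (m in names(maintenance))
      st[m] <- (if (m %in% names(st)) st[[m]] else 0) + maintenance[[m]]
  }
  st[biomass_met] <- 1
  rxn <- reaction_tbl(id, format_equation(st, reversible = FALSE),
                      kind = "biomass")
  list(coefficients = tibble(component = composition$component,
                             class = composition$class,
                             coefficient = coef),
       maintenance = maintenance,
       water_fraction = w,
       reaction = rxn)
}

#' Attach a biomass reaction as the model objective
#'
#' Adds the biomass reaction plus a demand draining the biomass
#' pseudo-metabolite, and selects the biomass reaction as objective.
#' Errors if a biomass reaction is already present or if any precursor is
#' missing from the model (all missing ids are listed).
#'
#' @param model A `gem`.
#' @param biomass Either the list returned by [build_biomass()] or a
#'   one-row [reaction_tbl()] with `kind = "biomass"`.
#' @return The model with the biomass reaction attached and
#'   `objective_id` set.
#' @export
attach_objective <- function(model, biomass) {
  rxn <- if (is.data.frame(biomass)) biomass else biomass$reaction
  if (any(model$reactions$kind == "biomass"))
    abort("model already contains a biomass reaction")
  st <- rxn$stoichiometry[[1]]
  produced <- names(st)[st > 0]
  precursors <- names(st)[st < 0]
  missing <- setdiff(precursors, model$metabolites$id)
  if (length(missing))
    abort(paste0("biomass precursor(s) missing from model: ",
                 paste(missing, collapse = ", ")))
  model <- gem_add_reactions(model, rxn)
  model$reactions$kind[model$reactions$id == rxn$id] <- "biomass"
  bm <- produced[!produced %in% precursors][1]
  dm_id <- paste0("DM_", met_base(bm))
  if (!dm_id %in% model$reactions$id) {
    dm <- reaction_tbl(dm_id, paste0(bm, " => "), kind = "demand")
    model <- gem_add_reactions(model, dm)
  }
  model$objective_id <- rxn$id
  validate_gem(model)
  model
}
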