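#' Molar masses of common biomass precursors and feed carriers
#'
#' Average molar masses (g/mol) used when converting measured contents
#' (g per 100 g fresh weight, percent of feed, g/kg or mg/kg feed) into
#' mmol per gram dry weight. Amino acids and fatty acids are the free
#' (protonated) forms; minerals are listed both as elements and as the
#' carrier compounds that feeding trials typically report (calcium
#' carbonate, magnesium L-aspartate, zinc methionine and so on), because
#' literature demands are expressed in the carrier's mass units.
#'
#' @format A tibble with columns `compound`, `class`
#'   (`amino_acid`, `fatty_acid`, `mineral`, `carrier`, `saccharide`, `other`),
#'   `molar_mass` (g/mol) and `note`.
#'
#' @details The eicosapentaenoic acid (EPA) entry is the free acid
#'   (302.45 g/mol); reported feed conversions for EPA are sometimes based
#'   on an unstated esterified carrier, so conversions for EPA should be
#'   interpreted with care.
#' @export
molar_mass_table <- tibble::tibble(
  compound = c(
    "glycine", "alanine", "serine", "proline", "valine", "threonine",
    "cysteine", "leucine", "isoleucine", "asparagine", "aspartate",
    "glutamine", "lysine", "glutamate", "methionine", "histidine",
    "phenylalanine", "arginine", "tyrosine", "tryptophan",
    "lauric acid", "myristic acid", "palmitic acid", "palmitoleic acid",
    "stearic acid", "oleic acid", "linoleic acid", "alpha-linolenic acid",
    "gamma-linolenic acid", "arachidonic acid", "EPA", "DHA",
    "calcium", "magnesium", "zinc", "selenium", "copper", "iron",
    "manganese", "phosphorus", "potassium",
    "calcium carbonate", "magnesium L-aspartate",
    "glucose", "glycogen unit"
  ),
  class = c(
    rep("amino_acid", 20),
    rep("fatty_acid", 12),
    rep("mineral", 9),
    rep("carrier", 2),
    rep("saccharide", 2)
  ),
  molar_mass = c(
    75.07, 89.09, 105.09, 115.13, 117.15, 119.12,
    121.16, 131.17, 131.17, 132.12, 133.10,
    146.15, 146.19, 147.13, 149.21, 155.15,
    165.19, 174.20, 181.19, 204.23,
    200.32, 228.37, 256.42, 254.41,
    284.48, 282.46, 280.45, 278.43,
    278.43, 304.47, 302.45, 328.49,
    40.08, 24.305, 65.38, 78.97, 63.55, 55.845,
    54.938, 30.974, 39.098,
    100.09, 155.39,
    180.16, 162.14
  ),
  note = c(
    rep("free amino acid", 20),
    rep("free fatty acid", 30 - 20), "free acid (esterified carriers differ)",
    "free fatty acid",
    rep("element", 9),
    "Ca carrier in feeds", "Mg carrier in feeds (monomagnesium salt)",
    "monosaccharide", "anhydroglucose unit of glycogen/starch"
  )
)

#' Look up a molar mass by compound name
#'
#' @param compound Character vector of compound names matching
#'   `molar_mass_table$compound` (case-insensitive).
#' @return Numeric vector of molar masses (g/mol); `NA` where unknown.
#' @examples
#' molar_mass(c("lysine", "DHA"))
#' @export
molar_mass <- function(compound) {
  idx <- match(tolower(compound), tolower(molar_mass_table$compound))
  molar_mass_table$molar_mass[idx]
}

#' Literature feed demands for essential amino acids of juvenile
#' *Eriocheir sinensis*
#'
#' Recommended dietary contents of the ten essential amino acids for
#' juvenile Chinese mitten crab, collected from published feeding trials,
#' expressed as percent of feed together with the molar mass of the free
#' amino acid used for unit conversion.
#'
#' @format Tibble with columns `nutrient`, `value`, `unit`
#'   (`percent_of_feed`), `carrier`, `carrier_molar_mass` (g/mol).
#' @seealso [literature_to_mmol()]
#' @export
essential_aa_demands <- tibble::tibble(
  nutrient = c("arginine", "lysine", "methionine", "leucine", "isoleucine",
               "histidine", "phenylalanine", "threonine", "tryptophan",
               "valine"),
  value = c(3.62, 2.34, 1.12, 2.36, 2.25, 0.864, 1.963, 1.59, 0.182, 1.504),
  unit = "percent_of_feed",
  carrier = nutrient,
  carrier_molar_mass = c(174.20, 146.19, 149.21, 131.17, 131.17,
                         155.15, 165.19, 119.12, 204.23, 117.15)
)

#' Literature feed demands for essential fatty acids of juvenile
#' *Eriocheir sinensis*
#'
#' @format Tibble in the same layout as [essential_aa_demands].
#' @export
fatty_acid_demands <- tibble::tibble(
  nutrient = c("linoleic acid", "linolenic acid", "EPA", "DHA"),
  value = c(2.79, 0.95, 0.28, 0.53),
  unit = "percent_of_feed",
  carrier = nutrient,
  carrier_molar_mass = c(280.45, 278.43, 302.45, 328.49)
)

#' Literature feed demands for mineral elements of juvenile
#' *Eriocheir sinensis*
#'
#' Calcium and magnesium demands are published as carrier-compound
#' contents (calcium carbonate, magnesium L-aspartate), so conversion uses
#' the carrier molar mass; zinc, selenium and copper are published as
#' elemental contents.
#'
#' @format Tibble in the same layout as [essential_aa_demands].
#' @export
mineral_demands <- tibble::tibble(
  nutrient = c("calcium", "magnesium", "zinc", "selenium", "copper"),
  value = c(2.9, 3.76, 20, 0.59, 24.66),
  unit = c("percent_of_feed", "g_per_kg", "mg_per_kg", "mg_per_kg",
           "mg_per_kg"),
  carrier = c("calcium carbonate", "magnesium L-aspartate", "zinc",
              "selenium", "copper"),
  carrier_molar_mass = c(100.09, 155.39, 65.38, 78.97, 63.55)
)
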