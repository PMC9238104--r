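#' Convert literature feed demands to mmol per gDW per hour
#'
#' Literature nutrient demands come as percent of feed, g/kg feed or
#' mg/kg feed of a carrier form (the free amino acid, calcium carbonate,
#' elemental zinc, ...). With the simulation convention of 1 g feed per
#' gDW per day, the conversions are all "mg per g feed divided by mg per
#' mmol": percent -> `value * 10 / carrier_molar_mass`;
#' g/kg -> `value / carrier_molar_mass`;
#' mg/kg -> `value / 1000 / carrier_molar_mass`.
#'
#' @param demands Data frame with columns `nutrient`, `value`, `unit`
#'   (`percent_of_feed`, `g_per_kg`, `mg_per_kg`) and
#'   `carrier_molar_mass` (g/mol of the measured form), as in
#'   [essential_aa_demands].
#' @return The input tibble with a `literature_mmol` column
#'   (mmol/gDW/h).
#' @examples
#' literature_to_mmol(essential_aa_demands)
#' @export
literature_to_mmol <- function(demands) {
  demands <- as_tibble(demands)
  stopifnot(all(demands$value >= 0), all(demands$carrier_molar_mass > 0))
  bad <- !demands$unit %in% c("percent_of_feed", "g_per_kg", "mg_per_kg")
  if (any(bad))
    abort(paste0("unknown demand unit(s): ",
                 paste(unique(demands$unit[bad]), collapse = ", ")))
  mg_per_g <- dplyr::case_when(
    demands$unit == "percent_of_feed" ~ demands$value * 10,
    demands$unit == "g_per_kg" ~ demands$value,
    demands$unit == "mg_per_kg" ~ demands$value / 1000)
  mutate(demands, literature_mmol = mg_per_g / demands$carrier_molar_mass)
}

#' Deposition rate of a nutrient
#'
#' The fraction of the total dietary requirement that is actually
#' incorporated into body mass: simulated uptake divided by the
#' literature demand (both in mmol/gDW/h). Undefined (NA) where the
#' literature demand is not positive; for display the package mirrors the
#' integer-percent convention via `round(100 * rate)`.
#'
#' @param simulated,literature Uptake rates in mmol/gDW/h.
#' @return Fractions (`simulated / literature`), NA where undefined.
#' @examples
#' round(100 * deposition_rate(0.0664, 0.1601)) # 41
#' @export
deposition_rate <- function(simulated, literature) {
  ifelse(literature > 0, simulated / literature, NA_real_)
}

#' Simulate optimal nutrient requirements at fixed biomass rate
#'
#' Fixes the biomass reaction at `biomass_rate` (lb = ub), optimizes, and
#' reads each nutrient's requirement off its exchange flux: uptake
#' (negative exchange flux) is reported positive; a nutrient that is net
#' exported at the optimum is reported negative and flagged as an
#' accumulation. With `parsimonious = TRUE` the flux distribution of
#' minimal total flux is used instead of a raw (degenerate) FBA optimum.
#'
#' @param model A `gem` with a biomass objective.
#' @param demands Optional literature demand table (see
#'   [literature_to_mmol()]) with an `exchange` or `nutrient` column
#'   matching exchange ids; when supplied, literature values and
#'   deposition rates are joined on.
#' @param biomass_rate Fixed biomass flux (gDW/h), default 1.
#' @param parsimonious Use [pfba()] instead of raw FBA.
#' @return A `requirement_table` tibble: `exchange`, `metabolite`,
#'   `simulated_mmol`, `accumulation`, and (when demands are given)
#'   `literature_mmol`, `deposition_rate`, `deposition_percent`.
#' @export
simulate_requirements <- function(model, demands = NULL, biomass_rate = 1,
                                  parsimonious = FALSE) {
  if (is.null(model$objective_id))
    abort("model has no biomass objective; attach one first")
  m <- gem_set_bounds(model, model$objective_id,
                      lb = biomass_rate, ub = biomass_rate)
  sol <- if (parsimonious) pfba(model, rate = biomass_rate)
         else fba(m, model$objective_id, "max")
  if (sol$status != "optimal")
    abort(paste0("model infeasible at biomass rate ", biomass_rate,
                 "; check precursor producibility"))
  ex <- exchange_table(model)
  flux <- sol$fluxes$flux[match(ex$id, sol$fluxes$id)]
  out <- tibble(exchange = ex$id, metabolite = ex$metabolite,
                simulated_mmol = -flux, accumulation = -flux < 0)
  if (!is.null(demands)) {
    demands <- literature_to_mmol(demands)
    if (!"exchange" %in% names(demands))
      demands$exchange <- paste0("EX_", demands$nutrient)
    out <- left_join(out,
                     select(demands, "exchange", nutrient = "nutrient",
                            literature_mmol = "literature_mmol"),
                     by = "exchange")
    out$deposition_rate <- deposition_rate(out$simulated_mmol,
                                           out$literature_mmol)
    out$deposition_percent <- round(100 * out$deposition_rate)
  }
  class(out) <- c("requirement_table", class(out))
  attr(out, "biomass_rate") <- biomass_rate
  out
}

#' Specific growth rate from a simulated biomass synthesis rate
#'
#' SGR is `[ln(m2) - ln(m1)] / (t2 - t1) * 100` percent per day. With a
#' daily feed ration between `feed_fraction_min` and `feed_fraction_max`
#' of body weight, a simulated dry-weight synthesis rate of `x` gDW per
#' day per gram of feed, and a water fraction `w` of fresh tissue, the
#' one-day fresh-weight gain is `f * m1 * x / (1 - w)`, giving
#' `SGR = [ln(m1 + f * m1 * x / (1 - w)) - ln(m1)] * 100`.
#'
#' @param x Simulated biomass synthesis rate (gDW per day per g feed).
#' @param m1 Initial fresh body mass (g); juvenile crabs average 8.41 g.
#' @param water_fraction Water fraction of fresh biomass (0.516).
#' @param feed_fraction_min,feed_fraction_max Daily feed as a fraction of
#'   body weight (3%-5% for juvenile crabs).
#' @return Tibble with one row: `x`, `sgr_min`, `sgr_max` (% per day).
#' @examples
#' sgr(0.1203) # about 0.74 - 1.24 % per day
#' @export
sgr <- function(x, m1 = 8.41, water_fraction = 0.516,
                feed_fraction_min = 0.03, feed_fraction_max = 0.05) {
  stopifnot(feed_fraction_min > 0, feed_fraction_min <= feed_fraction_max,
            water_fraction > 0, water_fraction < 1, m1 > 0, all(x >= 0))
  one <- function(f) (log(m1 + f * m1 * x / (1 - water_fraction)) - log(m1)) * 100
  tibble(x = x, sgr_min = one(feed_fraction_min),
         sgr_max = one(feed_fraction_max))
}

#' Maximum growth under a literature feed composition
#'
#' Sets each named nutrient's exchange lower bound to minus its
#' literature uptake rate (so the feed composition caps absorption),
#' maximizes biomass, and reports the achieved synthesis rate together
#' with each nutrient's offered vs absorbed amount -- the unabsorbed
#' remainder is what would be excreted into the water.
#'
#' @param model A `gem` with a biomass objective.
#' @param demands Literature demand table (see [literature_to_mmol()]);
#'   rows are matched to exchanges via an `exchange` column or
#'   `paste0("EX_", nutrient)`.
#' @return List with `rate` (gDW/h at the optimum) and `uptake`, a tibble
#'   `nutrient`, `exchange`, `offered`, `absorbed`, `unabsorbed`.
#' @export
growth_under_feed <- function(model, demands) {
  if (is.null(model$objective_id))
    abort("model has no biomass objective; attach one first")
  demands <- literature_to_mmol(demands)
  if (!"exchange" %in% names(demands))
    demands$exchange <- paste0("EX_", demands$nutrient)
  missing <- setdiff(demands$exchange, model$reactions$id)
  if (length(missing))
    abort(paste0("no exchange reaction for: ",
                 paste(missing, collapse = ", ")))
  for (i in seq_len(nrow(demands)))
    model <- gem_set_bounds(model, demands$exchange[i],
                            lb = -demands$literature_mmol[i])
  sol <- fba(model, model$objective_id, "max")
  if (sol$status != "optimal")
    abort(paste0("solver status ", sol$status, " under feed bounds"))
  flux <- sol$fluxes$flux[match(demands$exchange, sol$fluxes$id)]
  absorbed <- pmax(-flux, 0)
  uptake <- tibble(nutrient = demands$nutrient, exchange = demands$exchange,
                   offered = demands$literature_mmol, absorbed = absorbed,
                   unabsorbed = demands$literature_mmol - absorbed)
  list(rate = sol$objective_value, uptake = uptake)
}
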