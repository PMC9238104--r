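#' Tidy a model into a per-reaction tibble
#'
#' @param x A `gem`.
#' @param ... Unused.
#' @return One row per reaction: id, name, equation, bounds, kind,
#'   pathway, subsystem, gene and KO counts.
#' @method tidy gem
#' @export
tidy.gem <- function(x, ...) {
  tibble(id = x$reactions$id, name = x$reactions$name,
         equation = map2_chr(x$reactions$stoichiometry,
                             x$reactions$reversible, format_equation),
         lower_bound = x$reactions$lower_bound,
         upper_bound = x$reactions$upper_bound,
         kind = x$reactions$kind, pathway = x$reactions$pathway,
         subsystem = x$reactions$subsystem,
         n_genes = map_int(x$reactions$genes, length),
         n_kos = map_int(x$reactions$ko_ids, length))
}

#' Model-level summary in the style of a reconstruction feature table
#'
#' @param x A `gem`.
#' @param ... Unused.
#' @return One-row tibble: unigene, reaction (total and by kind),
#'   metabolite (by compartment), gene-reaction link, pathway and
#'   subsystem counts.
#' @method glance gem
#' @export
glance.gem <- function(x, ...) {
  kinds <- x$reactions$kind
  tibble(
    n_unigenes = length(unique(unlist(x$reactions$genes))),
    n_reactions = nrow(x$reactions),
    n_metabolic = sum(kinds == "metabolic"),
    n_transport = sum(kinds == "transport"),
    n_exchange = sum(kinds == "exchange"),
    n_demand = sum(kinds == "demand"),
    n_biomass = sum(kinds == "biomass"),
    n_metabolites = nrow(x$metabolites),
    n_cytosol = sum(x$metabolites$compartment == "c"),
    n_extracellular = sum(x$metabolites$compartment == "e"),
    n_gene_links = sum(map_int(x$reactions$genes, length) > 0),
    n_pathways = length(unique(stats::na.omit(x$reactions$pathway))),
    n_subsystems = length(unique(stats::na.omit(x$reactions$subsystem))))
}

#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(status = x$status, objective = x$objective, sense = x$sense,
         objective_value = x$objective_value,
         n_active = sum(abs(x$fluxes$flux) > 1e-9, na.rm = TRUE))
}

#' @method tidy connectivity_report
#' @export
tidy.connectivity_report <- function(x, ...) {
  bind_rows(imap(x$components, function(mets, i)
    tibble(component = i, metabolite = mets)))
}

#' @method glance connectivity_report
#' @export
glance.connectivity_report <- function(x, ...) {
  tibble(n_wcc = x$n_wcc,
         largest = max(c(0L, map_int(x$components, length))))
}

#' @method tidy gapfill_result
#' @export
tidy.gapfill_result <- function(x, ...) {
  bind_rows(imap(x$per_target, function(set, target)
    tibble(target = target,
           restored = !(length(set) == 1L && is.na(set[1])),
           added = list(if (length(set) == 1L && is.na(set[1]))
             character(0) else set))))
}

#' @method glance gapfill_result
#' @export
glance.gapfill_result <- function(x, ...) {
  tibble(scale = x$scale, n_added = length(x$added_reactions),
         n_restored = length(x$restored_targets),
         n_unrestored = length(x$unrestored))
}

#' @method tidy sanity_report
#' @export
tidy.sanity_report <- function(x, ...) {
  tibble(name = x$name, passed = x$passed,
         n_witnesses = map_int(x$witnesses, nrow), note = x$note)
}

#' @method glance sanity_report
#' @export
glance.sanity_report <- function(x, ...) {
  tibble(n_checks = nrow(x), n_passed = sum(x$passed, na.rm = TRUE),
         n_failed = sum(!x$passed, na.rm = TRUE),
         n_skipped = sum(is.na(x$passed)))
}

#' Sparsity pattern of the stoichiometric matrix
#'
#' @param object A `gem`.
#' @param ... Unused.
#' @return A ggplot showing the nonzero entries of S (metabolites x
#'   reactions), the usual visual fingerprint of a reconstruction.
#' @method autoplot gem
#' @export
autoplot.gem <- function(object, ...) {
  S <- stoichiometric_matrix(object)
  nz <- which(S != 0, arr.ind = TRUE)
  df <- tibble(metabolite = nz[, 1], reaction = nz[, 2],
               sign = ifelse(S[nz] > 0, "produced", "consumed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reaction,
                                   y = .data$metabolite,
                                   colour = .data$sign)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "reaction", y = "metabolite",
                  title = paste0("S: ", nrow(S), " x ", ncol(S),
                                 ", nz = ", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Flux distribution bar chart
#'
#' @param object A `flux_solution`.
#' @param top Number of largest-|flux| reactions to show.
#' @param ... Unused.
#' @method autoplot flux_solution
#' @export
autoplot.flux_solution <- function(object, top = 20, ...) {
  df <- arrange(object$fluxes, desc(abs(.data$flux)))
  df <- head(df[!is.na(df$flux) & abs(df$flux) > 1e-9, ], top)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$id, abs(.data$flux)),
                                   y = .data$flux, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (mmol/gDW/h)") +
    ggplot2::theme_minimal()
}

#' Sanity report overview plot
#'
#' @param object A `sanity_report`.
#' @param ... Unused.
#' @method autoplot sanity_report
#' @export
autoplot.sanity_report <- function(object, ...) {
  df <- tidy.sanity_report(object)
  df$status <- ifelse(is.na(df$passed), "skipped",
                      ifelse(df$passed, "pass", "fail"))
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(pass = "#2c7fb8", fail = "#d95f02",
                                          skipped = "grey70")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Literature vs simulated nutrient requirements
#'
#' @param object A `requirement_table` from [simulate_requirements()]
#'   with literature values joined.
#' @param ... Unused.
#' @method autoplot requirement_table
#' @export
autoplot.requirement_table <- function(object, ...) {
  if (!"literature_mmol" %in% names(object))
    abort("requirement table has no literature column to compare against")
  df <- tidyr::pivot_longer(
    select(filter(object, !is.na(.data$literature_mmol)),
           "exchange", "simulated_mmol", "literature_mmol"),
    cols = c("simulated_mmol", "literature_mmol"),
    names_to = "source", values_to = "mmol")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exchange, y = .data$mmol,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mmol/gDW/h") +
    ggplot2::theme_minimal()
}
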