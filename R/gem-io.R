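#' Read and write models in the package's canonical dialects
#'
#' The canonical on-disk form is a pair of TSV files
#' (`metabolites.tsv`, `reactions.tsv`) in one directory, with
#' stoichiometry encoded as `"id:coeff;id:coeff"` so models stay
#' diff-able and version-controllable. A single-file JSON dialect mirrors
#' it, and a best-effort SBML (level 3, with flux bounds and notes for
#' gene/pathway metadata) reader/writer interoperates with other
#' constraint-based tools. Saving then loading is the identity on ids,
#' stoichiometry and bounds in every dialect.
#'
#' @param model A `gem`.
#' @param path For `tsv`, a directory; for `json`/`sbml`, a file path.
#' @param dialect `"tsv"`, `"json"` or `"sbml"`; guessed from `path`
#'   (directory -> tsv, `.json` -> json, `.xml`/`.sbml` -> sbml) when
#'   missing.
#' @return `load_gem()` returns a validated `gem`; `save_gem()` returns
#'   `path` invisibly.
#' @examples
#' m <- gem(reactions = reaction_tbl("R1", "a[c] => b[c]"))
#' d <- file.path(tempdir(), "toy-model")
#' save_gem(m, d, "tsv")
#' m2 <- load_gem(d)
#' @name gem_io
NULL

guess_dialect <- function(path) {
  if (dir.exists(path) || !grepl("\\.[A-Za-z]+$", basename(path))) "tsv"
  else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
  else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
  else abort(paste0("cannot guess model dialect from path: ", path))
}

encode_stoich <- function(st)
  paste(names(st), format(unname(st), trim = TRUE, scientific = FALSE,
                          digits = 15), sep = ":", collapse = ";")

decode_stoich <- function(x, where = "stoichiometry") {
  if (is.na(x) || x == "") return(setNames(numeric(0), character(0)))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- map_int(kv, length) != 2L
  vals <- suppressWarnings(map_dbl(kv, function(p) as.numeric(p[2])))
  if (any(bad) || anyNA(vals))
    abort(paste0("malformed stoichiometry in ", where, ": '", x, "'"))
  setNames(vals, map_chr(kv, 1))
}

encode_ids <- function(lst) map_chr(lst, paste, collapse = "|")
decode_ids <- function(x) {
  map(x, function(s) {
    if (is.na(s) || s == "") character(0)
    else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

#' @rdname gem_io
#' @export
save_gem <- function(model, path, dialect = NULL) {
  validate_gem(model)
  dialect <- dialect %||% guess_dialect(path)
  switch(dialect,
    tsv = save_gem_tsv(model, path),
    json = save_gem_json(model, path),
    sbml = save_gem_sbml(model, path),
    abort(paste0("unknown dialect: ", dialect)))
  invisible(path)
}

#' @rdname gem_io
#' @export
load_gem <- function(path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  model <- switch(dialect,
    tsv = load_gem_tsv(path),
    json = load_gem_json(path),
    sbml = load_gem_sbml(path),
    abort(paste0("unknown dialect: ", dialect)))
  validate_gem(model)
  model
}

## ---- TSV ----

rxn_flat <- function(model) {
  tibble(id = model$reactions$id, name = model$reactions$name,
         stoichiometry = map_chr(model$reactions$stoichiometry, encode_stoich),
         lower_bound = model$reactions$lower_bound,
         upper_bound = model$reactions$upper_bound,
         reversible = model$reactions$reversible,
         genes = encode_ids(model$reactions$genes),
         ko_ids = encode_ids(model$reactions$ko_ids),
         pathway = model$reactions$pathway,
         subsystem = model$reactions$subsystem,
         kind = model$reactions$kind,
         objective = model$reactions$id %in% (model$objective_id %||% ""))
}

rxn_unflat <- function(flat) {
  rxns <- tibble(
    id = as.character(flat$id), name = as.character(flat$name),
    stoichiometry = imap(flat$stoichiometry,
                         function(s, i) decode_stoich(s, paste0("reaction row ", i,
                                                                " (", flat$id[i], ")"))),
    lower_bound = as.numeric(flat$lower_bound),
    upper_bound = as.numeric(flat$upper_bound),
    reversible = as.logical(flat$reversible),
    genes = decode_ids(flat$genes), ko_ids = decode_ids(flat$ko_ids),
    pathway = as.character(flat$pathway),
    subsystem = as.character(flat$subsystem),
    kind = as.character(flat$kind))
  objective <- flat$id[which(as.logical(flat$objective))]
  list(reactions = rxns,
       objective = if (length(objective)) objective[1] else NULL)
}

save_gem_tsv <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  readr::write_tsv(model$metabolites, file.path(path, "metabolites.tsv"))
  readr::write_tsv(rxn_flat(model), file.path(path, "reactions.tsv"))
}

load_gem_tsv <- function(path) {
  mf <- file.path(path, "metabolites.tsv"); rf <- file.path(path, "reactions.tsv")
  if (!file.exists(mf) || !file.exists(rf))
    abort(paste0("expected metabolites.tsv and reactions.tsv under ", path))
  mets <- readr::read_tsv(mf, col_types = readr::cols(
    id = "c", name = "c", formula = "c", charge = "i", compartment = "c"))
  flat <- readr::read_tsv(rf, col_types = readr::cols(
    id = "c", name = "c", stoichiometry = "c", lower_bound = "d",
    upper_bound = "d", reversible = "l", genes = "c", ko_ids = "c",
    pathway = "c", subsystem = "c", kind = "c", objective = "l"))
  mets$formula[is.na(mets$formula)] <- "UNKNOWN"
  r <- rxn_unflat(flat)
  structure(list(metabolites = mets, reactions = r$reactions,
                 objective_id = r$objective), class = "gem")
}

## ---- JSON ----

save_gem_json <- function(model, path) {
  obj <- list(metabolites = model$metabolites,
              reactions = rxn_flat(model),
              objective_id = model$objective_id)
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
}

load_gem_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mets <- as_tibble(obj$metabolites)
  if (!"charge" %in% names(mets)) mets$charge <- NA_integer_
  mets$charge <- as.integer(mets$charge)
  mets$formula[is.na(mets$formula)] <- "UNKNOWN"
  need <- c("name", "genes", "ko_ids", "pathway", "subsystem", "kind")
  flat <- as_tibble(obj$reactions)
  for (col in need) if (!col %in% names(flat)) flat[[col]] <- NA_character_
  if (!"objective" %in% names(flat))
    flat$objective <- flat$id %in% (obj$objective_id %||% "")
  r <- rxn_unflat(flat)
  structure(list(metabolites = mets, reactions = r$reactions,
                 objective_id = r$objective), class = "gem")
}

## ---- SBML (level 3, flux bounds as reaction attributes, metadata in notes) ----

sbml_note <- function(...) {
  kv <- c(...)
  kv <- kv[!is.na(kv) & kv != ""]
  paste(names(kv), kv, sep = "=", collapse = ";")
}

save_gem_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mod <- xml2::xml_add_child(doc, "model", id = "model")
  lc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cmp in unique(model$metabolites$compartment))
    xml2::xml_add_child(lc, "compartment", id = cmp, constant = "true")
  ls <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(ls, "species", id = m$id, name = m$name,
      compartment = m$compartment,
      constant = "false", boundaryCondition = "false",
      hasOnlySubstanceUnits = "false",
      notes = sbml_note(formula = m$formula,
                        charge = if (is.na(m$charge)) "" else as.character(m$charge)))
  }
  lr <- xml2::xml_add_child(mod, "listOfReactions")
  obj <- model$objective_id %||% ""
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(lr, "reaction", id = r$id, name = r$name,
      reversible = tolower(as.character(r$reversible)), fast = "false",
      lowerFluxBound = format(r$lower_bound, scientific = FALSE, digits = 15),
      upperFluxBound = format(r$upper_bound, scientific = FALSE, digits = 15),
      notes = sbml_note(genes = paste(r$genes[[1]], collapse = "|"),
                        ko_ids = paste(r$ko_ids[[1]], collapse = "|"),
                        pathway = r$pathway, subsystem = r$subsystem,
                        kind = r$kind,
                        objective = if (r$id == obj) "true" else ""))
    st <- r$stoichiometry[[1]]
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (k in seq_along(st)) {
      parent <- if (st[k] < 0) lre else lpr
      xml2::xml_add_child(parent, "speciesReference", species = names(st)[k],
        stoichiometry = format(abs(st[k]), scientific = FALSE, digits = 15),
        constant = "true")
    }
  }
  xml2::write_xml(doc, path)
}

parse_note <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(map_chr(kv, function(p) if (length(p) > 1) p[2] else ""),
           map_chr(kv, 1))
}

load_gem_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  notes <- map(xml2::xml_attr(sp, "notes"), parse_note)
  mets <- tibble(
    id = xml2::xml_attr(sp, "id"),
    name = xml2::xml_attr(sp, "name"),
    formula = map_chr(notes, function(n) n["formula"] %|na|% "UNKNOWN"),
    charge = as.integer(map_chr(notes, function(n) n["charge"] %|na|% NA)),
    compartment = xml2::xml_attr(sp, "compartment"))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rnotes <- map(xml2::xml_attr(rx, "notes"), parse_note)
  stoich <- map(rx, function(node) {
    take <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp)
      setNames(sign * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
               xml2::xml_attr(refs, "species"))
    }
    st <- c(take("./listOfReactants/speciesReference", -1),
            take("./listOfProducts/speciesReference", +1))
    st[st != 0]
  })
  note_col <- function(key) map_chr(rnotes, function(n) n[key] %|na|% NA)
  rxns <- tibble(
    id = xml2::xml_attr(rx, "id"), name = xml2::xml_attr(rx, "name"),
    stoichiometry = stoich,
    lower_bound = as.numeric(xml2::xml_attr(rx, "lowerFluxBound")),
    upper_bound = as.numeric(xml2::xml_attr(rx, "upperFluxBound")),
    reversible = xml2::xml_attr(rx, "reversible") == "true",
    genes = decode_ids(note_col("genes")),
    ko_ids = decode_ids(note_col("ko_ids")),
    pathway = note_col("pathway"), subsystem = note_col("subsystem"),
    kind = note_col("kind"))
  objective <- rxns$id[which(note_col("objective") == "true")]
  structure(list(metabolites = mets, reactions = rxns,
                 objective_id = if (length(objective)) objective[1] else NULL),
            class = "gem")
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x
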