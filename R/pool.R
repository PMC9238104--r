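#' Universal reaction pools
#'
#' A universal pool is the tabular reaction database (KEGG-like) that
#' draft reconstruction matches against and gap filling draws from: one
#' row per reaction with an equation string, the KEGG Orthology ids that
#' catalyse it, pathway/subsystem annotation, EC numbers and optional
#' curation flags (`general`, `incomplete`, ...).
#'
#' @param x A data frame with at least `reaction_id` and `equation`;
#'   `ko_ids`, `ec_numbers` and `flags` may be `"|"`-separated strings or
#'   list-columns; missing annotation columns are added empty.
#' @return A validated `universal_pool` tibble (every equation is checked
#'   to parse).
#' @export
as_pool <- function(x) {
  x <- as_tibble(x)
  if (!all(c("reaction_id", "equation") %in% names(x)))
    abort("a universal pool needs 'reaction_id' and 'equation' columns")
  if (anyDuplicated(x$reaction_id))
    abort(paste0("duplicate pool reaction id(s): ",
                 paste(unique(x$reaction_id[duplicated(x$reaction_id)]),
                       collapse = ", ")))
  for (col in c("ko_ids", "ec_numbers", "flags")) {
    if (!col %in% names(x)) x[[col]] <- rep(list(character(0)), nrow(x))
    if (is.character(x[[col]])) x[[col]] <- decode_ids(x[[col]])
  }
  for (col in c("pathway", "subsystem"))
    if (!col %in% names(x)) x[[col]] <- NA_character_
  for (i in seq_len(nrow(x))) parse_equation(x$equation[i])  # fail early
  class(x) <- c("universal_pool", class(x))
  x
}

#' @rdname as_pool
#' @param path TSV file with the pool columns.
#' @export
read_pool <- function(path) {
  as_pool(readr::read_tsv(path, col_types = readr::cols(.default = "c")))
}

#' @rdname as_pool
#' @param pool A `universal_pool`.
#' @export
write_pool <- function(pool, path) {
  flat <- as_tibble(pool)
  for (col in c("ko_ids", "ec_numbers", "flags"))
    if (is.list(flat[[col]])) flat[[col]] <- encode_ids(flat[[col]])
  readr::write_tsv(flat, path)
  invisible(path)
}

## convert pool rows into reaction-table rows ready for gem_add_reactions
pool_reactions <- function(pool, ids = pool$reaction_id) {
  rows <- pool[match(ids, pool$reaction_id), , drop = FALSE]
  reaction_tbl(id = rows$reaction_id, equation = rows$equation,
               ko_ids = rows$ko_ids, pathway = rows$pathway,
               subsystem = rows$subsystem)
}
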