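#' Read a herb attribute table
#'
#' The table carries one row per herb with "|"-delimited list cells:
#' `name`, `natures`, `tastes`, `channels`, `functions`, `indications`.
#' Nature/taste/channel cells hold raw annotations ("slight cold", "ping",
#' "tasteless", "lung|heart", ...) which are parsed through the attribute
#' lexicon into numeric vectors at read time. Duplicate names keep the last
#' row with a warning.
#'
#' @param path Path to a TSV or JSON file.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by extension).
#' @param synonyms Optional synonym table from [read_synonym_table()]; aliases
#'   are rewritten to their canonical label before any matching.
#' @return A tibble with columns `name`, raw annotation list-columns
#'   (`natures`, `tastes`, `channels`, `functions`, `indications`) and parsed
#'   numeric list-columns (`nature_vec`, `taste_vec`, `channel_vec`).
#' @export
read_herb_table <- function(path, format = c("auto", "tsv", "json"),
                            synonyms = NULL) {
  format <- resolve_format(path, match.arg(format))
  cols <- c("name", "natures", "tastes", "channels", "functions", "indications")
  if (format == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    check_columns(raw, cols, path)
    tbl <- tibble(
      name        = normalize_label(raw$name),
      natures     = split_list_cell(raw$natures),
      tastes      = split_list_cell(raw$tastes),
      channels    = split_list_cell(raw$channels),
      functions   = split_list_cell(raw$functions),
      indications = split_list_cell(raw$indications)
    )
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    tbl <- tibble(
      name        = normalize_label(purrr::map_chr(recs, "name")),
      natures     = purrr::map(recs, ~ normalize_label(as.character(.x$natures %||% character(0)))),
      tastes      = purrr::map(recs, ~ normalize_label(as.character(.x$tastes %||% character(0)))),
      channels    = purrr::map(recs, ~ normalize_label(as.character(.x$channels %||% character(0)))),
      functions   = purrr::map(recs, ~ normalize_label(as.character(.x$functions %||% character(0)))),
      indications = purrr::map(recs, ~ normalize_label(as.character(.x$indications %||% character(0))))
    )
  }
  if (!is.null(synonyms)) tbl$name <- apply_synonyms(tbl$name, synonyms)
  if (anyDuplicated(tbl$name)) {
    dups <- unique(tbl$name[duplicated(tbl$name)])
    warn(sprintf("Duplicate herb name(s) %s: keeping the last occurrence.",
                 paste(sprintf("\"%s\"", dups), collapse = ", ")))
    tbl <- tbl[!duplicated(tbl$name, fromLast = TRUE), , drop = FALSE]
  }
  tbl$nature_vec <- purrr::map2(tbl$natures, tbl$name,
    ~ parse_attr_for_herb(parse_nature, .x, .y, "natures"))
  tbl$taste_vec <- purrr::map2(tbl$tastes, tbl$name,
    ~ parse_attr_for_herb(parse_taste, .x, .y, "tastes"))
  tbl$channel_vec <- purrr::map2(tbl$channels, tbl$name,
    ~ parse_attr_for_herb(parse_channel, .x, .y, "channels"))
  tbl
}

#' Write a herb attribute table
#'
#' Serializes the raw annotation columns, so a write/read round trip
#' reproduces the canonical structure exactly.
#'
#' @param herbs Tibble from [read_herb_table()] (or built the same way).
#' @param path Output path.
#' @inheritParams read_herb_table
#' @return `path`, invisibly.
#' @export
write_herb_table <- function(herbs, path, format = c("auto", "tsv", "json")) {
  format <- resolve_format(path, match.arg(format))
  cols <- c("name", "natures", "tastes", "channels", "functions", "indications")
  check_columns(herbs, cols, "herb table")
  if (format == "tsv") {
    out <- tibble(
      name        = herbs$name,
      natures     = join_list_cell(herbs$natures),
      tastes      = join_list_cell(herbs$tastes),
      channels    = join_list_cell(herbs$channels),
      functions   = join_list_cell(herbs$functions),
      indications = join_list_cell(herbs$indications)
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    recs <- purrr::pmap(herbs[cols], function(name, natures, tastes, channels,
                                              functions, indications) {
      list(name = name, natures = as.list(natures), tastes = as.list(tastes),
           channels = as.list(channels), functions = as.list(functions),
           indications = as.list(indications))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a formula table
#'
#' One row per formula: `name`, `herbs` (ordered, "|"-delimited; position 1 is
#' the Master herb), `diseases` and `doids`. A duplicate herb within one
#' formula is an error; duplicate formula names keep the last row with a
#' warning. An empty `doids` cell is accepted (such formulae are skipped by
#' Sim-dependent pipelines).
#'
#' @inheritParams read_herb_table
#' @return A tibble with columns `name` and list-columns `herbs`, `diseases`,
#'   `doids`.
#' @export
read_formula_table <- function(path, format = c("auto", "tsv", "json"),
                               synonyms = NULL) {
  format <- resolve_format(path, match.arg(format))
  cols <- c("name", "herbs", "diseases", "doids")
  if (format == "tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    check_columns(raw, cols, path)
    tbl <- tibble(
      name     = normalize_label(raw$name),
      herbs    = split_list_cell(raw$herbs),
      diseases = split_list_cell(raw$diseases),
      doids    = split_list_cell(raw$doids, normalize = FALSE)
    )
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    tbl <- tibble(
      name     = normalize_label(purrr::map_chr(recs, "name")),
      herbs    = purrr::map(recs, ~ normalize_label(as.character(.x$herbs))),
      diseases = purrr::map(recs, ~ normalize_label(as.character(.x$diseases %||% character(0)))),
      doids    = purrr::map(recs, ~ as.character(.x$doids %||% character(0)))
    )
  }
  if (!is.null(synonyms)) {
    tbl$herbs <- purrr::map(tbl$herbs, apply_synonyms, synonyms = synonyms)
  }
  validate_formulae(tbl)
  if (anyDuplicated(tbl$name)) {
    dups <- unique(tbl$name[duplicated(tbl$name)])
    warn(sprintf("Duplicate formula name(s) %s: keeping the last occurrence.",
                 paste(sprintf("\"%s\"", dups), collapse = ", ")))
    tbl <- tbl[!duplicated(tbl$name, fromLast = TRUE), , drop = FALSE]
  }
  tbl
}

#' Write a formula table
#'
#' @param formulae Tibble from [read_formula_table()].
#' @param path Output path.
#' @inheritParams read_herb_table
#' @return `path`, invisibly.
#' @export
write_formula_table <- function(formulae, path,
                                format = c("auto", "tsv", "json")) {
  format <- resolve_format(path, match.arg(format))
  check_columns(formulae, c("name", "herbs", "diseases", "doids"),
                "formula table")
  if (format == "tsv") {
    out <- tibble(
      name     = formulae$name,
      herbs    = join_list_cell(formulae$herbs),
      diseases = join_list_cell(formulae$diseases),
      doids    = join_list_cell(formulae$doids)
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    recs <- purrr::pmap(
      formulae[c("name", "herbs", "diseases", "doids")],
      function(name, herbs, diseases, doids) {
        list(name = name, herbs = as.list(herbs),
             diseases = as.list(diseases), doids = as.list(doids))
      })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

validate_formulae <- function(formulae) {
  purrr::walk2(formulae$name, formulae$herbs, function(nm, hs) {
    if (length(hs) == 0) {
      abort(sprintf("Formula \"%s\" has no herbs.", nm))
    }
    if (anyDuplicated(hs)) {
      dup <- unique(hs[duplicated(hs)])
      abort(sprintf("Formula \"%s\" lists duplicate herb(s): %s.",
                    nm, paste(sprintf("\"%s\"", dup), collapse = ", ")))
    }
  })
  invisible(formulae)
}

#' Read a two-column synonym table
#'
#' TSV with columns `alias`, `canonical`. Applied by the readers before any
#' label matching, so herbs recorded under variant names unify.
#'
#' @param path Path to the TSV file.
#' @return A tibble with normalized `alias` and `canonical` columns.
#' @export
read_synonym_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  check_columns(raw, c("alias", "canonical"), path)
  tibble(alias = normalize_label(raw$alias),
         canonical = normalize_label(raw$canonical))
}

apply_synonyms <- function(labels, synonyms) {
  idx <- match(labels, synonyms$alias)
  ifelse(is.na(idx), labels, synonyms$canonical[idx])
}

#' Read a disease ontology from an OBO file
#'
#' Parses the `[Term]` stanzas of an OBO 1.2 file, keeping `id`, `name` and
#' `is_a` only, and validates that every edge endpoint is a declared term and
#' that the is_a graph is acyclic.
#'
#' @param path Path to the OBO file.
#' @return An `ontology_dag` object: list with `terms` (tibble of `id`,
#'   `term_name`), `edges` (tibble of `child`, `parent`), `parents` and
#'   `children` (named lists), and `roots`.
#' @export
read_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ids <- character(0); names_ <- character(0)
  edge_child <- character(0); edge_parent <- character(0)
  in_term <- FALSE; cur_id <- NA_character_; cur_name <- NA_character_
  flush <- function() {
    if (!is.na(cur_id)) {
      ids <<- c(ids, cur_id)
      names_ <<- c(names_, ifelse(is.na(cur_name), cur_id, cur_name))
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "[Term]") {
      flush(); in_term <- TRUE; cur_id <- NA_character_; cur_name <- NA_character_
    } else if (grepl("^\\[", line)) {
      flush(); in_term <- FALSE; cur_id <- NA_character_; cur_name <- NA_character_
    } else if (in_term && nzchar(line)) {
      if (!grepl("^[A-Za-z_]+:", line)) {
        abort(sprintf("Malformed OBO line %d: \"%s\".", i, line))
      }
      key <- sub(":.*$", "", line)
      val <- trimws(sub("^[A-Za-z_]+:\\s*", "", line))
      if (key == "id") {
        cur_id <- val
      } else if (key == "name") {
        cur_name <- val
      } else if (key == "is_a") {
        parent <- trimws(sub("!.*$", "", val))
        if (is.na(cur_id) || !nzchar(parent)) {
          abort(sprintf("Malformed is_a at OBO line %d.", i))
        }
        edge_child <- c(edge_child, cur_id)
        edge_parent <- c(edge_parent, parent)
      }
    }
  }
  flush()
  new_ontology(tibble(id = ids, term_name = names_),
               tibble(child = edge_child, parent = edge_parent))
}

#' Build an ontology DAG from term and edge tables
#'
#' @param terms Tibble with columns `id`, `term_name` (or a character vector
#'   of ids).
#' @param edges Tibble with columns `child`, `parent` (is_a links).
#' @return An `ontology_dag` object; see [read_obo()].
#' @export
new_ontology <- function(terms, edges) {
  if (is.character(terms)) terms <- tibble(id = terms, term_name = terms)
  check_columns(terms, c("id", "term_name"), "ontology terms")
  check_columns(edges, c("child", "parent"), "ontology edges")
  if (anyDuplicated(terms$id)) abort("Ontology declares duplicate term ids.")
  undeclared <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(undeclared)) {
    abort(sprintf("Ontology edge endpoint(s) not declared as terms: %s.",
                  paste(undeclared, collapse = ", ")))
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = terms$id)
    if (!igraph::is_dag(g)) abort("Ontology is_a graph contains a cycle.")
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  children <- split(edges$child, factor(edges$parent, levels = terms$id))
  roots <- terms$id[lengths(parents) == 0]
  structure(
    list(terms = as_tibble(terms), edges = as_tibble(edges),
         parents = parents, children = children, roots = roots),
    class = "ontology_dag"
  )
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d is_a edges, %d root(s)\n",
              nrow(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Read a GMT pathway collection
#'
#' Standard tab-separated GMT: pathway name, description, then gene ids. The
#' gene universe is the union of all pathway genes.
#'
#' @param path Path to the GMT file.
#' @return A `pathway_collection`: list with `pathways` (named list of gene
#'   character vectors) and `universe` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pws <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("Malformed GMT line %d: expected name, description and at least one gene.", i))
    }
    pws[[parts[[1]]]] <- unique(parts[-(1:2)])
  }
  new_pathway_collection(pws)
}

#' @rdname read_gmt
#' @param pathways Named list of gene-id character vectors.
#' @export
new_pathway_collection <- function(pathways) {
  if (length(pathways) == 0 || is.null(names(pathways))) {
    abort("`pathways` must be a non-empty named list of gene sets.")
  }
  if (any(lengths(pathways) == 0)) abort("Every pathway needs at least one gene.")
  structure(list(pathways = pathways,
                 universe = sort(unique(unlist(pathways, use.names = FALSE)))),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways over %d genes\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Read a herb-to-target table
#'
#' A two-column TSV (`herb`, `gene`) or three-column TSV (`herb`, `compound`,
#' `gene`); the compound column, when present, is carried as provenance and
#' enables compound-level sharing in [shared_targets()].
#'
#' @param path Path to the TSV file.
#' @return A `target_map` tibble with columns `herb`, `gene` and optionally
#'   `compound`.
#' @export
read_target_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("herb", "gene") %in% names(raw))) {
    abort(sprintf("Target table %s must have columns herb, gene (and optionally compound).", path))
  }
  out <- tibble(herb = normalize_label(raw$herb), gene = raw$gene)
  if ("compound" %in% names(raw)) out$compound <- raw$compound
  out <- dplyr::distinct(out)
  class(out) <- c("target_map", class(out))
  out
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) return("tsv")
  if (ext == "json") return("json")
  abort(sprintf("Cannot infer format from extension of \"%s\"; pass `format`.", path))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Fetch one formula row by name (after normalization); errors if absent.
get_formula <- function(formulae, name) {
  name <- normalize_label(name)
  i <- match(name, formulae$name)
  if (is.na(i)) abort(sprintf("Formula \"%s\" not found in the table.", name))
  formulae[i, ]
}

get_herb_row <- function(herbs, name) {
  name <- normalize_label(name)
  i <- match(name, herbs$name)
  if (is.na(i)) abort(sprintf("Herb \"%s\" not found in the herb table.", name))
  herbs[i, ]
}
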