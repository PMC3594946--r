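#' Load the bundled case-study database
#'
#' A small, fully annotated database shipped as plain-text files under
#' `inst/extdata/`. It contains the abstract 5-/4-herb worked-example pair
#' (shared herbs at positions (2, 1) and (4, 2)); the chronic-bronchitis
#' case study SSJY / SKT / SJZBY (8 herbs each) and the rheumatoid-arthritis
#' case study FDHJST (15 herbs) / FFT (8 herbs) / FFDHT (6 herbs); herb
#' attributes engineered so the case-study herb pairs (forsythia suspensa /
#' thunberg fritillary bulb, doubleteeth pubescent angelica / notopterygium
#' root, rhinoceros / buffalo horn, walnut kernel / cordyceps sinensis) score
#' AS above 3 while every other cross-product pair stays below; a toy
#' disease-ontology subset in which the case-study disease pairs score in the
#' high Sim band; a herb-target table whose SSJY/SKT shared-target set holds
#' exactly 78 genes; and a small GMT collection. The attribute annotations
#' are synthetic stand-ins for the original (non-redistributable) database
#' records, so AS totals here are not the historical values — only their
#' relation to the threshold 3 is meaningful.
#'
#' @return A list with `herbs`, `formulae`, `ontology`, `targets`,
#'   `pathways`, and `paths` (the source files).
#' @examples
#' fx <- fixture_case_study()
#' cd_score(fx$formulae, "abstract pair f1", "abstract pair f2")
#' @export
fixture_case_study <- function() {
  p <- function(f) system.file("extdata", f, package = "formulapair",
                               mustWork = TRUE)
  paths <- list(
    herbs = p("case_herbs.tsv"), formulae = p("case_formulae.tsv"),
    ontology = p("case_disease.obo"), targets = p("case_targets.tsv"),
    pathways = p("case_pathways.gmt")
  )
  list(
    herbs = read_herb_table(paths$herbs),
    formulae = read_formula_table(paths$formulae),
    ontology = read_obo(paths$ontology),
    targets = read_target_table(paths$targets),
    pathways = read_gmt(paths$pathways),
    paths = paths
  )
}

#' Specification for a synthetic formula database
#'
#' The generator emulates the shape of a curated formula database: herbs with
#' one or two natures (occasionally "ping", "slight" or "severe" modifiers),
#' one or two tastes (with occasional "tasteless"/"pucker" annotations),
#' channel tropisms, function/indication phrases drawn from fixed-size
#' vocabularies; formulae as duplicate-free ordered draws of 3-14 herbs, each
#' mapped to 1-3 ontology terms; a rooted is_a tree; a herb-target table and
#' a GMT collection over a shared gene pool. Generation is a pure function of
#' this spec.
#'
#' @param seed Integer seed; every artifact derives its own stream from it.
#' @param n_herbs,n_formulae Database size.
#' @param formula_length Length-2 integer range of herbs per formula.
#' @param n_functions,n_indications Vocabulary sizes.
#' @param functions_per_herb,indications_per_herb Length-2 ranges.
#' @param ontology_depth,ontology_branching Shape of the is_a tree.
#' @param n_genes Gene-pool size.
#' @param genes_per_herb Length-2 range of targets per herb.
#' @param n_pathways,pathway_size Pathway count and length-2 size range.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_herbs = 60L, n_formulae = 40L,
                         formula_length = c(3L, 14L),
                         n_functions = 40L, n_indications = 60L,
                         functions_per_herb = c(2L, 5L),
                         indications_per_herb = c(2L, 5L),
                         ontology_depth = 3L, ontology_branching = 3L,
                         n_genes = 300L, genes_per_herb = c(2L, 8L),
                         n_pathways = 15L, pathway_size = c(10L, 40L)) {
  spec <- list(seed = as.integer(seed), n_herbs = n_herbs,
               n_formulae = n_formulae, formula_length = formula_length,
               n_functions = n_functions, n_indications = n_indications,
               functions_per_herb = functions_per_herb,
               indications_per_herb = indications_per_herb,
               ontology_depth = ontology_depth,
               ontology_branching = ontology_branching,
               n_genes = n_genes, genes_per_herb = genes_per_herb,
               n_pathways = n_pathways, pathway_size = pathway_size)
  counts <- unlist(spec[c("n_herbs", "n_formulae", "n_functions",
                          "n_indications", "ontology_depth",
                          "ontology_branching", "n_genes", "n_pathways")])
  if (any(counts < 1)) abort("All fixture counts must be positive.")
  if (spec$formula_length[[2]] > spec$n_herbs) {
    abort("Infeasible spec: formulae longer than the herb vocabulary.")
  }
  structure(spec, class = "fixture_spec")
}

with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

sample_range <- function(rng, n = 1) {
  if (rng[[1]] == rng[[2]]) rep(rng[[1]], n) else sample(rng[[1]]:rng[[2]], n, replace = TRUE)
}

#' Generate a synthetic formula database from a spec
#'
#' Deterministic: the same spec yields byte-identical files. One random
#' stream per artifact (all derived from the single seed), so adding an
#' artifact never perturbs the earlier ones.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given the five artifacts are written
#'   (TSV/OBO/GMT) and their paths returned under `paths`.
#' @return A list with `herbs`, `formulae`, `ontology`, `targets`,
#'   `pathways` (and `paths` when `dir` is given).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  if (!inherits(spec, "fixture_spec")) abort("`spec` must come from fixture_spec().")
  herb_names <- sprintf("herb %03d", seq_len(spec$n_herbs))
  fun_vocab <- sprintf("function %02d", seq_len(spec$n_functions))
  ind_vocab <- sprintf("indication %02d", seq_len(spec$n_indications))

  herbs_raw <- with_stream(spec$seed, 1L, {
    rows <- purrr::map(herb_names, function(nm) {
      natures <- if (stats::runif(1) < 0.1) "ping" else {
        base <- sample(NATURES, sample(1:2, 1))
        mods <- sample(c("", "slight ", "severe "), length(base),
                       replace = TRUE, prob = c(0.7, 0.2, 0.1))
        paste0(mods, base)
      }
      tastes <- {
        base <- sample(TASTES, sample(1:2, 1))
        mods <- sample(c("", "slight "), length(base), replace = TRUE,
                       prob = c(0.8, 0.2))
        out <- paste0(mods, base)
        if (stats::runif(1) < 0.1) out <- c(out, "tasteless")
        if (stats::runif(1) < 0.1) out <- c(out, "pucker")
        out
      }
      tibble(
        name = nm,
        natures = list(natures), tastes = list(tastes),
        channels = list(sample(CHANNELS, sample(1:3, 1))),
        functions = list(sample(fun_vocab, sample_range(spec$functions_per_herb))),
        indications = list(sample(ind_vocab, sample_range(spec$indications_per_herb)))
      )
    })
    dplyr::bind_rows(rows)
  })
  herbs <- herbs_raw
  herbs$nature_vec <- purrr::map(herbs$natures, parse_nature)
  herbs$taste_vec <- purrr::map(herbs$tastes, parse_taste)
  herbs$channel_vec <- purrr::map(herbs$channels, parse_channel)

  ontology <- with_stream(spec$seed, 3L, {
    ids <- "T:0001"; parents <- character(0); children_of <- list("T:0001")
    level <- "T:0001"; counter <- 1L
    edges_child <- character(0); edges_parent <- character(0)
    for (d in seq_len(spec$ontology_depth)) {
      nxt <- character(0)
      for (p in level) {
        kids <- sprintf("T:%04d", counter + seq_len(spec$ontology_branching))
        counter <- counter + spec$ontology_branching
        ids <- c(ids, kids)
        edges_child <- c(edges_child, kids)
        edges_parent <- c(edges_parent, rep(p, length(kids)))
        nxt <- c(nxt, kids)
      }
      level <- nxt
    }
    new_ontology(tibble(id = ids, term_name = paste("term", ids)),
                 tibble(child = edges_child, parent = edges_parent))
  })
  leaves <- setdiff(ontology$terms$id, unique(ontology$edges$parent))

  formulae <- with_stream(spec$seed, 2L, {
    rows <- purrr::map(seq_len(spec$n_formulae), function(i) {
      len <- sample_range(spec$formula_length)
      doids <- sample(leaves, sample(1:3, 1))
      tibble(
        name = sprintf("formula %03d", i),
        herbs = list(sample(herb_names, len)),
        diseases = list(normalize_label(
          ontology$terms$term_name[match(doids, ontology$terms$id)])),
        doids = list(doids)
      )
    })
    dplyr::bind_rows(rows)
  })

  gene_pool <- sprintf("G%04d", seq_len(spec$n_genes))
  targets <- with_stream(spec$seed, 4L, {
    rows <- purrr::map(herb_names, function(nm) {
      tibble(herb = nm, gene = sample(gene_pool, sample_range(spec$genes_per_herb)))
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("target_map", class(out))
    out
  })

  pathways <- with_stream(spec$seed, 5L, {
    sizes <- sample_range(spec$pathway_size, spec$n_pathways)
    pws <- purrr::map(sizes, ~ sample(gene_pool, .x))
    names(pws) <- sprintf("pathway %02d", seq_len(spec$n_pathways))
    new_pathway_collection(pws)
  })

  out <- list(herbs = herbs, formulae = formulae, ontology = ontology,
              targets = targets, pathways = pathways)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      herbs = file.path(dir, "herbs.tsv"),
      formulae = file.path(dir, "formulae.tsv"),
      ontology = file.path(dir, "disease.obo"),
      targets = file.path(dir, "targets.tsv"),
      pathways = file.path(dir, "pathways.gmt")
    )
    write_herb_table(herbs, paths$herbs)
    write_formula_table(formulae, paths$formulae)
    write_obo(ontology, paths$ontology)
    readr::write_tsv(tibble(herb = targets$herb, gene = targets$gene),
                     paths$targets, progress = FALSE)
    write_gmt(pathways, paths$pathways)
    out$paths <- paths
  }
  out
}

#' Write an ontology DAG as an OBO file
#'
#' Emits the id/name/is_a subset read by [read_obo()].
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[[i]]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("name: ", dag$terms$term_name[[i]]),
               paste0("is_a: ", dag$parents[[id]], recycle0 = TRUE), "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a pathway collection as a GMT file
#'
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- purrr::imap_chr(pathways$pathways, function(genes, nm) {
    paste(c(nm, "na", genes), collapse = "\t")
  })
  readr::write_lines(unname(lines), path)
  invisible(path)
}
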