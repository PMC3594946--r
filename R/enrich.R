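#' Collect the target genes of a formula
#'
#' Union of the target sets of the formula's herbs. Herbs absent from the
#' target map are reported via a message, not an error; an empty union
#' warns.
#'
#' @param formulae Formula table.
#' @param name Formula name.
#' @param targets A `target_map` (see [read_target_table()]).
#' @return Character vector of gene ids (possibly empty).
#' @export
collect_targets <- function(formulae, name, targets) {
  f <- get_formula(formulae, name)
  herbs <- f$herbs[[1]]
  unmapped <- setdiff(herbs, unique(targets$herb))
  if (length(unmapped)) {
    inform(sprintf("Formula \"%s\": %d herb(s) without targets: %s.",
                   f$name, length(unmapped),
                   paste(unmapped, collapse = ", ")))
  }
  genes <- sort(unique(targets$gene[targets$herb %in% herbs]))
  if (length(genes) == 0) {
    warn(sprintf("Formula \"%s\" has no mapped targets.", f$name))
  }
  genes
}

#' Targets shared by two formulae
#'
#' With a plain herb-gene table this is the intersection of the two formulae's
#' target sets. When the table carries a `compound` column, sharing is lifted
#' to the compound level: the genes of compounds present in herbs of both
#' formulae.
#'
#' @inheritParams collect_targets
#' @param f1,f2 Formula names.
#' @return Character vector of gene ids.
#' @export
shared_targets <- function(formulae, f1, f2, targets) {
  if ("compound" %in% names(targets)) {
    h1 <- get_formula(formulae, f1)$herbs[[1]]
    h2 <- get_formula(formulae, f2)$herbs[[1]]
    c1 <- unique(targets$compound[targets$herb %in% h1])
    c2 <- unique(targets$compound[targets$herb %in% h2])
    shared_cpd <- intersect(c1, c2)
    return(sort(unique(targets$gene[targets$compound %in% shared_cpd])))
  }
  g1 <- suppressMessages(suppressWarnings(collect_targets(formulae, f1, targets)))
  g2 <- suppressMessages(suppressWarnings(collect_targets(formulae, f2, targets)))
  sort(intersect(g1, g2))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for over-representation of the query genes with the
#' one-sided hypergeometric tail P(X >= overlap), given the pathway size, the
#' query size and the collection-wide gene universe. Query genes outside the
#' universe are dropped with a warning. Rows with p below `alpha` are kept,
#' sorted by ascending p (ties by pathway name) and truncated to the `top`
#' best. A Benjamini-Hochberg column (`p_adjust`, computed over all pathways
#' before filtering) is carried along but not used for filtering.
#'
#' @param genes Character vector of query gene ids.
#' @param pathways A `pathway_collection` (see [read_gmt()]).
#' @param alpha Raw p-value threshold (default 0.01).
#' @param top Maximum number of rows reported (default 20).
#' @return A `tcm_ora` tibble: `pathway`, `overlap`, `pathway_size`,
#'   `query_size`, `universe_size`, `p_value`, `p_adjust`.
#' @export
overrepresentation <- function(genes, pathways, alpha = 0.01, top = 20) {
  if (!inherits(pathways, "pathway_collection")) {
    abort("`pathways` must be a pathway_collection.")
  }
  genes <- unique(genes)
  outside <- setdiff(genes, pathways$universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the pathway universe were dropped.",
                 length(outside)))
    genes <- intersect(genes, pathways$universe)
  }
  n_univ <- length(pathways$universe)
  n_query <- length(genes)
  rows <- purrr::imap(pathways$pathways, function(pw_genes, pw_name) {
    k <- length(intersect(genes, pw_genes))
    m <- length(pw_genes)
    p <- phyper(k - 1, m, n_univ - m, n_query, lower.tail = FALSE)
    tibble(pathway = pw_name, overlap = k, pathway_size = m,
           query_size = n_query, universe_size = n_univ, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out <- dplyr::filter(out, .data$p_value < alpha)
  out <- dplyr::arrange(out, .data$p_value, .data$pathway)
  out <- head(out, top)
  class(out) <- c("tcm_ora", class(out))
  out
}

#' @rdname overrepresentation
#' @param x A `tcm_ora` tibble.
#' @param ... Unused.
#' @export
glance.tcm_ora <- function(x, ...) {
  tibble(n_enriched = nrow(x),
         min_p = if (nrow(x)) min(x$p_value) else NA_real_,
         query_size = if (nrow(x)) x$query_size[[1]] else NA_integer_,
         universe_size = if (nrow(x)) x$universe_size[[1]] else NA_integer_)
}

#' @rdname overrepresentation
#' @export
tidy.tcm_ora <- function(x, ...) as_tibble(x)
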