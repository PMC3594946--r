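#' Weight ratio of two positional weights
#'
#' The replacement model requires the rare herb and its candidate to hold
#' comparable ranks in their formulae: min(w1, w2)/max(w1, w2) must exceed
#' 0.8, so the Master/Adviser/Soldier/Guild order is preserved after the
#' swap.
#'
#' @param w1,w2 Positive positional weights (see [herb_weight()]).
#' @return A number in `(0, 1]`; 1 when the weights are equal.
#' @export
weight_ratio <- function(w1, w2) {
  if (any(w1 <= 0) || any(w2 <= 0)) abort("Weights must be positive.")
  pmin(w1, w2) / pmax(w1, w2)
}

#' Find common-herb replacements for a rare herb
#'
#' Scans every formula pair (F1 containing the rare herb, F2 not containing
#' it) whose combinational degree falls in the low band `(0, 0.3]` — the two
#' formulae share a few herbs, which keeps the rare herb itself out of the
#' shared set — and proposes every herb j of F2 that satisfies the three
#' replacement conditions: Sim(F1, F2) in `(0.7, 1]`, AS(rare, j) > 3, and
#' weight ratio min/max > 0.8. Pairs in which either formula lacks mapped
#' DOIDs are skipped (their count is reported via a message). Proposals are
#' sorted by AS descending, then weight ratio descending, then donor label.
#'
#' @param formulae Formula table.
#' @param rare_herb Name of the rare herb to replace.
#' @param herbs Herb attribute table covering the candidate herbs.
#' @param dag Disease-ontology DAG for the Sim condition.
#' @param rare_list Optional character vector of rare-herb labels; donors on
#'   this list are never proposed.
#' @param scale CD normalization constant.
#' @param as_threshold Strict lower bound on AS (default 3).
#' @param ratio_threshold Strict lower bound on the weight ratio (default 0.8).
#' @param method,decay Term-similarity configuration (see
#'   [term_similarity()]).
#' @return A `tcm_replacements` tibble, one row per proposal: formulae,
#'   herbs, weights, `cd`, `sim`, `as_total`, `weight_ratio` and the swapped
#'   formula in the list-column `new_formula`.
#' @examples
#' fx <- fixture_case_study()
#' find_replacements(fx$formulae, "forsythia suspensa", fx$herbs, fx$ontology)
#' @export
find_replacements <- function(formulae, rare_herb, herbs, dag,
                              rare_list = NULL, scale = 7.5,
                              as_threshold = 3, ratio_threshold = 0.8,
                              method = c("wang", "resnik_norm", "lin"),
                              decay = 0.5) {
  method <- match.arg(method)
  rare_herb <- normalize_label(rare_herb)
  if (!is.null(rare_list)) rare_list <- normalize_label(rare_list)
  empty <- tibble(
    rare_formula = character(0), donor_formula = character(0),
    rare_herb = character(0), rare_weight = numeric(0),
    donor_herb = character(0), donor_weight = numeric(0),
    cd = numeric(0), sim = numeric(0), as_total = numeric(0),
    weight_ratio = numeric(0), new_formula = list()
  )
  hosts <- which(purrr::map_lgl(formulae$herbs, ~ rare_herb %in% .x))
  if (length(hosts) == 0) {
    warn(sprintf("Rare herb \"%s\" occurs in no formula.", rare_herb))
    return(new_replacements(empty))
  }
  skipped_unmappable <- 0L
  rows <- list()
  for (i in hosts) {
    f1 <- formulae[i, ]
    h1 <- f1$herbs[[1]]
    rare_pos <- match(rare_herb, h1)
    rare_w <- herb_weight(rare_pos, length(h1))
    for (j in seq_len(nrow(formulae))) {
      if (j == i) next
      f2 <- formulae[j, ]
      h2 <- f2$herbs[[1]]
      if (rare_herb %in% h2) next
      sh <- shared_herbs_vec(h1, h2)
      cd <- normalize_cd(cd_raw_from_shared(sh), scale)
      if (!(cd > 0 && cd_band(cd) == "low")) next
      if (length(f1$doids[[1]]) == 0 || length(f2$doids[[1]]) == 0) {
        skipped_unmappable <- skipped_unmappable + 1L
        next
      }
      sim <- sim_score(formulae, dag, f1$name, f2$name, method, decay)$sim
      if (!(sim_band(sim) == "high")) next
      for (pos2 in seq_along(h2)) {
        cand <- h2[[pos2]]
        if (cand %in% h1) next               # already in the host formula
        if (!is.null(rare_list) && cand %in% rare_list) next
        w2 <- herb_weight(pos2, length(h2))
        wr <- weight_ratio(rare_w, w2)
        if (!(wr > ratio_threshold)) next
        as_row <- as_score(herbs, rare_herb, cand, as_threshold)
        if (!(as_row$as_total > as_threshold)) next
        rows[[length(rows) + 1L]] <- tibble(
          rare_formula = f1$name, donor_formula = f2$name,
          rare_herb = rare_herb, rare_weight = rare_w,
          donor_herb = cand, donor_weight = w2,
          cd = cd, sim = sim, as_total = as_row$as_total,
          weight_ratio = wr,
          new_formula = list(apply_replacement(f1, rare_herb, cand))
        )
      }
    }
  }
  if (skipped_unmappable > 0) {
    inform(sprintf("%d low-CD pair(s) skipped: no mapped DOIDs on one side.",
                   skipped_unmappable))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty
  out <- dplyr::arrange(out, dplyr::desc(.data$as_total),
                        dplyr::desc(.data$weight_ratio), .data$donor_herb)
  new_replacements(out)
}

new_replacements <- function(tbl) {
  class(tbl) <- c("tcm_replacements", class(tbl))
  tbl
}

#' Swap one herb of a formula in place
#'
#' Produces a new formula of the same length and order in which `old` is
#' replaced by `new` at its original position.
#'
#' @param formula One-row formula tibble (or a formula table plus a name via
#'   `formula_name`).
#' @param old,new Herb labels; `old` must be present, `new` absent.
#' @param new_name Name of the resulting formula; defaults to
#'   `"<name>+swap"`.
#' @return A one-row formula tibble.
#' @export
apply_replacement <- function(formula, old, new, new_name = NULL) {
  if (nrow(formula) != 1) abort("`formula` must be a single formula row.")
  old <- normalize_label(old); new <- normalize_label(new)
  herbs <- formula$herbs[[1]]
  pos <- match(old, herbs)
  if (is.na(pos)) {
    abort(sprintf("Herb \"%s\" is not in formula \"%s\".", old, formula$name))
  }
  if (new %in% herbs) {
    abort(sprintf("Herb \"%s\" is already in formula \"%s\".", new, formula$name))
  }
  herbs[[pos]] <- new
  out <- formula
  out$name <- new_name %||% paste0(formula$name, "+swap")
  out$herbs <- list(herbs)
  out
}
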