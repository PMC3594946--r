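#' Match unshared herbs across two formulae by high attribute similarity
#'
#' Scores every (unshared herb of F1) x (unshared herb of F2) pair, keeps
#' pairs with AS strictly above the threshold, then reduces them to a
#' one-to-one matching by greedy selection in descending AS (ties broken by
#' herb labels), so each herb is matched at most once and the matched counts
#' per side are well defined.
#'
#' @param herbs Herb attribute table.
#' @param unshared1,unshared2 Character vectors of herb labels (no overlap
#'   expected).
#' @param threshold Strict AS cutoff (default 3).
#' @return Tibble with columns `herb1`, `herb2`, `as_total`, sorted by
#'   descending AS.
#' @export
match_high_as_pairs <- function(herbs, unshared1, unshared2, threshold = 3) {
  empty <- tibble(herb1 = character(0), herb2 = character(0),
                  as_total = numeric(0))
  if (length(unshared1) == 0 || length(unshared2) == 0) return(empty)
  grid <- tidyr::expand_grid(herb1 = normalize_label(unshared1),
                             herb2 = normalize_label(unshared2))
  scored <- as_pairs(herbs, grid, threshold)
  scored <- dplyr::filter(scored, .data$as_total > threshold)
  if (nrow(scored) == 0) return(empty)
  scored <- dplyr::arrange(scored, dplyr::desc(.data$as_total),
                           .data$herb1, .data$herb2)
  used1 <- character(0); used2 <- character(0); keep <- logical(nrow(scored))
  for (k in seq_len(nrow(scored))) {
    a <- scored$herb1[[k]]; b <- scored$herb2[[k]]
    if (!(a %in% used1) && !(b %in% used2)) {
      keep[[k]] <- TRUE
      used1 <- c(used1, a); used2 <- c(used2, b)
    }
  }
  scored[keep, c("herb1", "herb2", "as_total")]
}

#' Simplify a middle-CD, high-Sim formula pair into a smaller formula
#'
#' For a pair with combinational degree in the middle band `(0.3, 0.7]` and
#' disease similarity in the high band `(0.7, 1]`, the shared herbs plus the
#' unshared herbs matched at AS > 3 are assumed to carry the common effect.
#' With K shared herbs and P (Q) matched herbs on the F1 (F2) side, the
#' emitted formula follows the "least herbs" rule: P > Q keeps the F2 side
#' ("new F2": K shared + Q matched herbs of F2); P < Q keeps the F1 side. At
#' P = Q the side with the greater total positional weight of its matched
#' herbs wins ("higher weights, more importance"); equal totals emit both
#' sides. Emitted herbs are ordered shared-first (in F1 order), then matched
#' herbs in their source-formula order.
#'
#' @inheritParams find_replacements
#' @param f1,f2 Formula names.
#' @param force Skip the band preconditions (useful for exploration).
#' @param matched Optional pre-computed matching (tibble with columns
#'   `herb1`, `herb2`, `as_total`) standing in for
#'   [match_high_as_pairs()]; lets callers plug in a different matching
#'   strategy, in which case P and Q may differ.
#' @param new_name Optional name(s) for the emitted formula(e); the default
#'   joins the initials of the shared herbs with " simplified".
#' @return A `tcm_simplification` object: list with `f1`, `f2`, `cd`, `sim`,
#'   `k_shared`, `shared`, `matched_pairs`, `p`, `q`, `sum_wp`, `sum_wq`,
#'   `branch` (`"new_F1"`, `"new_F2"` or `"both"`) and `new_formulae` (a
#'   formula tibble with 1 or 2 rows). Use [tidy()] for the matched pairs and
#'   [glance()] for the one-row summary.
#' @examples
#' fx <- fixture_case_study()
#' simplify_pair(fx$formulae, "fdhjst", "fft", fx$herbs, fx$ontology)
#' @export
simplify_pair <- function(formulae, f1, f2, herbs, dag = NULL,
                          as_threshold = 3, scale = 7.5,
                          method = c("wang", "resnik_norm", "lin"),
                          decay = 0.5, force = FALSE, matched = NULL,
                          new_name = NULL) {
  method <- match.arg(method)
  r1 <- get_formula(formulae, f1)
  r2 <- get_formula(formulae, f2)
  h1 <- r1$herbs[[1]]; h2 <- r2$herbs[[1]]
  sh <- shared_herbs_vec(h1, h2)
  cd <- normalize_cd(cd_raw_from_shared(sh), scale)
  sim <- NA_real_
  if (!is.null(dag) && length(r1$doids[[1]]) > 0 && length(r2$doids[[1]]) > 0) {
    sim <- sim_score(formulae, dag, r1$name, r2$name, method, decay)$sim
  }
  if (!force) {
    if (cd_band(cd) != "middle") {
      abort(sprintf(
        "CD band precondition failed: cd = %.3f is \"%s\", not \"middle\" (use force = TRUE to override).",
        cd, as.character(cd_band(cd))))
    }
    if (is.na(sim) || sim_band(sim) != "high") {
      abort(sprintf(
        "Sim band precondition failed: sim = %s is not \"high\" (use force = TRUE to override).",
        if (is.na(sim)) "unavailable" else sprintf("%.3f", sim)))
    }
  }
  un1 <- setdiff(h1, sh$herb)
  un2 <- setdiff(h2, sh$herb)
  if (is.null(matched)) {
    matched <- match_high_as_pairs(herbs, un1, un2, as_threshold)
  } else {
    check_columns(matched, c("herb1", "herb2", "as_total"), "`matched`")
    if (!all(matched$herb1 %in% un1) || !all(matched$herb2 %in% un2)) {
      abort("`matched` may only pair unshared herbs of f1 with unshared herbs of f2.")
    }
  }
  p <- length(unique(matched$herb1))
  q <- length(unique(matched$herb2))
  sum_wp <- sum(herb_weight(match(matched$herb1, h1), length(h1)))
  sum_wq <- sum(herb_weight(match(matched$herb2, h2), length(h2)))
  branch <- if (p > q) "new_F2"
            else if (p < q) "new_F1"
            else if (sum_wp > sum_wq) "new_F1"
            else if (sum_wp < sum_wq) "new_F2"
            else "both"

  build_side <- function(side) {
    matched_side <- if (side == 1) unique(matched$herb1) else unique(matched$herb2)
    src <- if (side == 1) h1 else h2
    matched_side <- matched_side[order(match(matched_side, src))]
    c(sh$herb, matched_side)   # shared herbs already in F1 order
  }
  default_name <- function(suffix) {
    initials <- paste(substr(sh$herb, 1, 1), collapse = "")
    paste0(if (nzchar(initials)) initials else "k0", " simplified", suffix)
  }
  make_formula <- function(herb_list, nm) {
    tibble(name = normalize_label(nm), herbs = list(herb_list),
           diseases = list(union(r1$diseases[[1]], r2$diseases[[1]])),
           doids = list(union(r1$doids[[1]], r2$doids[[1]])))
  }
  new_formulae <- switch(branch,
    new_F1 = make_formula(build_side(1), (new_name %||% default_name(""))[[1]]),
    new_F2 = make_formula(build_side(2), (new_name %||% default_name(""))[[1]]),
    both = dplyr::bind_rows(
      make_formula(build_side(1),
                   (new_name %||% c(default_name(" f1"), default_name(" f2")))[[1]]),
      make_formula(build_side(2),
                   (new_name %||% c(default_name(" f1"), default_name(" f2")))[[2]])
    )
  )
  structure(
    list(f1 = r1$name, f2 = r2$name, cd = cd, sim = sim,
         k_shared = nrow(sh), shared = sh, matched_pairs = matched,
         p = p, q = q, sum_wp = sum_wp, sum_wq = sum_wq,
         branch = branch, new_formulae = new_formulae),
    class = "tcm_simplification"
  )
}

#' @export
print.tcm_simplification <- function(x, ...) {
  cat(sprintf("<tcm_simplification> %s + %s\n", x$f1, x$f2))
  cat(sprintf("  cd = %.3f, sim = %s, K = %d shared, P = %d, Q = %d\n",
              x$cd, if (is.na(x$sim)) "NA" else sprintf("%.3f", x$sim),
              x$k_shared, x$p, x$q))
  cat(sprintf("  sum W_p = %.3f, sum W_q = %.3f -> branch %s\n",
              x$sum_wp, x$sum_wq, x$branch))
  for (i in seq_len(nrow(x$new_formulae))) {
    cat(sprintf("  %s: %s\n", x$new_formulae$name[[i]],
                paste(x$new_formulae$herbs[[i]], collapse = " | ")))
  }
  invisible(x)
}

#' @rdname simplify_pair
#' @param x A `tcm_simplification` object.
#' @param ... Unused.
#' @export
tidy.tcm_simplification <- function(x, ...) {
  x$matched_pairs
}

#' @rdname simplify_pair
#' @export
glance.tcm_simplification <- function(x, ...) {
  tibble(f1 = x$f1, f2 = x$f2, cd = x$cd, sim = x$sim,
         k_shared = x$k_shared, p = x$p, q = x$q,
         sum_wp = x$sum_wp, sum_wq = x$sum_wq, branch = x$branch,
         n_new = nrow(x$new_formulae),
         new_size = length(x$new_formulae$herbs[[1]]))
}

#' @rdname find_replacements
#' @param x A `tcm_replacements` tibble.
#' @param ... Unused.
#' @export
glance.tcm_replacements <- function(x, ...) {
  tibble(n_proposals = nrow(x),
         n_donor_formulae = dplyr::n_distinct(x$donor_formula),
         n_donor_herbs = dplyr::n_distinct(x$donor_herb),
         best_as = if (nrow(x)) max(x$as_total) else NA_real_)
}

#' @rdname find_replacements
#' @export
tidy.tcm_replacements <- function(x, ...) {
  out <- dplyr::select(as_tibble(x), -"new_formula")
  out
}
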