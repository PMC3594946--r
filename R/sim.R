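#' Semantic similarity between two ontology terms
#'
#' The default is Wang's structure-only measure: each term's ancestors get an
#' S-value equal to the best decaying path weight `decay^distance` (max over
#' all upward is_a paths, the term itself scoring 1); the similarity of two
#' terms is the sum of both S-values over their common ancestors divided by
#' the sum of all their S-values. Two corpus-free information-content
#' variants are available, with term probability estimated from descendant
#' counts within the DAG: `resnik_norm` (IC of the most informative common
#' ancestor, normalized by the maximum attainable IC) and `lin`
#' (2 IC(MICA) / (IC(t1) + IC(t2))). All methods are symmetric, lie in
#' `[0, 1]`, and return exactly 1 for a term against itself.
#'
#' @param dag An `ontology_dag` (see [read_obo()]).
#' @param t1,t2 Term ids present in `dag`.
#' @param method `"wang"` (default), `"resnik_norm"` or `"lin"`.
#' @param decay Wang edge decay factor, strictly between 0 and 1
#'   (default 0.5).
#' @return A number in `[0, 1]`.
#' @export
term_similarity <- function(dag, t1, t2, method = c("wang", "resnik_norm", "lin"),
                            decay = 0.5) {
  method <- match.arg(method)
  check_term <- function(t) {
    if (!t %in% dag$terms$id) abort(sprintf("Term \"%s\" is not in the ontology.", t))
  }
  check_term(t1); check_term(t2)
  if (t1 == t2) return(1)
  switch(method,
    wang = wang_similarity(dag, t1, t2, decay),
    resnik_norm = ic_similarity(dag, t1, t2, "resnik_norm"),
    lin = ic_similarity(dag, t1, t2, "lin")
  )
}

# Wang S-values: best decaying path weight from `term` to each of its
# ancestors (term itself = 1), maximizing over all upward paths.
wang_svalues <- function(dag, term, decay) {
  if (!is.numeric(decay) || length(decay) != 1 || decay <= 0 || decay >= 1) {
    abort("`decay` must lie strictly between 0 and 1.")
  }
  s <- setNames(1, term)
  queue <- term
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    for (p in dag$parents[[node]]) {
      cand <- s[[node]] * decay
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

wang_similarity <- function(dag, t1, t2, decay) {
  s1 <- wang_svalues(dag, t1, decay)
  s2 <- wang_svalues(dag, t2, decay)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Descendant counts (including self) give a corpus-free term frequency.
descendant_counts <- function(dag) {
  ids <- dag$terms$id
  memo <- new.env(parent = emptyenv())
  count <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    kids <- dag$children[[t]]
    desc <- t
    for (k in kids) desc <- union(desc, attr(count(k), "set"))
    res <- length(desc)
    attr(res, "set") <- desc
    memo[[t]] <- res
    res
  }
  setNames(vapply(ids, function(t) as.numeric(count(t)), numeric(1)), ids)
}

ancestors_of <- function(dag, term) {
  seen <- character(0)
  queue <- term
  while (length(queue)) {
    node <- queue[[1]]; queue <- queue[-1]
    if (node %in% seen) next
    seen <- c(seen, node)
    queue <- c(queue, dag$parents[[node]])
  }
  seen
}

ic_similarity <- function(dag, t1, t2, flavor) {
  n <- nrow(dag$terms)
  if (n < 2) return(0)
  counts <- descendant_counts(dag)
  ic <- -log(counts / n)
  common <- intersect(ancestors_of(dag, t1), ancestors_of(dag, t2))
  if (length(common) == 0) return(0)
  mica <- max(ic[common])
  if (flavor == "resnik_norm") {
    ic_max <- -log(1 / n)
    return(mica / ic_max)
  }
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  2 * mica / denom
}

#' Disease similarity (Sim) between two formulae
#'
#' Averages the pairwise term similarities over every (DOID of f1, DOID of
#' f2) pair — p * q values for p and q mapped diseases. Formulae without any
#' mapped DOID cannot be scored and raise an error; pipelines that sweep a
#' database skip them with a logged count instead.
#'
#' @inheritParams shared_herbs
#' @param dag An `ontology_dag` holding every DOID used.
#' @inheritParams term_similarity
#' @return One-row tibble: `f1`, `f2`, `p`, `q`, `sim`, `sim_band`.
#' @export
sim_score <- function(formulae, dag, f1, f2,
                      method = c("wang", "resnik_norm", "lin"), decay = 0.5) {
  method <- match.arg(method)
  r1 <- get_formula(formulae, f1)
  r2 <- get_formula(formulae, f2)
  d1 <- r1$doids[[1]]; d2 <- r2$doids[[1]]
  if (length(d1) == 0 || length(d2) == 0) {
    abort(sprintf(
      "Unmappable formula: \"%s\" has no DOIDs; Sim is undefined.",
      if (length(d1) == 0) r1$name else r2$name
    ))
  }
  vals <- vapply(d1, function(a) {
    vapply(d2, function(b) term_similarity(dag, a, b, method, decay), numeric(1))
  }, numeric(length(d2)))
  sim <- mean(vals)
  tibble(f1 = r1$name, f2 = r2$name,
         p = length(d1), q = length(d2),
         sim = sim, sim_band = sim_band(sim))
}

#' Band a disease-similarity value
#'
#' `[0, 0.3]` no similarity, `(0.3, 0.7]` significant, `(0.7, 1]` high.
#'
#' @param sim Similarity value(s) in `[0, 1]`.
#' @return Factor with levels none, significant, high.
#' @export
sim_band <- function(sim) {
  if (any(sim < 0 | sim > 1)) abort("`sim` must lie in [0, 1].")
  band <- cut(sim, breaks = c(-Inf, 0.3, 0.7, 1),
              labels = c("none", "significant", "high"), right = TRUE)
  factor(as.character(band), levels = c("none", "significant", "high"))
}
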