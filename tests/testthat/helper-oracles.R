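# Independent oracles and tiny builders used across the suite. These
# deliberately re-derive quantities by brute force (path enumeration, subset
# enumeration, elementwise loops) so they share no code with the package
# implementations they check.

# Build an in-memory herb profile row from raw annotations.
make_herb <- function(name, natures = character(0), tastes = character(0),
                      channels = character(0), functions = character(0),
                      indications = character(0)) {
  nv <- parse_nature(natures); tv <- parse_taste(tastes)
  cv <- parse_channel(channels)
  tibble::tibble(
    name = normalize_label(name),
    natures = list(natures), tastes = list(tastes), channels = list(channels),
    functions = list(as.character(functions)),
    indications = list(as.character(indications)),
    nature_vec = list(nv), taste_vec = list(tv), channel_vec = list(cv)
  )
}

make_formula <- function(name, herbs, diseases = character(0),
                         doids = character(0)) {
  tibble::tibble(name = normalize_label(name), herbs = list(normalize_label(herbs)),
                 diseases = list(diseases), doids = list(doids))
}

# Brute-force raw CD: enumerate all label pairs, average Eq.-style weights.
oracle_cd_raw <- function(h1, h2) {
  total <- 0
  for (i in seq_along(h1)) {
    for (j in seq_along(h2)) {
      if (h1[[i]] == h2[[j]]) {
        w1 <- 1 + (1 - i) / length(h1)
        w2 <- 1 + (1 - j) / length(h2)
        total <- total + (w1 + w2) / 2
      }
    }
  }
  total
}

# Elementwise min/max loop oracle.
oracle_minmax <- function(u, v) {
  num <- 0; den <- 0
  for (k in seq_along(u)) {
    num <- num + min(u[[k]], v[[k]])
    den <- den + max(u[[k]], v[[k]])
  }
  if (den == 0) 0 else num / den
}

oracle_dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) + length(b) == 0) return(0)
  shared <- sum(vapply(a, function(x) x %in% b, logical(1)))
  2 * shared / (length(a) + length(b))
}

# Random DAG on n terms: term i > 1 draws 1-2 parents among 1..(i-1), so the
# graph is acyclic by construction and may have multiple parents.
random_dag <- function(n) {
  ids <- sprintf("N%02d", seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in seq(2, n)) {
    for (p in sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))) {
      child <- c(child, ids[[i]]); parent <- c(parent, ids[[p]])
    }
  }
  new_ontology(tibble::tibble(id = ids, term_name = ids),
               tibble::tibble(child = child, parent = parent))
}

# Wang oracle: enumerate every upward path explicitly and take, per ancestor,
# the max decay^length over all paths reaching it.
oracle_wang_svalues <- function(dag, term, decay) {
  best <- list()
  walk <- function(node, value) {
    if (is.null(best[[node]]) || value > best[[node]]) best[[node]] <<- value
    for (p in dag$parents[[node]]) walk(p, value * decay)
  }
  walk(term, 1)
  unlist(best)
}

oracle_wang <- function(dag, t1, t2, decay = 0.5) {
  s1 <- oracle_wang_svalues(dag, t1, decay)
  s2 <- oracle_wang_svalues(dag, t2, decay)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Exhaustive hypergeometric tail: over all query-sized subsets of the
# universe, the fraction whose overlap with the pathway reaches k.
oracle_hyper_tail <- function(universe, pathway, query_size, k) {
  subsets <- utils::combn(universe, query_size)
  hits <- sum(apply(subsets, 2, function(s) length(intersect(s, pathway)) >= k))
  hits / ncol(subsets)
}
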