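#' Min/max ratio similarity between two non-negative vectors
#'
#' The nature, taste and channel components of the attribute similarity are
#' the ratio of the elementwise-minimum sum to the elementwise-maximum sum.
#' When both vectors are all-zero (no annotation on either side) the
#' similarity is defined as 0, so missing annotations never inflate a score.
#'
#' @param u,v Equal-length non-negative numeric vectors.
#' @return A number in `[0, 1]`.
#' @examples
#' minmax_similarity(parse_nature("ping"), parse_nature("slight cold"))
#' @export
minmax_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("`u` and `v` must have equal length.")
  if (any(u < 0) || any(v < 0)) abort("Entries must be non-negative.")
  denom <- sum(pmax(u, v))
  if (denom == 0) return(0)
  sum(pmin(u, v)) / denom
}

#' Dice similarity between two phrase sets
#'
#' The function and indication components: twice the shared count over the
#' sum of the set sizes. Both-empty input returns 0.
#'
#' @param set1,set2 Character vectors of normalized phrases.
#' @return A number in `[0, 1]`.
#' @export
dice_similarity <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  denom <- length(set1) + length(set2)
  if (denom == 0) return(0)
  2 * length(intersect(set1, set2)) / denom
}

#' Attribute similarity (AS) between two herbs
#'
#' Sums five components, each worth at most 1: nature, taste and channel
#' similarities are min/max ratios of the parsed intensity vectors; function
#' and indication similarities are Dice coefficients of the phrase sets. A
#' total above 3 marks the pair as highly similar.
#'
#' @param herbs Herb table (see [read_herb_table()]).
#' @param h1,h2 Herb names.
#' @param threshold High-similarity cutoff on the total (default 3, strict).
#' @return One-row tibble: `herb1`, `herb2`, `a_nature`, `b_taste`,
#'   `c_channel`, `d_function`, `e_indication`, `as_total`,
#'   `high_similarity`.
#' @examples
#' fx <- fixture_case_study()
#' as_score(fx$herbs, "forsythia suspensa", "thunberg fritillary bulb")
#' @export
as_score <- function(herbs, h1, h2, threshold = 3) {
  r1 <- get_herb_row(herbs, h1)
  r2 <- get_herb_row(herbs, h2)
  as_score_rows(r1, r2, threshold)
}

as_score_rows <- function(r1, r2, threshold = 3) {
  a <- minmax_similarity(r1$nature_vec[[1]], r2$nature_vec[[1]])
  b <- minmax_similarity(r1$taste_vec[[1]], r2$taste_vec[[1]])
  cc <- minmax_similarity(r1$channel_vec[[1]], r2$channel_vec[[1]])
  d <- dice_similarity(r1$functions[[1]], r2$functions[[1]])
  e <- dice_similarity(r1$indications[[1]], r2$indications[[1]])
  total <- a + b + cc + d + e
  tibble(
    herb1 = r1$name, herb2 = r2$name,
    a_nature = a, b_taste = b, c_channel = cc,
    d_function = d, e_indication = e,
    as_total = total, high_similarity = total > threshold
  )
}

#' Attribute similarity over pairs of herbs
#'
#' Scores either every unordered pair in the table or, when `pairs` is given,
#' exactly those pairs.
#'
#' @inheritParams as_score
#' @param pairs Optional two-column data frame (or tibble) of herb name pairs.
#' @return Tibble with one row per pair, columns as in [as_score()].
#' @export
as_pairs <- function(herbs, pairs = NULL, threshold = 3) {
  if (is.null(pairs)) {
    if (nrow(herbs) < 2) {
      return(as_score_rows(herbs[0, ], herbs[0, ], threshold))
    }
    idx <- utils::combn(nrow(herbs), 2)
    pairs <- tibble(herb1 = herbs$name[idx[1, ]], herb2 = herbs$name[idx[2, ]])
  }
  pairs <- as_tibble(pairs)
  names(pairs)[1:2] <- c("herb1", "herb2")
  dplyr::bind_rows(purrr::map2(
    pairs$herb1, pairs$herb2,
    function(a, b) as_score(herbs, a, b, threshold)
  ))
}
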