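#' Positional weight of a herb in a formula
#'
#' A formula lists its herbs in decreasing importance (Master, Adviser,
#' Soldier, Guild). The weight of the herb at 1-based position m of an L-herb
#' formula is 1 + (1 - m)/L, so the Master herb weighs exactly 1 and the last
#' herb exactly 1/L.
#'
#' @param position 1-based position(s) within the formula.
#' @param length Number of herbs in the formula.
#' @return Numeric weight(s) in `[1/length, 1]`.
#' @examples
#' herb_weight(3, 8)   # 0.75
#' herb_weight(1, 15)  # 1
#' @export
herb_weight <- function(position, length) {
  if (any(length < 1) || any(length != as.integer(length))) {
    abort("`length` must be a positive integer.")
  }
  if (any(position < 1) || any(position > length) ||
      any(position != as.integer(position))) {
    abort("`position` must be an integer in [1, length].")
  }
  1 + (1 - position) / length
}

#' Herbs shared by two formulae
#'
#' Matches herbs across the two formulae by normalized-label equality and
#' reports each shared herb with its 1-based position and positional weight on
#' both sides, ordered by position in the first formula.
#'
#' @param formulae Formula table (see [read_formula_table()]).
#' @param f1,f2 Formula names.
#' @return A tibble with columns `herb`, `pos1`, `pos2`, `w1`, `w2`.
#' @export
shared_herbs <- function(formulae, f1, f2) {
  r1 <- get_formula(formulae, f1)
  r2 <- get_formula(formulae, f2)
  shared_herbs_vec(r1$herbs[[1]], r2$herbs[[1]])
}

shared_herbs_vec <- function(h1, h2) {
  common <- intersect(h1, h2)
  pos1 <- match(common, h1)
  ord <- order(pos1)
  common <- common[ord]; pos1 <- pos1[ord]
  pos2 <- match(common, h2)
  tibble(
    herb = common, pos1 = pos1, pos2 = pos2,
    w1 = if (length(common)) herb_weight(pos1, length(h1)) else numeric(0),
    w2 = if (length(common)) herb_weight(pos2, length(h2)) else numeric(0)
  )
}

#' Raw combinational degree of two formulae
#'
#' The raw CD sums, over every shared herb, the mean of its two positional
#' weights. It is symmetric, zero exactly when the formulae share no herb, and
#' bounded above by (min(L1, L2) + 1)/2.
#'
#' @inheritParams shared_herbs
#' @return A non-negative number.
#' @export
combinational_degree_raw <- function(formulae, f1, f2) {
  sh <- shared_herbs(formulae, f1, f2)
  cd_raw_from_shared(sh)
}

cd_raw_from_shared <- function(sh) sum((sh$w1 + sh$w2) / 2)

#' Normalize a raw combinational degree to [0, 1]
#'
#' Raw CDs over a formula database span `[0, scale]`; the default scale 7.5 is
#' the raw CD of a 14-herb formula against itself, the ceiling observed over
#' the reference database. Values above the scale (possible when user
#' databases hold longer formulae) clamp to 1 with a warning.
#'
#' @param cd_raw Non-negative raw CD value(s).
#' @param scale Positive normalization constant (default 7.5).
#' @return Values in `[0, 1]`.
#' @export
normalize_cd <- function(cd_raw, scale = 7.5) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    abort("`scale` must be a single positive number.")
  }
  if (any(cd_raw < 0)) abort("`cd_raw` must be non-negative.")
  if (any(cd_raw > scale)) {
    warn(sprintf("%d raw CD value(s) exceed the scale %g and were clamped to 1.",
                 sum(cd_raw > scale), scale))
  }
  pmin(cd_raw / scale, 1)
}

#' Band a normalized combinational degree
#'
#' 0 means no combination (no shared herbs); `(0, 0.3]` low, `(0.3, 0.7]`
#' middle, `(0.7, 1]` high combination. Intervals are closed on the right.
#'
#' @param cd Normalized CD value(s) in `[0, 1]`.
#' @return Factor with levels none, low, middle, high.
#' @export
cd_band <- function(cd) {
  if (any(cd < 0 | cd > 1)) abort("`cd` must lie in [0, 1].")
  band <- cut(cd, breaks = c(-Inf, 0, 0.3, 0.7, 1),
              labels = c("none", "low", "middle", "high"), right = TRUE)
  factor(as.character(band), levels = c("none", "low", "middle", "high"))
}

#' Score one formula pair by combinational degree
#'
#' @inheritParams shared_herbs
#' @param scale Normalization constant passed to [normalize_cd()].
#' @return One-row tibble: `f1`, `f2`, `n_shared`, `cd_raw`, `cd`, `cd_band`,
#'   with the shared-herb tibble in the list-column `shared`.
#' @examples
#' fx <- fixture_case_study()
#' cd_score(fx$formulae, "ssjy", "skt")
#' @export
cd_score <- function(formulae, f1, f2, scale = 7.5) {
  sh <- shared_herbs(formulae, f1, f2)
  raw <- cd_raw_from_shared(sh)
  cd <- normalize_cd(raw, scale)
  tibble(
    f1 = normalize_label(f1), f2 = normalize_label(f2),
    n_shared = nrow(sh), cd_raw = raw, cd = cd,
    cd_band = cd_band(cd), shared = list(sh)
  )
}

#' Score every formula pair by combinational degree
#'
#' @inheritParams cd_score
#' @return Tibble with one row per unordered pair (`f1` earlier in the table
#'   than `f2`), columns as in [cd_score()] minus the `shared` list-column.
#' @export
cd_pairs <- function(formulae, scale = 7.5) {
  n <- nrow(formulae)
  if (n < 2) {
    return(tibble(f1 = character(0), f2 = character(0),
                  n_shared = integer(0), cd_raw = numeric(0),
                  cd = numeric(0),
                  cd_band = cd_band(numeric(0))))
  }
  idx <- utils::combn(n, 2)
  rows <- purrr::map(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    sh <- shared_herbs_vec(formulae$herbs[[i]], formulae$herbs[[j]])
    raw <- cd_raw_from_shared(sh)
    tibble(f1 = formulae$name[[i]], f2 = formulae$name[[j]],
           n_shared = nrow(sh), cd_raw = raw)
  })
  out <- dplyr::bind_rows(rows)
  out$cd <- normalize_cd(out$cd_raw, scale)
  out$cd_band <- cd_band(out$cd)
  out
}
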