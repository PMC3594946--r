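#' Normalize a herb, phrase or formula label
#'
#' Labels are matched across tables by string equality, so every reader and
#' every user-facing function funnels free-text labels through this one rule:
#' lowercase, collapse internal whitespace, trim surrounding whitespace and
#' leading/trailing punctuation. The function is idempotent.
#'
#' @param x Character vector of raw labels.
#' @return Character vector of canonical labels.
#' @examples
#' normalize_label("Thunberg  Fritillary Bulb ")
#' @export
normalize_label <- function(x) {
  if (!is.character(x)) abort("`x` must be a character vector.")
  out <- tolower(x)
  out <- stringr::str_squish(out)
  out <- stringr::str_remove_all(out, "^[[:punct:]\\s]+|[[:punct:]\\s]+$")
  out <- stringr::str_squish(out)
  bad <- !is.na(out) & out == ""
  if (any(bad)) {
    abort(paste0(
      "Label(s) empty after normalization: ",
      paste(sprintf("\"%s\"", x[bad]), collapse = ", ")
    ))
  }
  out
}

# Split a "|"-delimited list cell into normalized tokens; empty cell -> chr(0).
split_list_cell <- function(x, normalize = TRUE) {
  purrr::map(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    parts <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (normalize && length(parts)) parts <- normalize_label(parts)
    parts
  })
}

join_list_cell <- function(x) {
  purrr::map_chr(x, function(v) paste(v, collapse = "|"))
}
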