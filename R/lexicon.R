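#' Attribute lexicon: natures, tastes and channel tropisms
#'
#' The annotation vocabulary used in herb tables. Natures sit on the cold-hot
#' axis; "ping" means neutral and spreads 0.25 over all four natures. Tastes
#' carry two modifier annotations, "tasteless" (adds 0.5 to sweet) and
#' "pucker" (adds 0.5 to sour). "slight" scales a base annotation to 0.8 and
#' "severe" to 1.2. Channel tropisms are plain 0/1 indicators over the twelve
#' organs.
#'
#' @name attribute-lexicon
#' @keywords internal
NULL

NATURES  <- c("cold", "cool", "warm", "hot")
TASTES   <- c("spicy", "sour", "sweet", "bitter", "salty")
CHANNELS <- c(
  "heart", "liver", "spleen", "lung", "kidney", "stomach",
  "large intestine", "small intestine", "bladder", "gallbladder",
  "pericardium", "three warmers"
)

MOD_SLIGHT <- 0.8
MOD_SEVERE <- 1.2
PING_VALUE <- 0.25

# Split "slight cold" into (modifier weight, base token). Unmodified -> 1.0.
parse_modifier <- function(token) {
  if (startsWith(token, "slight ")) {
    list(value = MOD_SLIGHT, base = sub("^slight ", "", token))
  } else if (startsWith(token, "severe ")) {
    list(value = MOD_SEVERE, base = sub("^severe ", "", token))
  } else {
    list(value = 1, base = token)
  }
}

#' Parse nature annotations into a four-component intensity vector
#'
#' @param annotations Character vector of annotations, e.g. `c("slight cold")`
#'   or `"ping"`. Each is a base nature (cold/cool/warm/hot), optionally
#'   prefixed by "slight" (0.8) or "severe" (1.2), or the single annotation
#'   "ping" (0.25 on every nature).
#' @return Named numeric vector over cold, cool, warm, hot.
#' @examples
#' parse_nature("ping")
#' parse_nature("slight cold")
#' @export
parse_nature <- function(annotations) {
  annotations <- normalize_label(as.character(annotations))
  vec <- setNames(numeric(length(NATURES)), NATURES)
  if (length(annotations) == 0) return(vec)
  if ("ping" %in% annotations) {
    if (length(annotations) > 1) {
      abort("\"ping\" cannot be combined with other nature annotations.")
    }
    vec[] <- PING_VALUE
    return(vec)
  }
  for (token in annotations) {
    m <- parse_modifier(token)
    if (!m$base %in% NATURES) {
      abort(sprintf("Unknown nature annotation: \"%s\".", token))
    }
    vec[m$base] <- m$value
  }
  vec
}

#' Parse taste annotations into a five-component intensity vector
#'
#' Base tastes score 1, "slight <taste>" scores 0.8, "tasteless" adds 0.5 to
#' sweet and "pucker" adds 0.5 to sour. The bonuses stack additively on any
#' value already present, so `c("sour", "pucker")` gives sour = 1.5.
#'
#' @param annotations Character vector of taste annotations.
#' @return Named numeric vector over spicy, sour, sweet, bitter, salty.
#' @examples
#' parse_taste("tasteless")
#' parse_taste(c("sour", "pucker"))
#' @export
parse_taste <- function(annotations) {
  annotations <- normalize_label(as.character(annotations))
  vec <- setNames(numeric(length(TASTES)), TASTES)
  for (token in annotations) {
    if (token == "tasteless") {
      vec["sweet"] <- vec["sweet"] + 0.5
    } else if (token == "pucker") {
      vec["sour"] <- vec["sour"] + 0.5
    } else {
      m <- parse_modifier(token)
      if (!m$base %in% TASTES) {
        abort(sprintf("Unknown taste annotation: \"%s\".", token))
      }
      vec[m$base] <- vec[m$base] + m$value
    }
  }
  vec
}

#' Parse channel-tropism annotations into a twelve-organ indicator vector
#'
#' @param annotations Character vector of organ labels (subset of the twelve).
#' @return Named 0/1 numeric vector over the twelve organs.
#' @examples
#' parse_channel(c("lung", "heart"))
#' @export
parse_channel <- function(annotations) {
  annotations <- normalize_label(as.character(annotations))
  vec <- setNames(numeric(length(CHANNELS)), CHANNELS)
  bad <- setdiff(annotations, CHANNELS)
  if (length(bad)) {
    abort(sprintf(
      "Unknown channel annotation(s): %s.",
      paste(sprintf("\"%s\"", bad), collapse = ", ")
    ))
  }
  vec[annotations] <- 1
  vec
}

# Vectorized safe wrappers used by the reader: annotate errors with the herb.
parse_attr_for_herb <- function(parser, annotations, herb, attr) {
  tryCatch(
    parser(annotations),
    error = function(e) {
      abort(sprintf(
        "Herb \"%s\", %s column: %s", herb, attr, conditionMessage(e)
      ))
    }
  )
}
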