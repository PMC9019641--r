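#' @keywords internal
EQ5D_DIMENSIONS <- c("mo", "sc", "ua", "pd", "ad")

#' @keywords internal
EQ5D_DIMENSION_LABELS <- c(
  mo = "mobility", sc = "self-care", ua = "usual activities",
  pd = "pain or discomfort", ad = "anxiety or depression"
)

#' Validate EQ-5D-3L health-state strings
#'
#' An EQ-5D-3L health state is written as a 5-digit string over \{1, 2, 3\},
#' one digit per dimension in the order mobility (MO), self-care (SC),
#' usual activities (UA), pain/discomfort (PD), anxiety/depression (AD);
#' "11111" is full health and "33333" the worst describable state.
#'
#' Leading/trailing whitespace is trimmed; anything else (wrong length,
#' digits outside 1-3, `NA`) is a hard error naming the offending value and,
#' where a single digit is at fault, the offending dimension.
#'
#' @param states character vector of candidate state strings.
#' @return the trimmed, validated character vector, invisibly usable
#'   downstream.
#' @examples
#' validate_states(c("11111", " 12321 "))
#' @export
validate_states <- function(states) {
  if (length(states) == 0) stop("no health states supplied")
  states <- trimws(as.character(states))
  bad_form <- is.na(states) | !grepl("^[0-9]{5}$", states)
  if (any(bad_form)) {
    stop("invalid health state(s): ",
         paste(unique(states[bad_form]), collapse = ", "),
         " (expected a 5-digit string over {1,2,3})")
  }
  lv <- state_levels_unchecked(states)
  bad <- lv < 1L | lv > 3L
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid level '%d' in dimension %s (%s) of state '%s': levels must be 1, 2 or 3",
      lv[idx[1], idx[2]], toupper(EQ5D_DIMENSIONS[idx[2]]),
      EQ5D_DIMENSION_LABELS[idx[2]], states[idx[1]]
    ))
  }
  states
}

# digits -> n x 5 integer matrix, no validation
state_levels_unchecked <- function(states) {
  m <- matrix(
    as.integer(unlist(strsplit(states, "", fixed = TRUE), use.names = FALSE)),
    ncol = 5L, byrow = TRUE
  )
  colnames(m) <- EQ5D_DIMENSIONS
  m
}

#' Decompose health states into per-dimension levels
#'
#' @inheritParams validate_states
#' @return integer matrix with one row per state and columns
#'   `mo`, `sc`, `ua`, `pd`, `ad`, entries in \{1, 2, 3\}.
#' @examples
#' state_levels("12321")
#' @export
state_levels <- function(states) {
  state_levels_unchecked(validate_states(states))
}

#' Recompose level matrices into state strings
#'
#' Inverse of [state_levels()]; `levels_to_states(state_levels(x))`
#' round-trips exactly.
#'
#' @param levels integer matrix with 5 columns, entries in \{1, 2, 3\}.
#' @return character vector of 5-digit state strings.
#' @export
levels_to_states <- function(levels) {
  levels <- as.matrix(levels)
  if (ncol(levels) != 5L) stop("'levels' must have 5 columns")
  if (!all(levels %in% 1:3)) stop("levels must be 1, 2 or 3")
  apply(levels, 1L, paste0, collapse = "")
}

#' Enumerate all 243 EQ-5D-3L health states
#'
#' @return character vector of the 3^5 = 243 distinct states, each exactly
#'   once, in lexicographic order ("11111" ... "33333").
#' @examples
#' length(enumerate_states())
#' @export
enumerate_states <- function() {
  g <- expand.grid(ad = 1:3, pd = 1:3, ua = 1:3, sc = 1:3, mo = 1:3)
  sort(paste0(g$mo, g$sc, g$ua, g$pd, g$ad))
}

#' Distance of a health state from full health
#'
#' The distance is the sum of the five dimension levels minus 5, i.e. the
#' total number of level steps separating the state from 11111. For example
#' 12321 is at distance (1+2+3+2+1) - 5 = 4.
#'
#' @inheritParams validate_states
#' @return integer vector of distances in 0..10.
#' @examples
#' distance_to_full(c("11111", "12321", "33333"))
#' @export
distance_to_full <- function(states) {
  as.integer(rowSums(state_levels(states)) - 5L)
}

#' Grade health states into four severity classes
#'
#' Rule-based classification of EQ-5D-3L states by their distance to full
#' health and level pattern:
#' \describe{
#'   \item{full}{distance 0 (the state 11111).}
#'   \item{mild}{distance 1-4, no dimension at level 3, and at most three
#'     dimensions at level 2.}
#'   \item{severe}{distance 7-9, no dimension at level 1, and at least two
#'     dimensions at level 3.}
#'   \item{moderate}{everything else (the explicit residual class).}
#' }
#' The rules are applied in the order full, mild, severe, moderate and
#' partition all 243 states.
#'
#' @inheritParams validate_states
#' @return factor with ordered levels `full < mild < moderate < severe`.
#' @examples
#' grade_states(c("11111", "21111", "12321", "33233"))
#' @export
grade_states <- function(states) {
  lv <- state_levels(states)
  d <- rowSums(lv) - 5L
  n1 <- rowSums(lv == 1L)
  n2 <- rowSums(lv == 2L)
  n3 <- rowSums(lv == 3L)
  g <- ifelse(d == 0L, "full",
       ifelse(d >= 1L & d <= 4L & n3 == 0L & n2 <= 3L, "mild",
       ifelse(d >= 7L & d <= 9L & n1 == 0L & n3 >= 2L, "severe",
              "moderate")))
  factor(g, levels = GRADE_LEVELS, ordered = TRUE)
}

#' @keywords internal
GRADE_LEVELS <- c("full", "mild", "moderate", "severe")
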