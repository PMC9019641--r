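#' Construct an EQ-5D-3L value set (tariff)
#'
#' A 3-level value set maps each of the 243 health states to a utility by
#' subtracting decrements from 1: a constant decrement `C` for departing from
#' (or, under the default convention used here, for merely describing) one's
#' health, a per-dimension per-level decrement, and an extra `N3` decrement
#' whenever any dimension is at level 3.
#'
#' @param decrements 5 x 3 numeric matrix of decrements, rows named
#'   `mo, sc, ua, pd, ad`, columns levels 1-3. Column 1 must be all zero and
#'   each row must be non-decreasing in the level.
#' @param constant_c the constant decrement C (>= 0).
#' @param n3_present decrement applied when any dimension is at level 3.
#' @param n3_absent decrement applied otherwise (conventionally 0).
#' @param name short label for the value set.
#' @return an object of class `value_set_3l`.
#' @seealso [cn_tto_value_set()] for the shipped Chinese TTO tariff,
#'   [utility()] for scoring.
#' @export
value_set_3l <- function(decrements, constant_c, n3_present, n3_absent = 0,
                         name = "custom") {
  decrements <- as.matrix(decrements)
  if (!identical(dim(decrements), c(5L, 3L)))
    stop("'decrements' must be a 5 x 3 matrix (dimensions x levels)")
  if (is.null(rownames(decrements))) rownames(decrements) <- EQ5D_DIMENSIONS
  decrements <- decrements[EQ5D_DIMENSIONS, , drop = FALSE]
  colnames(decrements) <- paste0("level", 1:3)
  if (any(decrements[, 1] != 0))
    stop("level-1 decrements must all be 0")
  if (any(decrements[, 3] < decrements[, 2]) || any(decrements[, 2] < 0))
    stop("decrements must satisfy 0 <= level2 <= level3 in every dimension")
  if (constant_c < 0 || n3_present < 0 || n3_absent < 0)
    stop("constant and N3 decrements must be non-negative")
  structure(
    list(decrements = decrements, constant_c = constant_c,
         n3_present = n3_present, n3_absent = n3_absent, name = name),
    class = "value_set_3l"
  )
}

#' The Chinese time trade-off value set for the EQ-5D-3L
#'
#' The coefficient system of the Chinese Utility Value Integral System
#' (time trade-off): per-dimension level-2/level-3 decrements, constant
#' C = 0.039 and N3 = 0.022 when any dimension is at level 3.
#'
#' @return a [value_set_3l()] object.
#' @examples
#' utility("11111", cn_tto_value_set())
#' @export
cn_tto_value_set <- function() {
  dec <- rbind(
    mo = c(0, 0.099, 0.246),
    sc = c(0, 0.105, 0.208),
    ua = c(0, 0.074, 0.193),
    pd = c(0, 0.092, 0.236),
    ad = c(0, 0.086, 0.205)
  )
  value_set_3l(dec, constant_c = 0.039, n3_present = 0.022, n3_absent = 0,
               name = "cn_tto_3l")
}

#' @export
print.value_set_3l <- function(x, ...) {
  cat("EQ-5D-3L value set:", x$name, "\n")
  print(x$decrements)
  cat(sprintf("constant C = %.3f, N3 = %.3f (present) / %.3f (absent)\n",
              x$constant_c, x$n3_present, x$n3_absent))
  invisible(x)
}

#' Score EQ-5D-3L health states to utilities
#'
#' Computes `F = 1 - C - MO - SC - UA - PD - AD - N3`, where the dimension
#' terms are the tariff decrements for the state's levels and N3 is added
#' when any dimension is at level 3.
#'
#' Two conventions exist for the constant C. The standard published Chinese
#' tariff subtracts C only when some dimension exceeds level 1, so 11111
#' scores exactly 1. The default here (`constant = "always"`) subtracts C
#' unconditionally, so 11111 scores 1 - C = 0.961 under the Chinese TTO
#' tariff; this is the convention consistent with the full-health utility
#' reported in the motivating study. Utilities are carried at full float
#' precision; round for reporting (conventionally 3 decimals).
#'
#' @inheritParams validate_states
#' @param value_set a [value_set_3l()]; default the Chinese TTO tariff.
#' @param constant `"always"` (default) subtracts C from every state;
#'   `"standard"` subtracts it only when the state differs from 11111.
#' @return numeric vector of utilities (each <= 1; may be negative).
#' @examples
#' utility(c("11111", "11112", "12321", "33333"))
#' utility("11111", constant = "standard")  # exactly 1
#' @export
utility <- function(states, value_set = cn_tto_value_set(),
                    constant = c("always", "standard")) {
  constant <- match.arg(constant)
  stopifnot(inherits(value_set, "value_set_3l"))
  lv <- state_levels(states)
  dec <- value_set$decrements
  dim_sum <- rowSums(matrix(
    dec[cbind(rep(1:5, each = nrow(lv)), as.vector(lv))],
    ncol = 5L
  ))
  any3 <- rowSums(lv == 3L) > 0L
  n3 <- ifelse(any3, value_set$n3_present, value_set$n3_absent)
  cc <- if (constant == "always") value_set$constant_c
        else ifelse(rowSums(lv) > 5L, value_set$constant_c, 0)
  1 - cc - dim_sum - n3
}

#' Read / write value sets as delimited text
#'
#' The on-disk format is a plain CSV with columns `term`, `level`, `value`:
#' one row per dimension-level decrement (`term` in `mo, sc, ua, pd, ad`,
#' `level` 1-3) plus rows `constant` (C), `n3_present` and `n3_absent`
#' (with empty `level`). The package ships the Chinese TTO tariff at
#' `system.file("extdata", "cn_tto_3l.csv", package = "eq5dhrqol")`.
#'
#' @param path file path.
#' @return `read_value_set()` returns a [value_set_3l()];
#'   `write_value_set()` returns `path` invisibly.
#' @export
read_value_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term", "level", "value")
  if (!all(need %in% names(df)))
    stop("value-set file must have columns term, level, value")
  dec <- matrix(0, 5, 3, dimnames = list(EQ5D_DIMENSIONS, NULL))
  for (d in EQ5D_DIMENSIONS) for (l in 1:3) {
    row <- df$term == d & !is.na(df$level) & df$level == l
    if (sum(row) != 1) stop("missing or duplicated entry for ", d, " level ", l)
    dec[d, l] <- df$value[row]
  }
  scalar <- function(term) {
    row <- df$term == term
    if (sum(row) != 1) stop("missing or duplicated entry for '", term, "'")
    df$value[row]
  }
  value_set_3l(dec, constant_c = scalar("constant"),
               n3_present = scalar("n3_present"),
               n3_absent = scalar("n3_absent"),
               name = tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_value_set
#' @param value_set a [value_set_3l()] to serialize.
#' @export
write_value_set <- function(value_set, path) {
  stopifnot(inherits(value_set, "value_set_3l"))
  df <- data.frame(
    term = c(rep(EQ5D_DIMENSIONS, each = 3), "constant", "n3_present", "n3_absent"),
    level = c(rep(1:3, 5), NA, NA, NA),
    value = c(as.vector(t(value_set$decrements)),
              value_set$constant_c, value_set$n3_present, value_set$n3_absent)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
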