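#' Construct a contingency table of counts
#'
#' Thin validated wrapper around an r x c matrix of non-negative integer
#' counts with row and column labels; the common input type for
#' [chi_square()] and [fisher_exact()].
#'
#' @param counts matrix (or object coercible to one) of counts, r >= 2 rows
#'   and c >= 2 columns, all entries non-negative integers, grand total >= 1.
#' @param row_labels,col_labels optional character labels; default taken from
#'   `dimnames(counts)` or generated.
#' @return an integer matrix of class `contingency_table`.
#' @examples
#' contingency_table(rbind(c(86, 95), c(47, 22)),
#'                   row_labels = c("18-35", "35-53"),
#'                   col_labels = c("hiv_positive", "hiv_negative"))
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("a contingency table needs at least 2 rows and 2 columns")
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  counts <- matrix(as.integer(round(counts)), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  if (sum(counts) < 1L) stop("grand total must be at least 1")
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  if (is.null(rownames(counts))) rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  class(counts) <- c("contingency_table", class(counts))
  counts
}

as_counts <- function(table) {
  if (inherits(table, "contingency_table")) unclass(table)
  else unclass(contingency_table(table))
}

#' @keywords internal
new_test_result <- function(method, p_value, statistic = NA_real_,
                            df = NA_integer_, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = min(p_value, 1), note = note),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %.4f, df = %s\n", x$statistic,
                ifelse(is.na(x$df), "-", x$df)))
  cat("  p-value =", format_p(x$p_value), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# journal-style p formatting: ".002", "<.001", ".95"
format_p <- function(p) {
  ifelse(p < 0.001, "<.001",
         sub("^0\\.", ".", sprintf(ifelse(p < 0.01, "%.3f", "%.2f"), p)))
}
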