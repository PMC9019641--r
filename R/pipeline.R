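#' Cross-tabulate two respondent variables
#'
#' Counts of `row_var` by `col_var` with label order fixed by the schema
#' vocabularies ([cohort_vocab()]; the derived `grade` column uses the
#' severity order full, mild, moderate, severe). Every respondent falls in
#' exactly one cell.
#'
#' @param cohort respondent data.frame (a `grade`/`utility` column may be
#'   present, e.g. from [score_cohort()]).
#' @param row_var,col_var column names.
#' @return a [contingency_table()].
#' @examples
#' crosstab(fixture_cohort(), "age_band", "group")
#' @export
crosstab <- function(cohort, row_var, col_var) {
  for (v in c(row_var, col_var))
    if (!v %in% names(cohort)) stop("unknown variable: ", v)
  lev <- function(v) {
    vocab <- cohort_vocab()
    if (v == "grade") GRADE_LEVELS
    else if (v == "insured") c("TRUE", "FALSE")
    else if (v %in% names(vocab)) vocab[[v]]
    else sort(unique(as.character(cohort[[v]])))
  }
  tab <- table(factor(as.character(cohort[[row_var]]), levels = lev(row_var)),
               factor(as.character(cohort[[col_var]]), levels = lev(col_var)))
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  contingency_table(counts)
}

#' Score and grade a respondent cohort
#'
#' Appends `utility`, `grade` and `distance` columns computed from the
#' `state` column.
#'
#' @param cohort respondent data.frame (validated).
#' @param value_set a [value_set_3l()].
#' @param constant constant-C convention, see [utility()].
#' @return the cohort with three extra columns.
#' @export
score_cohort <- function(cohort, value_set = cn_tto_value_set(),
                         constant = c("always", "standard")) {
  constant <- match.arg(constant)
  cohort <- validate_cohort(cohort)
  cohort$utility <- utility(cohort$state, value_set, constant)
  cohort$grade <- as.character(grade_states(cohort$state))
  cohort$distance <- distance_to_full(cohort$state)
  cohort
}

# test-selection policy for association tables: exact test when any expected
# count is below `exact_threshold` and the enumeration is affordable;
# otherwise Pearson chi-square (Yates on 2x2 only).
association_test <- function(table, exact_threshold = 5, max_tables = 1e6) {
  counts <- as_counts(table)
  keep_r <- rowSums(counts) > 0; keep_c <- colSums(counts) > 0
  counts <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2)
    return(new_test_result("not testable (degenerate table)", p_value = 1,
                           note = "fewer than 2 non-empty rows or columns"))
  e <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(e < exact_threshold)) {
    ft <- tryCatch(fisher_exact(counts, max_tables = max_tables),
                   error = function(err) NULL)
    if (!is.null(ft)) return(ft)
  }
  chi_square(counts, yates = nrow(counts) == 2 && ncol(counts) == 2)
}

#' Run the full cross-sectional HRQoL analysis
#'
#' End-to-end battery on a respondent cohort: baseline demographic
#' comparisons between HIV groups (chi-square, Yates on 2x2), per-dimension
#' EQ-5D-3L level tables with Freeman-Halton exact tests, utility summaries
#' (median/IQR and full-health counts), the four-level grade table with the
#' group-comparison chi-square, grade-by-factor association tests, and a
#' proportional-odds ordinal regression of grade on age band and prenatal
#' care visits.
#'
#' Severe-grade respondents are kept in the utility summaries and dimension
#' tables but excluded (with a logged notice) from the grade-comparison
#' test, the grade-by-factor tests and the ordinal regression, mirroring the
#' motivating study's handling of its single severe respondent.
#'
#' @param cohort respondent data.frame or path to a respondent CSV.
#' @param value_set tariff used for scoring.
#' @param constant constant-C convention, see [utility()].
#' @param quantile_type convention for [median_iqr()].
#' @param exact_threshold expected-count threshold below which grade-factor
#'   tables use the exact test.
#' @param max_tables enumeration guard forwarded to [fisher_exact()].
#' @param quiet suppress the exclusion notice.
#' @return an object of class `study_report`; see [write_study_report()].
#' @examples
#' rep <- run_study(fixture_cohort())
#' rep$utility_summary$hiv_positive$median
#' @export
run_study <- function(cohort, value_set = cn_tto_value_set(),
                      constant = c("always", "standard"),
                      quantile_type = c("linear", "nearest"),
                      exact_threshold = 5, max_tables = 1e6, quiet = FALSE) {
  constant <- match.arg(constant)
  quantile_type <- match.arg(quantile_type)
  if (is.character(cohort) && length(cohort) == 1) cohort <- read_cohort(cohort)
  scored <- score_cohort(cohort, value_set, constant)
  n_g <- table(factor(scored$group, levels = COHORT_GROUPS))
  if (any(n_g == 0))
    stop("both groups must be present; missing: ",
         paste(COHORT_GROUPS[n_g == 0], collapse = ", "))

  demo_vars <- c("age_band", "education", "occupation", "income_band",
                 "prenatal_visits_band", "family_size_band", "insured")
  baseline <- lapply(demo_vars, function(v) {
    tab <- crosstab(scored, v, "group")
    list(variable = v, counts = tab,
         test = chi_square(tab, yates = nrow(tab) == 2))
  })
  names(baseline) <- demo_vars

  dimensions <- lapply(EQ5D_DIMENSIONS, function(d) {
    lv <- state_levels(scored$state)[, d]
    counts <- contingency_table(
      table(factor(lv, levels = 1:3),
            factor(scored$group, levels = COHORT_GROUPS)))
    list(dimension = d, counts = counts,
         test = fisher_exact(counts, max_tables = max_tables))
  })
  names(dimensions) <- EQ5D_DIMENSIONS

  util_sum <- function(rows) {
    q <- median_iqr(rows$utility, type = quantile_type)
    full_n <- sum(rows$grade == "full")
    list(n = nrow(rows), median = unname(q["median"]), q1 = unname(q["q1"]),
         q3 = unname(q["q3"]), full_n = full_n,
         full_pct = round(100 * full_n / nrow(rows), 2))
  }
  utility_summary <- c(
    lapply(split(scored, factor(scored$group, COHORT_GROUPS)), util_sum),
    list(overall = util_sum(scored))
  )

  grade_table <- crosstab(scored, "grade", "group")
  excluded <- scored$id[scored$grade == "severe"]
  if (length(excluded) && !quiet)
    message("excluding ", length(excluded), " severe-grade respondent(s) ",
            "from grade-association analyses: ",
            paste(excluded, collapse = ", "))
  nonsev <- scored[scored$grade != "severe", , drop = FALSE]
  grade_nonsev <- crosstab(nonsev, "grade", "group")
  grade_nonsev <- contingency_table(
    grade_nonsev[rowSums(grade_nonsev) > 0, , drop = FALSE])
  grade_test <- chi_square(grade_nonsev,
                           yates = nrow(grade_nonsev) == 2)

  factors <- lapply(demo_vars, function(v) {
    tab <- crosstab(nonsev, "grade", v)
    tab <- contingency_table(tab[rowSums(tab) > 0, , drop = FALSE])
    list(variable = v, counts = tab,
         test = association_test(tab, exact_threshold, max_tables))
  })
  names(factors) <- demo_vars

  ord_outcome <- factor(nonsev$grade, levels = setdiff(GRADE_LEVELS, "severe"),
                        ordered = TRUE)
  x <- cbind(age_35_53 = as.numeric(nonsev$age_band == "35-53"),
             prenatal_visits = match(nonsev$prenatal_visits_band,
                                     cohort_vocab()$prenatal_visits_band))
  ordinal <- fit_proportional_odds(ord_outcome, x)

  structure(list(
    n_per_group = as.list(n_g),
    baseline = baseline,
    dimensions = dimensions,
    utility_summary = utility_summary,
    grade_table = grade_table,
    grade_test = grade_test,
    factors = factors,
    ordinal = ordinal,
    excluded_ids = excluded,
    config = list(value_set = value_set$name, constant = constant,
                  quantile_type = quantile_type,
                  exact_threshold = exact_threshold, max_tables = max_tables)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("HRQoL study report: %d HIV-positive, %d HIV-negative\n",
              x$n_per_group$hiv_positive, x$n_per_group$hiv_negative))
  cat("\nUtility summaries (median [Q1, Q3]; full health n (%)):\n")
  for (g in names(x$utility_summary)) {
    s <- x$utility_summary[[g]]
    cat(sprintf("  %-13s %.3f [%.3f, %.3f]; full health %d (%.2f%%)\n",
                g, s$median, s$q1, s$q3, s$full_n, s$full_pct))
  }
  cat("\nDimension comparisons (Freeman-Halton exact):\n")
  for (d in names(x$dimensions))
    cat(sprintf("  %-3s p = %s\n", d, format_p(x$dimensions[[d]]$test$p_value)))
  cat(sprintf("\nGrade comparison (severe excluded): chi2 = %.3f, df %d, p = %s\n",
              x$grade_test$statistic, x$grade_test$df,
              format_p(x$grade_test$p_value)))
  cat("\nOrdinal regression (grade ~ age band + prenatal visits):\n")
  print(round(cbind(B = x$ordinal$coefficients, se = x$ordinal$se_coefficients,
                    OR = x$ordinal$odds_ratio), 4))
  invisible(x)
}

# convert a report into plain lists for JSON
report_as_list <- function(report) {
  tab2list <- function(tab) list(rows = rownames(tab), cols = colnames(tab),
                                 counts = unclass(unname(apply(tab, 1, as.integer,
                                                               simplify = FALSE))))
  test2list <- function(t) list(method = t$method,
                                statistic = if (is.na(t$statistic)) NULL else t$statistic,
                                df = if (is.na(t$df)) NULL else t$df,
                                p_value = t$p_value)
  block <- function(b) list(counts = tab2list(b$counts), test = test2list(b$test))
  ord <- report$ordinal
  list(
    n_per_group = report$n_per_group,
    baseline = lapply(report$baseline, block),
    dimensions = lapply(report$dimensions, block),
    utility_summary = report$utility_summary,
    grade_table = tab2list(report$grade_table),
    grade_test = test2list(report$grade_test),
    factors = lapply(report$factors, block),
    ordinal = list(
      levels = ord$levels, converged = ord$converged,
      thresholds = as.list(ord$thresholds),
      se_thresholds = as.list(stats::setNames(ord$se_thresholds,
                                              names(ord$thresholds))),
      coefficients = as.list(ord$coefficients),
      se_coefficients = as.list(ord$se_coefficients),
      odds_ratio = as.list(ord$odds_ratio),
      ci_lower = as.list(ord$ci_lower), ci_upper = as.list(ord$ci_upper),
      log_lik = ord$log_lik, n = ord$n
    ),
    excluded_ids = as.list(report$excluded_ids),
    config = report$config
  )
}

#' Write a study report as JSON plus delimited tables
#'
#' The JSON carries raw floats; the optional delimited tables are
#' human-readable TSVs with journal-style p-values (".002", "<.001").
#'
#' @param report a `study_report` from [run_study()].
#' @param json_path output path for the JSON report.
#' @param tables_dir optional directory for TSV tables (created if needed).
#' @return `json_path`, invisibly.
#' @export
write_study_report <- function(report, json_path, tables_dir = NULL) {
  stopifnot(inherits(report, "study_report"))
  jsonlite::write_json(report_as_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(tables_dir)) {
    dir.create(tables_dir, showWarnings = FALSE, recursive = TRUE)
    dump_blocks <- function(blocks, file) {
      con <- file.path(tables_dir, file)
      lines <- character(0)
      for (b in blocks) {
        tab <- b$counts; t <- b$test
        lines <- c(lines,
                   paste0("# ", b$variable %||% b$dimension,
                          "\tstatistic=", ifelse(is.na(t$statistic), "-",
                                                 sprintf("%.3f", t$statistic)),
                          "\tdf=", ifelse(is.na(t$df), "-", t$df),
                          "\tp=", format_p(t$p_value)),
                   paste(c("", colnames(tab)), collapse = "\t"),
                   vapply(seq_len(nrow(tab)), function(i)
                     paste(c(rownames(tab)[i], tab[i, ]), collapse = "\t"),
                     character(1)),
                   "")
      }
      writeLines(lines, con)
    }
    dump_blocks(report$baseline, "baseline.tsv")
    dump_blocks(report$dimensions, "dimensions.tsv")
    dump_blocks(list(list(variable = "grade_by_group_all",
                          counts = report$grade_table,
                          test = report$grade_test)), "grades.tsv")
    dump_blocks(report$factors, "factors.tsv")
  }
  invisible(json_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
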