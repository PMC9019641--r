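# independent oracles used across test files

# textbook closed form for the 2x2 Pearson statistic (no correction)
chisq_2x2_closed_form <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# two-sided Fisher exact p for a 2x2 by direct hypergeometric summation
fisher_2x2_hypergeom <- function(m, tie_tol = 1e-7) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(support, rs[1], rs[2], cs[1])
  p_obs <- dhyper(m[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

# random r x c count table with no empty margins
random_table <- function(r, c, lambda = 8) {
  repeat {
    m <- matrix(rpois(r * c, lambda), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# Cramer's V from a count table, dropping empty rows/columns
cramers_v <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - e)^2 / e)
  sqrt(chi2 / (sum(tab) * (min(dim(tab)) - 1)))
}

# study margins as used by the fixture tests (counts, per group)
expected_margins <- function() {
  list(
    hiv_positive = list(
      n = 133L,
      dimensions = rbind(mo = c(119, 14, 0), sc = c(130, 3, 0),
                         ua = c(109, 23, 1), pd = c(98, 34, 1),
                         ad = c(77, 52, 4)),
      demographics = list(
        age_band = c(86, 47), education = c(114, 19), occupation = c(118, 15),
        income_band = c(70, 63), prenatal_visits_band = c(48, 34, 20, 31),
        family_size_band = c(18, 70, 45), insured = c(126, 7))
    ),
    hiv_negative = list(
      n = 117L,
      dimensions = rbind(mo = c(107, 9, 1), sc = c(115, 2, 0),
                         ua = c(104, 11, 2), pd = c(91, 24, 2),
                         ad = c(90, 22, 5)),
      demographics = list(
        age_band = c(95, 22), education = c(92, 25), occupation = c(102, 15),
        income_band = c(51, 66), prenatal_visits_band = c(56, 25, 16, 20),
        family_size_band = c(16, 58, 43), insured = c(112, 5))
    )
  )
}
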