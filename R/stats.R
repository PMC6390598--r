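as_count_matrix <- function(table) {
  m <- as.matrix(table)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("contingency table must contain non-negative integer counts")
  }
  storage.mode(m) <- "double"
  if (sum(m) == 0) stop("contingency table is empty")
  m
}

# log multivariate hypergeometric probability of a margin-fixed table
log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

#' Exact Fisher test for a 2x2 table (minimum-likelihood two-sided)
#'
#' Enumerates every 2x2 table with the observed margins and sums the
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (ties included).  This is the
#' two-sided convention that reproduces standard software output for
#' cohort characteristic tables.
#'
#' @param table A 2x2 matrix (or coercible) of non-negative counts.
#' @return An object of class `htest` with the two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(23, 1, 34, 6), nrow = 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_count_matrix(table)
  if (!all(dim(m) == c(2, 2))) stop("fisher_exact_2x2 expects a 2x2 table")
  r <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(r == 0) || any(cs == 0)) stop("all margins must be positive")
  k <- max(0, cs[1] - r[2]):min(r[1], cs[1])
  logp <- dhyper(k, r[1], r[2], cs[1], log = TRUE)
  logp_obs <- dhyper(m[1, 1], r[1], r[2], cs[1], log = TRUE)
  p <- sum(exp(logp[logp <= logp_obs + 1e-7]))
  structure(list(
    statistic = NULL, p.value = min(p, 1),
    method = "Exact Fisher test (two-sided, minimum likelihood)",
    alternative = "two.sided",
    data.name = deparse(substitute(table))
  ), class = "htest")
}

# enumerate all tables with the given margins, calling fn(logprob) per
# table; errors out past `limit` tables
enumerate_tables <- function(row_margins, col_margins, fn, limit = 1e7) {
  r <- length(row_margins)
  nc <- length(col_margins)
  # cheap upper bound on the number of candidate tables (compositions per
  # row ignoring column caps); refuse infeasible enumerations up front
  est <- prod(choose(row_margins + nc - 1, nc - 1))
  if (!is.finite(est) || est > limit) {
    stop("exact enumeration guard exceeded (more than ", limit,
         " candidate tables); use freeman_halton_mc() instead")
  }
  count <- 0L
  cell_rows <- matrix(0, nrow = r, ncol = nc)
  recurse <- function(i, cols_left) {
    if (i > r) {
      count <<- count + 1L
      fn(log_table_prob(cell_rows))
      return(invisible())
    }
    for (comp in compositions(row_margins[i], cols_left)) {
      cell_rows[i, ] <<- comp
      recurse(i + 1L, cols_left - comp)
    }
  }
  recurse(1L, col_margins)
  count
}

# all vectors x >= 0 with sum(x) == total and x <= caps, as a list
compositions <- function(total, caps) {
  cvals <- function(j, rem) {
    if (j == length(caps)) {
      if (rem <= caps[j]) return(list(rem)) else return(list())
    }
    out <- list()
    for (v in max(0, rem - sum(caps[(j + 1):length(caps)])):min(caps[j], rem)) {
      for (tail in cvals(j + 1L, rem - v)) out[[length(out) + 1L]] <- c(v, tail)
    }
    out
  }
  cvals(1L, total)
}

#' Freeman-Halton exact test for an r x c table
#'
#' The exact (Fisher-type) test for a general r x c contingency table:
#' all tables with the observed row and column margins are enumerated, and
#' the p-value is the sum of multivariate-hypergeometric probabilities of
#' the tables whose probability does not exceed the observed table's
#' probability (ties included).  Reduces exactly to [fisher_exact_2x2()]
#' on 2x2 input.  Enumeration is guarded at `limit` tables.
#'
#' @param table An r x c matrix (or coercible) of non-negative counts.
#' @param limit Maximum number of tables to enumerate before erroring and
#'   advising the Monte-Carlo fallback.
#' @param check If `TRUE`, verify that the enumerated probabilities sum to
#'   1 within 1e-9 (exact-test conservation law).
#' @return An object of class `htest`; `attr(, "total_prob")` carries the
#'   enumerated probability mass.
#' @examples
#' # genotype (rows L858R / exon19del / G719X) by compound/single status
#' freeman_halton_test(matrix(c(4, 38, 0, 17, 3, 2), nrow = 3, byrow = TRUE))
#' @export
freeman_halton_test <- function(table, limit = 1e7, check = FALSE) {
  m <- as_count_matrix(table)
  r <- rowSums(m); cs <- colSums(m)
  logp_obs <- log_table_prob(m)
  p <- 0; total <- 0
  enumerate_tables(r, cs, function(lp) {
    pr <- exp(lp)
    total <<- total + pr
    if (lp <= logp_obs + 1e-7) p <<- p + pr
  }, limit = limit)
  if (check && abs(total - 1) > 1e-9) {
    stop("enumerated probabilities sum to ", total, ", not 1")
  }
  structure(list(
    statistic = NULL, p.value = min(p, 1),
    method = "Freeman-Halton exact test (two-sided, minimum likelihood)",
    alternative = "two.sided",
    data.name = deparse(substitute(table))
  ), class = "htest", total_prob = total)
}

#' Monte-Carlo Freeman-Halton p-value
#'
#' Estimates the exact p-value by sampling margin-fixed tables from the
#' null (Patefield's algorithm via [stats::r2dtable()]) and counting draws
#' whose probability does not exceed the observed table's.
#'
#' @param table An r x c count matrix.
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Optional seed.
#' @return A list with `p.value` and its Monte-Carlo standard error.
#' @export
freeman_halton_mc <- function(table, n_draws = 1e5, seed = NULL) {
  m <- as_count_matrix(table)
  logp_obs <- log_table_prob(m)
  with_seed_if(seed, {
    draws <- stats::r2dtable(n_draws, rowSums(m), colSums(m))
    lp <- vapply(draws, log_table_prob, numeric(1))
    hit <- lp <= logp_obs + 1e-7
    list(p.value = mean(hit),
         se = stats::sd(hit) / sqrt(n_draws))
  })
}

#' Pearson chi-square test for an r x c table
#'
#' Pearson statistic (no continuity correction) with
#' `df = (r - 1) * (c - 1)`; at df = 2 the upper-tail p-value has the
#' closed form `exp(-chisq / 2)`, used as an analytic cross-check.
#'
#' @param table An r x c count matrix.
#' @return An object of class `htest`.
#' @export
chisq_rxc <- function(table) {
  m <- as_count_matrix(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) stop("zero expected cell count")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  res$method <- "Pearson chi-square test (no continuity correction)"
  res
}

#' Pooled two-sample t-test from group summaries
#'
#' Student's t-test computed from (n, mean, sd) summaries of two groups
#' using the pooled variance, df = n1 + n2 - 2, two-sided.  This is the
#' form recoverable from published mean +/- SD rows.
#'
#' @param n1,mean1,sd1 Summary statistics of group 1 (sample SD).
#' @param n2,mean2,sd2 Summary statistics of group 2.
#' @return An object of class `htest`.
#' @examples
#' t_test_summary(57, 66.4, 9.6, 7, 66.7, 9.3)
#' @export
t_test_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(
    statistic = c(t = tt), parameter = c(df = df),
    p.value = 2 * pt(-abs(tt), df),
    method = "Pooled two-sample t-test from summary statistics",
    alternative = "two.sided",
    estimate = c(`mean difference` = mean1 - mean2),
    data.name = "group summaries"
  ), class = "htest")
}

#' Build the genotype-by-compound-status contingency table
#'
#' Cross-tabulates per-patient records into the fixed-order 3 x 2 table
#' (rows L858R, exon19del, G719X; columns compound, single) analysed with
#' the Freeman-Halton exact test.
#'
#' @param records A data frame with columns `genotype` (one of `"L858R"`,
#'   `"exon19del"`, `"G719X"`) and `status` (`"single"`/`"compound"`).
#' @return A 3 x 2 integer matrix with dimnames.
#' @export
build_compound_table <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) stop("no cohort records supplied")
  genotypes <- c("L858R", "exon19del", "G719X")
  bad <- setdiff(unique(records$genotype), genotypes)
  if (length(bad) > 0) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  bad_s <- setdiff(unique(records$status), c("single", "compound"))
  if (length(bad_s) > 0) stop("unknown status: ", paste(bad_s, collapse = ", "))
  tab <- table(factor(records$genotype, genotypes),
               factor(records$status, c("compound", "single")))
  m <- matrix(as.integer(tab), nrow = 3,
              dimnames = list(genotype = genotypes,
                              status = c("compound", "single")))
  m
}
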