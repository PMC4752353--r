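# Frequency tests used alongside the multivariate machinery: the G-test
# (log-likelihood ratio) with pairwise batteries, the Fisher exact test and
# the Kruskal-Wallis rank test.

freq_test_result <- function(statistic, df, p, method, dims = NULL) {
  structure(list(statistic = statistic, df = df, p.value = p,
                 method = method, dims = dims),
            class = "freq_test")
}

#' @export
print.freq_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && !is.na(x$statistic)) {
    cat(sprintf("statistic = %.5g", x$statistic))
    if (!is.null(x$df) && !is.na(x$df)) cat(sprintf(", df = %g", x$df))
    cat(", ")
  }
  cat(sprintf("p = %.5g\n", x$p.value))
  invisible(x)
}

#' G-test (log-likelihood ratio test) of frequencies
#'
#' G = 2 * sum O * ln(O / E) over cells with O > 0; df = k - 1 for a
#' one-way table against given or uniform expectations, (r-1)(c-1) for a
#' two-way table against independence; p from the upper chi-squared tail.
#' No Williams or Yates correction is applied by default; a Williams
#' correction is available by flag.
#'
#' @param observed count vector (one-way) or matrix (two-way).
#' @param expected optional expected counts or probabilities (one-way only);
#'   defaults to uniform (one-way) or the independence expectation
#'   (two-way).
#' @param williams apply the Williams correction (divides G by the Williams
#'   q factor).
#' @return a `freq_test` result with `statistic` (G), `df`, `p.value`.
#' @export
#' @examples
#' g_test(c(10, 20))  # G = 3.398, df = 1
g_test <- function(observed, expected = NULL, williams = FALSE) {
  if (anyNA(observed) || any(observed < 0)) stop("counts must be non-negative")
  if (is.matrix(observed)) {
    if (!is.null(expected)) stop("expected is only supported for one-way tables")
    rs <- rowSums(observed); cs <- colSums(observed); N <- sum(observed)
    if (N == 0) stop("table is empty")
    E <- outer(rs, cs) / N
    df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
    dims <- dim(observed)
  } else {
    O <- observed
    if (is.null(expected)) {
      E <- rep(sum(O) / length(O), length(O))
    } else {
      if (length(expected) != length(O)) stop("expected length mismatch")
      if (any(expected < 0)) stop("expected must be non-negative")
      E <- expected / sum(expected) * sum(O)
    }
    df <- length(observed) - 1L
    dims <- length(observed)
    observed <- O
  }
  if (any(E == 0 & observed > 0)) {
    stop("expected cell is zero where observed count is positive")
  }
  keep <- observed > 0
  G <- 2 * sum(observed[keep] * log(observed[keep] / E[keep]))
  if (williams) {
    N <- sum(observed)
    qw <- if (is.matrix(observed)) {
      1 + ((N * sum(1 / rowSums(observed)) - 1) *
             (N * sum(1 / colSums(observed)) - 1)) / (6 * N * df)
    } else {
      1 + (length(observed)^2 - 1) / (6 * N * df)
    }
    G <- G / qw
  }
  freq_test_result(G, df, stats::pchisq(G, df, lower.tail = FALSE),
                   if (williams) "G-test (Williams-corrected)" else "G-test",
                   dims)
}

#' Pairwise G-tests between groups
#'
#' Tests every unordered pair of rows of a group x category count table with
#' a two-way [g_test()] on the 2 x k subtable (columns that are zero in both
#' rows are dropped). Raw p-values are reported by default, mirroring how
#' such pairwise batteries are usually tabulated; Holm adjustment is
#' available.
#'
#' @param counts matrix of counts with one row per group (rownames used as
#'   labels).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param williams passed to [g_test()].
#' @return symmetric matrix of p-values (diagonal `NA`), with attribute
#'   `"G"` carrying the matching G statistics.
#' @export
pairwise_g_tests <- function(counts, adjust = "none", williams = FALSE) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (k < 2L) stop("need at least 2 groups")
  labs <- rownames(counts) %||% as.character(seq_len(k))
  pr <- utils::combn(k, 2L)
  p <- g <- numeric(ncol(pr))
  for (j in seq_len(ncol(pr))) {
    sub <- counts[pr[, j], , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    ft <- g_test(sub, williams = williams)
    p[j] <- ft$p.value; g[j] <- ft$statistic
  }
  if (adjust != "none") p <- stats::p.adjust(p, adjust)
  P <- G <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (j in seq_len(ncol(pr))) {
    P[pr[1, j], pr[2, j]] <- P[pr[2, j], pr[1, j]] <- p[j]
    G[pr[1, j], pr[2, j]] <- G[pr[2, j], pr[1, j]] <- g[j]
  }
  attr(P, "G") <- G
  attr(P, "adjust") <- adjust
  P
}

#' Fisher exact test
#'
#' For 2 x 2 tables: the exact two-sided p-value by hypergeometric
#' enumeration, defined as the sum of the probabilities of all tables (with
#' the observed margins) whose probability does not exceed that of the
#' observed table -- the common two-sided convention (conventions differ;
#' this one matches [stats::fisher.test()]). For larger tables the p-value
#' is estimated by Monte-Carlo simulation of tables with fixed margins.
#'
#' @param table count matrix.
#' @param mc_reps Monte-Carlo replicates for tables larger than 2 x 2.
#' @param seed integer seed for the Monte-Carlo path.
#' @return a `freq_test` result (statistic is `NA`: the test is defined by
#'   its p-value).
#' @export
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2))  # p = 1/3
fisher_exact <- function(table, mc_reps = 10000, seed = NULL) {
  table <- as.matrix(table)
  if (anyNA(table) || any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margin (empty row or column): p = 1")
    return(freq_test_result(NA_real_, NA_integer_, 1,
                            "Fisher exact test (degenerate margins)",
                            dim(table)))
  }
  if (all(dim(table) == 2L)) {
    m <- sum(table[1, ]); n <- sum(table[2, ]); kk <- sum(table[, 1])
    a_range <- max(0L, kk - n):min(kk, m)
    probs <- stats::dhyper(a_range, m, n, kk)
    p_obs <- stats::dhyper(table[1, 1], m, n, kk)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(freq_test_result(NA_real_, NA_integer_, min(p, 1),
                            "Fisher exact test (2x2, enumeration)",
                            dim(table)))
  }
  p <- with_seed(seed, {
    stats::fisher.test(table, simulate.p.value = TRUE, B = mc_reps)$p.value
  })
  freq_test_result(NA_real_, NA_integer_, p,
                   sprintf("Fisher exact test (Monte-Carlo, B = %d)", mc_reps),
                   dim(table))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based comparison of two or more numeric samples (tie-corrected H,
#' chi-squared reference with groups - 1 df), as used for comparing the
#' visually estimated plant fraction of pellets across seasons. Delegates to
#' [stats::kruskal.test()].
#'
#' @param x list of numeric vectors, or a numeric vector.
#' @param g grouping vector when `x` is a vector.
#' @return a `freq_test` result with `statistic` (H), `df`, `p.value`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 3.857
kruskal_wallis <- function(x, g = NULL) {
  vals <- if (is.list(x)) unlist(x) else x
  k <- if (is.list(x)) length(x) else length(unique(g))
  if (length(unique(vals)) == 1L) {
    # all observations tied: H degenerates to 0, no evidence of difference
    return(freq_test_result(0, k - 1L, 1, "Kruskal-Wallis rank sum test"))
  }
  kt <- if (is.list(x)) stats::kruskal.test(x) else stats::kruskal.test(x, g)
  freq_test_result(unname(kt$statistic), unname(kt$parameter), kt$p.value,
                   "Kruskal-Wallis rank sum test")
}
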