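# Hill-number ("true diversity") profiles and bootstrap Tukey-like
# contrasts. All indices are expressed as members of Hill's one-parameter
# family ^qD: q = 0 gives richness, q -> 1 the exponential of Shannon
# entropy, q = 2 the inverse Simpson concentration; larger q down-weights
# rare categories, negative q up-weights them.

#' Hill number of order q
#'
#' ^qD = (sum_i p_i^q)^(1/(1-q)) for q != 1 and exp(-sum_i p_i log p_i) at
#' q = 1, with p_i the relative abundances over categories with positive
#' counts. Zero-count categories are excluded for every q (mandatory for
#' q < 0, where 0^q diverges).
#'
#' @param counts non-negative count (or abundance) vector with positive sum.
#' @param q diversity order (any real; vectorised).
#' @return `^qD` (>= 1), one value per element of `q`.
#' @export
#' @examples
#' hill_number(c(80, 20), q = 0:2)  # 2, 1.649, 1.471
hill_number <- function(counts, q) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("all counts are zero")
  p <- counts[counts > 0] / tot
  vapply(q, function(qi) {
    if (qi == 0) {
      length(p)  # richness, exactly
    } else if (abs(qi - 1) < 1e-12) {
      exp(-sum(p * log(p)))
    } else {
      exp(log(sum(p^qi)) / (1 - qi))
    }
  }, numeric(1))
}

# Hill numbers for each column of a count matrix (categories x replicates);
# used by the bootstrap where many pooled count vectors are evaluated.
hill_cols <- function(M, q) {
  tot <- colSums(M)
  P <- sweep(M, 2L, tot, "/")
  out <- matrix(NA_real_, length(q), ncol(M))
  for (k in seq_along(q)) {
    qi <- q[k]
    if (qi == 0) {
      out[k, ] <- colSums(M > 0)
    } else if (abs(qi - 1) < 1e-12) {
      PL <- P * log(P)
      PL[P == 0] <- 0
      out[k, ] <- exp(-colSums(PL))
    } else {
      Pq <- P^qi
      Pq[P == 0] <- 0
      out[k, ] <- exp(log(colSums(Pq)) / (1 - qi))
    }
  }
  out
}

#' Simpson concentration and diversity with variance
#'
#' Simpson concentration lambda = sum_i p_i^2 (the probability that two
#' randomly drawn items share a category), Gini-Simpson diversity
#' 1 - lambda, and the classical large-sample variance estimator
#' var = (4/N) * (sum_i p_i^3 - (sum_i p_i^2)^2).
#'
#' @param counts non-negative count vector with total N >= 2.
#' @return list with `lambda`, `diversity` (1 - lambda), `variance`, `n_items`.
#' @export
#' @examples
#' simpson_with_variance(c(80, 20))
simpson_with_variance <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (N < 2) stop("need at least 2 items")
  p <- counts / N
  lambda <- sum(p^2)
  list(lambda = lambda, diversity = 1 - lambda,
       variance = (4 / N) * (sum(p^3) - lambda^2), n_items = N)
}

#' Diversity profile per group
#'
#' Pools counts over pellets (or availability samples) within each group and
#' evaluates Hill numbers over a grid of orders, plus the Simpson index with
#' its variance.
#'
#' @param dataset a [pellet_dataset()] or [availability_dataset()].
#' @param group_by covariate names to group by; empty pools everything.
#' @param q_grid diversity orders; default the integral orders -1..3.
#' @return data.frame with the group covariates, `q` and `hill`; attribute
#'   `"groups"` holds per-group `n_items`, `richness`, `simpson_lambda`,
#'   `simpson_diversity`, `simpson_variance`. Groups with zero pooled counts
#'   are skipped with a warning.
#' @export
diversity_profile <- function(dataset, group_by = character(),
                              q_grid = -1:3) {
  stopifnot(inherits(dataset, c("pellet_dataset", "availability_dataset")))
  g <- group_factor(dataset$info, group_by)
  idx <- split(seq_len(nrow(dataset$info)), g)
  pooled <- lapply(idx, function(i) colSums(dataset$counts[i, , drop = FALSE]))
  keep <- vapply(pooled, sum, numeric(1)) > 0
  if (!all(keep)) {
    warning("skipping group(s) with zero counts: ",
            paste(names(idx)[!keep], collapse = ", "))
  }
  pooled <- pooled[keep]
  rows <- lapply(names(pooled), function(lv) {
    data.frame(group = lv, q = q_grid,
               hill = hill_number(pooled[[lv]], q_grid),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  gsum <- do.call(rbind, lapply(names(pooled), function(lv) {
    sv <- simpson_with_variance(pooled[[lv]])
    data.frame(group = lv, n_items = sv$n_items,
               richness = sum(pooled[[lv]] > 0),
               simpson_lambda = sv$lambda, simpson_diversity = sv$diversity,
               simpson_variance = sv$variance, stringsAsFactors = FALSE)
  }))
  res <- cbind(group_key_frame(out$group, group_by),
               out[setdiff(names(out), "group")])
  attr(res, "groups") <- cbind(group_key_frame(gsum$group, group_by),
                               gsum[setdiff(names(gsum), "group")])
  attr(res, "group_by") <- group_by
  class(res) <- c("diversity_profile", "data.frame")
  res
}

#' Bootstrap Tukey-like contrasts of Hill diversities
#'
#' All-pairs comparison of group diversities at each order in `q_set`. The
#' resampling unit is the pellet: within each group, pellets are resampled
#' with replacement `B` times, counts are pooled per replicate, and Hill
#' numbers recomputed. For a pair (a, b) the two-tailed p-value is the
#' bootstrap tail probability of the centred difference,
#' p = (#\{|d* - d| >= |d|\} + 1) / (B + 1), with d the observed difference
#' of pooled-count Hill numbers. Across pairs (within each q) a single-step
#' max-modulus adjustment is applied: the adjusted p uses the bootstrap
#' distribution of the maximum |centred difference| over all pairs, so
#' adjusted p >= raw p by construction. Holm adjustment of the raw p-values
#' is available as an alternative.
#'
#' @param dataset a [pellet_dataset()] (or availability dataset; resampling
#'   unit is then the sample).
#' @param group_by covariate names defining the groups (>= 2 groups, each
#'   with >= 2 pellets).
#' @param q_set diversity orders to test; default `c(0, 1, 2)`.
#' @param B bootstrap replications (default 5000).
#' @param seed integer seed (mandatory for reproducibility; recorded in the
#'   output).
#' @param adjust `"maxmod"` (default), `"holm"` or `"none"`.
#' @return data.frame with `group_a`, `group_b`, `q`, `diff` (observed
#'   difference a - b), `p_raw`, `p_adj`, `B`, `seed`.
#' @export
bootstrap_hill_contrasts <- function(dataset, group_by = character(),
                                     q_set = c(0, 1, 2), B = 5000,
                                     seed = NULL,
                                     adjust = c("maxmod", "holm", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(dataset, c("pellet_dataset", "availability_dataset")))
  g <- group_factor(dataset$info, group_by)
  idx <- split(seq_len(nrow(dataset$info)), g)
  if (length(idx) < 2L) stop("need at least 2 groups")
  small <- vapply(idx, length, integer(1)) < 2L
  if (any(small)) {
    stop("group(s) with fewer than 2 pellets cannot be resampled: ",
         paste(names(idx)[small], collapse = ", "))
  }
  X <- lapply(idx, function(i) dataset$counts[i, , drop = FALSE])
  obs <- vapply(X, function(m) hill_number(colSums(m), q_set),
                numeric(length(q_set)))
  obs <- matrix(obs, nrow = length(q_set))  # q x group

  boot <- with_seed(seed, {
    lapply(X, function(m) {
      n <- nrow(m)
      f <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
      W <- vapply(seq_len(B), function(b) tabulate(f[, b], nbins = n),
                  numeric(n))
      pooled <- crossprod(m, W)  # taxa x B
      hill_cols(pooled, q_set)   # q x B
    })
  })

  groups <- names(idx)
  pairs <- utils::combn(seq_along(groups), 2L)
  nq <- length(q_set)
  # centred bootstrap differences: q x B per pair
  cent <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    (boot[[a]] - boot[[b]]) - (obs[, a] - obs[, b])
  })
  res <- list()
  for (k in seq_len(nq)) {
    d_obs <- obs[k, pairs[1L, ]] - obs[k, pairs[2L, ]]
    t_abs <- vapply(cent, function(m) abs(m[k, ]), numeric(B))  # B x pairs
    p_raw <- (colSums(t_abs >= rep(abs(d_obs), each = B)) + 1) / (B + 1)
    p_adj <- switch(adjust,
      maxmod = {
        M <- apply(t_abs, 1L, max)
        (vapply(abs(d_obs), function(d) sum(M >= d), numeric(1)) + 1) / (B + 1)
      },
      holm = stats::p.adjust(p_raw, "holm"),
      none = p_raw
    )
    res[[k]] <- data.frame(group_a = groups[pairs[1L, ]],
                           group_b = groups[pairs[2L, ]],
                           q = q_set[k], diff = d_obs, p_raw = p_raw,
                           p_adj = pmax(p_adj, p_raw), B = B,
                           seed = if (is.null(seed)) NA_integer_ else seed,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("diversity_contrasts", "data.frame")
  out
}
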