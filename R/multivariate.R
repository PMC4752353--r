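# Permutational MANOVA on distance matrices (McArdle-Anderson partitioning
# of the Gower-centred inner-product matrix, sequential terms, free
# permutation of observations) and a Levene-type test of multivariate
# dispersion homogeneity in principal-coordinate space.

#' Ecological distance matrix from a count table
#'
#' Computes a pellets x pellets distance matrix from per-pellet counts.
#' Bray-Curtis (the default throughout the package:
#' d_ij = sum|x_i - x_j| / sum(x_i + x_j)), Jaccard or Euclidean, delegated
#' to [vegan::vegdist()]. Rows with zero totals are rejected: an empty
#' pellet has no composition and must be excluded before distance
#' computation.
#'
#' @param x count matrix (rows = pellets) or a [pellet_dataset()].
#' @param method `"bray"`, `"jaccard"` or `"euclidean"`.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
diet_distance <- function(x, method = c("bray", "jaccard", "euclidean")) {
  method <- match.arg(method)
  if (inherits(x, "pellet_dataset")) x <- x$counts
  x <- as.matrix(x)
  if (method != "euclidean" && any(rowSums(x) == 0)) {
    stop("zero-total row(s) ",
         paste(which(rowSums(x) == 0), collapse = ", "),
         ": exclude empty pellets before computing distances")
  }
  as.matrix(vegan::vegdist(x, method = method))
}

#' Bray-Curtis distance matrix
#'
#' Shorthand for `diet_distance(x, "bray")`.
#' @inheritParams diet_distance
#' @export
bray_curtis_matrix <- function(x) diet_distance(x, "bray")

# All permutations of 1..n as a list (used for exhaustive small-sample
# permutation tests).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (s in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

# Gower-centred inner-product matrix of a distance matrix.
gower_matrix <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Sequential orthogonal projectors for the terms of a model formula.
# Returns list(P = per-term projector matrices, df = per-term df,
# R = residual projector, df_res, labels).
design_projectors <- function(formula, data, as_factors = TRUE) {
  rhs <- stats::as.formula(paste("~", paste(deparse(formula[[length(formula)]]),
                                            collapse = "")))
  tt <- stats::terms(rhs, data = data)
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0L) stop("model formula has no terms")
  vars <- all.vars(rhs)
  data <- data[vars]
  if (as_factors) {
    for (v in vars) if (!is.numeric(data[[v]]) || length(unique(data[[v]])) < nrow(data)) {
      data[[v]] <- factor(data[[v]])
    }
  }
  n <- nrow(data)
  X <- matrix(1, n, 1)
  qr_prev <- qr(X)
  rank_prev <- 1L
  Q_prev <- qr.Q(qr_prev)[, 1L, drop = FALSE]
  H_prev <- tcrossprod(Q_prev)
  P <- list(); df <- integer(0)
  for (k in seq_along(labels)) {
    f_k <- stats::as.formula(paste("~", paste(labels[seq_len(k)], collapse = "+")))
    Xk <- stats::model.matrix(f_k, data)
    qk <- qr(Xk)
    if (qk$rank <= rank_prev) {
      stop("aliased (singular) term in design: ", labels[k])
    }
    Qk <- qr.Q(qk)[, seq_len(qk$rank), drop = FALSE]
    Hk <- tcrossprod(Qk)
    P[[k]] <- Hk - H_prev
    df[k] <- qk$rank - rank_prev
    H_prev <- Hk
    rank_prev <- qk$rank
  }
  list(P = P, df = df, R = diag(n) - H_prev, df_res = n - rank_prev,
       labels = labels)
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared interpoint distances by a (possibly
#' crossed) factorial design, using sequential (Type I, model-order) sums of
#' squares from the Gower-centred inner-product matrix, and tests each
#' term's pseudo-F against the residual by free permutation of observation
#' labels: p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1).
#'
#' With univariate responses and Euclidean distances the pseudo-F of a
#' one-factor model equals the classical one-way ANOVA F.
#'
#' @param d distance matrix (or `dist`).
#' @param formula right-hand-side model formula over columns of `data`,
#'   e.g. `~ year * month * area`; terms are fitted sequentially in formula
#'   order.
#' @param data data.frame of covariates, rows aligned with `d`. Character
#'   and discrete variables are coerced to factors.
#' @param n_perm number of permutations (default 999). When the complete
#'   permutation group is no larger than `n_perm` (n! <= n_perm), all
#'   permutations are enumerated instead of sampled and the p-value is exact:
#'   p = #\{F_perm >= F_obs\} / n!.
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova` : list with `aov_tab` (term, df, SS,
#'   pseudo-F, R2, p_perm), `total_ss`, `n_perm`, `exhaustive`, `seed`.
#' @export
permanova <- function(d, formula, data, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (nrow(data) != n) stop("design rows must align with the distance matrix")
  G <- gower_matrix(D)
  total_ss <- sum(diag(G))
  if (total_ss <= .Machine$double.eps * n) {
    stop("total sum of squares is zero: all observations are identical")
  }
  dp <- design_projectors(formula, data)
  if (dp$df_res <= 0L) stop("no residual degrees of freedom")
  ss <- vapply(dp$P, function(P) sum(P * G), numeric(1))
  ss_res <- sum(dp$R * G)
  f_obs <- (ss / dp$df) / (ss_res / dp$df_res)

  perm_f <- function(perm) {
    Gp <- G[perm, perm]
    ssp <- vapply(dp$P, function(P) sum(P * Gp), numeric(1))
    (ssp / dp$df) / (sum(dp$R * Gp) / dp$df_res)
  }
  # ties at F_obs (e.g. within-group relabellings) must count as exceedances
  # despite floating-point reordering noise
  f_lo <- f_obs - pmax(1e-12, abs(f_obs) * 1e-10)
  exhaustive <- n <= 10 && factorial(n) <= n_perm
  exceed <- numeric(length(ss))
  if (exhaustive) {
    perms <- all_permutations(n)
    for (perm in perms) exceed <- exceed + (perm_f(perm) >= f_lo)
    p <- exceed / length(perms)
  } else {
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        exceed <- exceed + (perm_f(sample.int(n)) >= f_lo)
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  }
  aov_tab <- data.frame(term = c(dp$labels, "Residual"),
                        df = c(dp$df, dp$df_res),
                        ss = c(ss, ss_res),
                        pseudo_F = c(f_obs, NA_real_),
                        R2 = c(ss, ss_res) / total_ss,
                        p_perm = c(p, NA_real_),
                        stringsAsFactors = FALSE)
  structure(list(aov_tab = aov_tab, total_ss = total_ss, n_perm = n_perm,
                 exhaustive = exhaustive, seed = seed), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational multivariate analysis of variance\n")
  cat("sequential (Type I) SS,", x$n_perm, "free permutations\n\n")
  print(x$aov_tab, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Multivariate homogeneity of group dispersions
#'
#' A multivariate analogue of Levene's test: embeds the distance matrix by
#' principal-coordinate analysis (retaining negative eigenvalues with their
#' sign), computes each observation's distance to its own group centroid
#' with the negative-axis correction (squared distance = real-part
#' contribution minus imaginary-part contribution, floored at 0), and tests
#' equality of group mean distances with a one-way F whose null distribution
#' comes from permuting group labels.
#'
#' @param d distance matrix (or `dist`).
#' @param groups grouping vector (>= 2 groups of >= 2 observations).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return object of class `dispersion_test`: list with `distances`
#'   (per-observation distance to own centroid), `group_stats` (mean and sd
#'   per group), `F`, `df`, `p_perm`, `n_perm`, `seed`.
#' @export
dispersion_test <- function(d, groups, n_perm = 999, seed = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  groups <- factor(groups)
  if (length(groups) != n) stop("groups must align with the distance matrix")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop("group(s) of size 1: ",
         paste(names(which(table(groups) < 2L)), collapse = ", "))
  }
  G <- gower_matrix(D)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  neg <- eig$values < -tol
  Vp <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]),
                                                  sum(pos))
  Vn <- eig$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eig$values[neg]),
                                                  sum(neg))
  dist_to_centroid <- numeric(n)
  for (lv in levels(groups)) {
    i <- which(groups == lv)
    cp <- colMeans(Vp[i, , drop = FALSE])
    cn <- if (ncol(Vn) > 0) colMeans(Vn[i, , drop = FALSE]) else numeric(0)
    sq <- rowSums(sweep(Vp[i, , drop = FALSE], 2L, cp)^2)
    if (ncol(Vn) > 0) {
      sq <- sq - rowSums(sweep(Vn[i, , drop = FALSE], 2L, cn)^2)
    }
    dist_to_centroid[i] <- sqrt(pmax(sq, 0))
  }
  f_stat <- function(z, g) {
    m <- tapply(z, g, mean)
    nk <- tabulate(g)
    ssb <- sum(nk * (m - mean(z))^2)
    ssw <- sum((z - m[g])^2)
    (ssb / (nlevels(g) - 1)) / (ssw / (length(z) - nlevels(g)))
  }
  F_obs <- f_stat(dist_to_centroid, groups)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      if (f_stat(dist_to_centroid[sample.int(n)], groups) >= F_obs) {
        exceed <- exceed + 1L
      }
    }
  })
  gs <- data.frame(group = levels(groups),
                   n = as.integer(table(groups)),
                   mean_dist = as.numeric(tapply(dist_to_centroid, groups, mean)),
                   sd_dist = as.numeric(tapply(dist_to_centroid, groups, stats::sd)),
                   stringsAsFactors = FALSE)
  structure(list(distances = dist_to_centroid, group_stats = gs, F = F_obs,
                 df = c(nlevels(groups) - 1L, n - nlevels(groups)),
                 p_perm = (exceed + 1) / (n_perm + 1), n_perm = n_perm,
                 seed = seed),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate homogeneity of group dispersions\n")
  print(x$group_stats, row.names = FALSE, digits = 4)
  cat(sprintf("\nF = %.4f on %d and %d df, permutation p = %.4g (%d perms)\n",
              x$F, x$df[1], x$df[2], x$p_perm, x$n_perm))
  invisible(x)
}
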