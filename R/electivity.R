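# Electivity: prey preference/avoidance given environmental availability.
# Two indices, both mapping to [-1, +1]: the Ivlev selectivity index as
# modified by Jacobs (D) and the Vanderploeg-Scavia electivity index (E*),
# the latter preferred at small sample sizes.

#' Ivlev-Jacobs selectivity index
#'
#' D = (r - p) / (r + p - 2 r p), where r is the proportion of a prey type
#' in the diet and p its proportion in the environment. D ranges from -1
#' (total avoidance) through 0 (random selection) to +1 (maximum positive
#' selection) and is antisymmetric under swapping r and p.
#'
#' @param r,p proportions in \[0,1\] (vectorised).
#' @return D in \[-1,1\]; `NaN` where r = p = 0 (undefined: the taxon occurs
#'   in neither diet nor environment).
#' @export
#' @examples
#' jacobs_D(0.5, 0.25)  # 0.5
#' jacobs_D(0, 0.4)     # -1 (total avoidance)
jacobs_D <- function(r, p) {
  stopifnot(all(r >= 0 & r <= 1, na.rm = TRUE),
            all(p >= 0 & p <= 1, na.rm = TRUE))
  num <- r - p
  den <- r + p - 2 * r * p
  out <- ifelse(den == 0 & num == 0, NaN, num / den)
  out
}

#' Vanderploeg-Scavia selectivity coefficient and electivity index
#'
#' W_i = (r_i / p_i) / sum_i (r_i / p_i) and
#' E*_i = (W_i - 1/n) / (W_i + 1/n), with n the number of available prey
#' types. Taxa present in the diet but absent from the availability sample
#' (p_i = 0, r_i > 0) take E*_i = +1 by limit and are excluded from the
#' normalisation of the finite W (which then still sum to 1); taxa absent
#' from both are undefined (`NaN`).
#'
#' @param r_vec,p_vec proportion vectors of equal length n >= 2. They are
#'   renormalised to sum to 1 internally, so E* is invariant to rescaling
#'   either vector by a positive constant.
#' @param n number of available prey types used in E*; defaults to
#'   `length(p_vec)`.
#' @return list with components `W` and `E_star`.
#' @export
#' @examples
#' vanderploeg_scavia(c(0.8, 0.2), c(0.5, 0.5))
vanderploeg_scavia <- function(r_vec, p_vec, n = length(p_vec)) {
  stopifnot(length(r_vec) == length(p_vec), length(p_vec) >= 2L)
  if (all(p_vec == 0)) stop("all availability proportions are zero")
  if (any(r_vec < 0) || any(p_vec < 0)) stop("proportions must be non-negative")
  r <- r_vec / sum(r_vec)
  p <- p_vec / sum(p_vec)
  ratio <- ifelse(p > 0, r / p, ifelse(r > 0, Inf, NaN))
  finite <- is.finite(ratio)
  W <- ratio
  W[finite] <- ratio[finite] / sum(ratio[finite])
  E <- (W - 1 / n) / (W + 1 / n)
  E[is.infinite(ratio)] <- 1
  E[is.nan(ratio)] <- NaN
  W[is.infinite(ratio)] <- Inf
  list(W = W, E_star = E)
}

#' Electivity profile: join diet to availability
#'
#' Renormalises diet and availability proportions over a shared taxon
#' universe and computes, per taxon: r, p, the selectivity coefficient W,
#' the Ivlev-Jacobs D and the Vanderploeg-Scavia E*, plus a degeneracy flag.
#' Degenerate taxa are flagged, never silently dropped: availability
#' censuses only see epigeal and flying prey, so diet taxa missing from the
#' availability sample are an expected, ecologically meaningful case.
#'
#' @param diet named numeric vector of diet composition (counts or
#'   percentages; renormalised), or a `diet_summary` with a single group
#'   (its `pct_numeric` is used).
#' @param availability named numeric vector of availability composition
#'   (pooled counts), or an [availability_dataset()] (counts pooled over all
#'   samples; set `pool = FALSE` to average per-sample proportions instead).
#' @param universe `"union"` (default: all taxa seen in either table) or
#'   `"availability_taxa"` (restrict to taxa in the availability sample).
#' @param pool when `availability` is a dataset: pool counts across samples
#'   (default) or average per-sample proportions.
#' @return an `electivity_table` data.frame: `taxon`, `r`, `p`, `W`, `D`,
#'   `E_star`, `flag` (one of `ok`, `absent_in_both`,
#'   `absent_in_availability`, `absent_in_diet`); attribute `n_types` gives
#'   the n used in E*.
#' @export
electivity_profile <- function(diet, availability,
                               universe = c("union", "availability_taxa"),
                               pool = TRUE) {
  universe <- match.arg(universe)
  if (inherits(diet, "diet_summary")) {
    if (length(unique(interaction(diet[attr(diet, "group_by")], drop = TRUE))) > 1L &&
        length(attr(diet, "group_by")) > 0L) {
      stop("diet summary has multiple groups; subset to one group first")
    }
    diet <- stats::setNames(diet$pct_numeric, diet$taxon)
  }
  if (inherits(availability, "availability_dataset")) {
    availability <- if (pool) {
      colSums(availability$counts)
    } else {
      props <- sweep(availability$counts, 1L, rowSums(availability$counts), "/")
      colMeans(props, na.rm = TRUE)
    }
  }
  diet <- diet[!is.na(diet)]
  if (is.null(names(diet)) || is.null(names(availability))) {
    stop("diet and availability must be named by taxon")
  }
  taxa <- switch(universe,
                 union = union(names(diet), names(availability)),
                 availability_taxa = names(availability))
  if (length(intersect(names(diet), names(availability))) == 0L) {
    stop("diet and availability share no taxa")
  }
  rd <- stats::setNames(rep(0, length(taxa)), taxa)
  pd <- rd
  rd[intersect(taxa, names(diet))] <- diet[intersect(taxa, names(diet))]
  pd[intersect(taxa, names(availability))] <-
    availability[intersect(taxa, names(availability))]
  if (sum(rd) <= 0) stop("diet composition sums to zero over the universe")
  if (sum(pd) <= 0) stop("availability sums to zero over the universe")
  r <- rd / sum(rd)
  p <- pd / sum(pd)
  n <- length(taxa)
  vs <- vanderploeg_scavia(r, p, n = n)
  D <- jacobs_D(r, p)
  flag <- ifelse(r == 0 & p == 0, "absent_in_both",
                 ifelse(p == 0, "absent_in_availability",
                        ifelse(r == 0, "absent_in_diet", "ok")))
  out <- data.frame(taxon = taxa, r = unname(r), p = unname(p),
                    W = unname(vs$W), D = unname(D),
                    E_star = unname(vs$E_star), flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_types") <- n
  attr(out, "universe") <- universe
  class(out) <- c("electivity_table", "data.frame")
  out
}

#' Write an electivity table to CSV
#' @param x an `electivity_table`.
#' @param path output CSV path.
#' @export
write_electivity_table <- function(x, path) {
  write_delim_file(as.data.frame(x), path, infer_sep(path))
  invisible(path)
}
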