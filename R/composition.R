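# Diet composition: the four standard representations of a pellet diet
# (%n numeric frequency, %p presence, %vol volumetric, %b dry biomass) and
# the per-prey volume and dry-mass estimators underneath them.

#' Geometric prey volume
#'
#' Volume of one prey item under its taxon's shape model, in cm^3:
#' prolate spheroid V = (4/3) * pi * (L/2) * (W/2)^2, cylinder
#' V = pi * (W/2)^2 * L (both with L, W in mm, converted mm^3 -> cm^3), or
#' the taxon's fixed displacement volume measured in alcohol.
#'
#' @param taxon one row of a [trait_table()] (data.frame or list).
#' @param length,width item dimensions in mm; default to the taxon's mean
#'   dimensions.
#' @return volume in cm^3.
#' @export
#' @examples
#' tt <- trait_table(data.frame(name = "Coleoptera",
#'                              shape_model = "prolate_spheroid",
#'                              mean_length_mm = 10, mean_width_mm = 4))
#' prey_volume(tt[1, ])  # 0.083776 cm^3
prey_volume <- function(taxon, length = NULL, width = NULL) {
  shape <- as.character(taxon$shape_model)
  if (shape == "fixed_displacement") {
    v <- taxon$fixed_volume_cm3
    if (is.null(v) || is.na(v)) stop("no fixed volume for taxon ", taxon$name)
    return(as.numeric(v))
  }
  L <- if (!is.null(length) && !is.na(length)) length else taxon$mean_length_mm
  W <- if (!is.null(width) && !is.na(width)) width else taxon$mean_width_mm
  if (is.null(L) || is.null(W) || is.na(L) || is.na(W)) {
    stop("missing length/width for taxon ", taxon$name)
  }
  mm3 <- switch(shape,
    prolate_spheroid = (4 / 3) * pi * (L / 2) * (W / 2)^2,
    cylinder = pi * (W / 2)^2 * L,
    stop("unknown shape model: ", shape)
  )
  mm3 / 1000
}

#' Cohort mean dry masses
#'
#' Assembles the fallback mass table used by [prey_dry_mass()]: the
#' per-taxon mean dry masses from a trait table and their overall mean
#' (the fallback for unidentifiable remains).
#'
#' @param traits a [trait_table()].
#' @return list with `group` (named numeric, mg) and `overall` (numeric, mg).
#' @export
cohort_means <- function(traits) {
  g <- stats::setNames(traits$group_mean_mass_mg, traits$name)
  list(group = g, overall = mean(g, na.rm = TRUE))
}

#' Estimated dry mass of one prey item
#'
#' Three-tier estimation hierarchy, in strict precedence:
#' 1. measured length and an allometric regression for the taxon:
#'    m = a * L^b (mg, L in mm);
#' 2. taxon identified but unmeasured (or no regression): the taxon's mean
#'    recorded dry mass;
#' 3. unidentifiable remains: the overall mean dry mass across all groups.
#'
#' @param taxon one row of a [trait_table()], or `NULL` for unidentified
#'   remains.
#' @param length item length in mm, or `NA`/`NULL` if unmeasured.
#' @param means fallback masses, as produced by [cohort_means()].
#' @return dry mass in mg (positive).
#' @export
prey_dry_mass <- function(taxon = NULL, length = NULL, means) {
  if (!is.null(taxon) && !is.null(length) && length(length) == 1L &&
      !is.na(length) && !is.na(taxon$mass_a) && !is.na(taxon$mass_b)) {
    return(as.numeric(taxon$mass_a) * length^as.numeric(taxon$mass_b))
  }
  if (!is.null(taxon)) {
    gm <- means$group[[as.character(taxon$name)]]
    if (!is.null(gm) && !is.na(gm)) return(as.numeric(gm))
  }
  if (!is.null(means$overall) && is.finite(means$overall)) {
    return(means$overall)
  }
  stop("cannot estimate dry mass: no regression and no mean masses available",
       if (!is.null(taxon)) paste0(" (taxon ", taxon$name, ")"))
}

# Shared grouping machinery: split a pellet dataset into groups and return
# per-group pooled counts, presence counts and bookkeeping.
group_pellets <- function(dataset, group_by) {
  stopifnot(inherits(dataset, "pellet_dataset"))
  if (nrow(dataset$info) == 0L) stop("empty dataset")
  g <- group_factor(dataset$info, group_by)
  idx <- split(seq_len(nrow(dataset$info)), g)
  list(levels = names(idx), index = idx, factor = g)
}

#' Diet composition by numeric frequency and presence
#'
#' Per group of pellets: %n_i = 100 * (total count of taxon i) / (total prey
#' items), and %p_i = 100 * (number of pellets containing taxon i) /
#' (number of pellets). Groups with zero prey items get `NA` %n and are
#' flagged with a warning.
#'
#' @param dataset a [pellet_dataset()].
#' @param group_by character vector of covariate column names (subset of the
#'   `info` columns, e.g. `c("year", "month", "area")`); empty pools all
#'   pellets into one group.
#' @return a `diet_summary` data.frame: one row per group x taxon with the
#'   group covariates, `taxon`, `count`, `n_pellets`, `pct_numeric` and
#'   `pct_presence`; attribute `"groups"` holds the per-group summary
#'   (`n_pellets`, `n_items`, `plant_presence_pct`).
#' @export
#' @examples
#' ds <- pellet_dataset(
#'   data.frame(pellet_id = c("a", "b"), year = 2009, month = 5,
#'              area = "High", plant_fraction = 0.1),
#'   matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'          dimnames = list(NULL, c("ants", "beetles"))))
#' diet_frequencies(ds)
diet_frequencies <- function(dataset, group_by = character()) {
  gp <- group_pellets(dataset, group_by)
  taxa <- colnames(dataset$counts)
  rows <- lapply(seq_along(gp$index), function(k) {
    i <- gp$index[[k]]
    cnt <- dataset$counts[i, , drop = FALSE]
    tot <- sum(cnt)
    if (tot == 0) {
      warning("group '", gp$levels[k], "' has zero prey items; %n undefined")
    }
    pooled <- colSums(cnt)
    data.frame(group = gp$levels[k], taxon = taxa, count = as.integer(pooled),
               n_pellets = length(i),
               pct_numeric = if (tot > 0) 100 * pooled / tot else NA_real_,
               pct_presence = 100 * colSums(cnt > 0) / length(i),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  groups <- data.frame(
    group = gp$levels,
    n_pellets = vapply(gp$index, length, integer(1)),
    n_items = vapply(gp$index, function(i) sum(dataset$counts[i, , drop = FALSE]),
                     numeric(1)),
    plant_presence_pct = vapply(gp$index, function(i) {
      100 * mean(dataset$info$plant_fraction[i] > 0)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- cbind(group_key_frame(out$group, group_by),
               out[setdiff(names(out), "group")])
  attr(out, "groups") <- cbind(group_key_frame(groups$group, group_by),
                               groups[setdiff(names(groups), "group")])
  attr(out, "group_by") <- group_by
  class(out) <- c("diet_summary", "data.frame")
  out
}

# Mean volume per taxon (cm^3) resolved from the trait table; errors name
# the first unresolvable counted taxon.
taxon_mean_volumes <- function(taxa, traits) {
  vapply(taxa, function(tx) {
    row <- traits[traits$name == tx, , drop = FALSE]
    if (nrow(row) == 0L) stop("no trait entry for counted taxon ", tx)
    tryCatch(prey_volume(row[1, ]),
             error = function(e) stop("cannot resolve volume for taxon ", tx,
                                      ": ", conditionMessage(e), call. = FALSE))
  }, numeric(1))
}

#' Diet composition by volume
#'
#' Applies taxon mean volumes (from [prey_volume()] on the trait table's mean
#' dimensions, or the fixed displacement volume) to the pooled count table:
#' %vol_i = 100 * count_i * V_i / sum_j count_j * V_j. Per-item measured
#' volumes are deliberately not used in this pathway: mean volumes applied to
#' frequency tables is the standard estimator this mirrors.
#'
#' @inheritParams diet_frequencies
#' @param traits a [trait_table()] covering every counted taxon.
#' @return a `diet_summary` data.frame as [diet_frequencies()], with an
#'   additional `pct_volume` column and a `volume_overestimate` flag column
#'   (carried from the trait table, marking taxa whose volume model is known
#'   to overestimate the ingested volume, e.g. snail shells).
#' @export
diet_volume_profile <- function(dataset, traits, group_by = character()) {
  out <- diet_frequencies(dataset, group_by)
  all_taxa <- colnames(dataset$counts)
  counted <- all_taxa[colSums(dataset$counts) > 0]
  vols <- stats::setNames(rep(NA_real_, length(all_taxa)), all_taxa)
  vols[counted] <- taxon_mean_volumes(counted, traits = traits)
  over <- stats::setNames(traits$volume_overestimate, traits$name)
  wt <- ifelse(out$count > 0, out$count * vols[out$taxon], 0)
  key <- do.call(paste, c(out[intersect(names(out),
                                        c(attr(out, "group_by"), "group"))],
                          sep = "\r"))
  denom <- stats::ave(wt, key, FUN = sum)
  out$pct_volume <- ifelse(denom > 0, 100 * wt / denom, NA_real_)
  out$volume_overestimate <- unname(over[out$taxon]) %in% TRUE
  out
}

#' Diet composition by dry biomass
#'
#' %b_i = 100 * (summed estimated dry mass of items of taxon i) / (total
#' estimated dry mass), with per-item masses from the [prey_dry_mass()]
#' hierarchy: measured items use the taxon's allometric regression where one
#' exists, unmeasured items fall back to the taxon mean mass, and taxa with
#' no mean fall back to the overall mean.
#'
#' @inheritParams diet_volume_profile
#' @return a `diet_summary` data.frame with an additional `pct_biomass`
#'   column.
#' @export
diet_biomass_profile <- function(dataset, traits, group_by = character()) {
  out <- diet_frequencies(dataset, group_by)
  means <- cohort_means(traits)
  taxa <- colnames(dataset$counts)
  trows <- lapply(stats::setNames(taxa, taxa), function(tx) {
    r <- traits[traits$name == tx, , drop = FALSE]
    if (nrow(r) > 0L) r[1, ] else NULL
  })
  fallback <- vapply(taxa, function(tx) {
    prey_dry_mass(trows[[tx]], length = NA, means = means)
  }, numeric(1))

  gp <- group_pellets(dataset, group_by)
  meas <- dataset$measurements
  mass_tab <- lapply(seq_along(gp$index), function(k) {
    i <- gp$index[[k]]
    cnt <- colSums(dataset$counts[i, , drop = FALSE])
    mass <- cnt * fallback
    if (!is.null(meas)) {
      pm <- meas[meas$pellet_id %in% dataset$info$pellet_id[i] &
                   meas$taxon %in% taxa, , drop = FALSE]
      if (nrow(pm) > 0L) {
        for (tx in unique(pm$taxon)) {
          lens <- pm$length_mm[pm$taxon == tx]
          lens <- lens[!is.na(lens)]
          n_meas <- min(length(lens), cnt[[tx]])
          if (n_meas > 0L) {
            m_meas <- vapply(lens[seq_len(n_meas)], function(L) {
              prey_dry_mass(trows[[tx]], length = L, means = means)
            }, numeric(1))
            mass[[tx]] <- sum(m_meas) + (cnt[[tx]] - n_meas) * fallback[[tx]]
          }
        }
      }
    }
    mass
  })
  mass_flat <- unlist(mass_tab)
  stopifnot(length(mass_flat) == nrow(out))
  key <- rep(gp$levels, each = length(taxa))
  denom <- stats::ave(mass_flat, key, FUN = sum)
  out$pct_biomass <- ifelse(denom > 0, 100 * mass_flat / denom, NA_real_)
  out
}

#' Full diet summary
#'
#' Convenience wrapper computing %n, %p, %vol and %b in one table.
#'
#' @inheritParams diet_volume_profile
#' @return a `diet_summary` data.frame with `pct_numeric`, `pct_presence`,
#'   `pct_volume`, `pct_biomass` columns.
#' @export
diet_summary <- function(dataset, traits, group_by = character()) {
  vol <- diet_volume_profile(dataset, traits, group_by)
  bio <- diet_biomass_profile(dataset, traits, group_by)
  vol$pct_biomass <- bio$pct_biomass
  vol
}

#' Write a diet summary to CSV
#'
#' One row per (group, taxon) with whichever composition columns are present.
#'
#' @param summary a `diet_summary` data.frame.
#' @param path output CSV path.
#' @export
write_diet_summary <- function(summary, path) {
  write_delim_file(as.data.frame(summary), path, infer_sep(path))
  invisible(path)
}
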