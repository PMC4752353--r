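# Shared data model: pellet datasets, availability datasets, prey trait
# tables, and the validation report that ties them together.

#' Default study-area labels
#'
#' The five named sampling areas of the original island study. The label set
#' is configurable everywhere it is used; these are only defaults.
#' @export
AIRE_AREAS <- c("High", "Low", "North", "West", "Jetty")

RESERVED_PELLET_COLS <- c("pellet_id", "year", "month", "area", "plant_fraction")
RESERVED_AVAIL_COLS <- c("sample_id", "year", "month", "area")
SHAPE_MODELS <- c("prolate_spheroid", "cylinder", "fixed_displacement")

#' Construct a pellet dataset
#'
#' A pellet dataset couples per-pellet covariates (year, month, area, visually
#' estimated plant fraction) with an integer prey-count matrix (pellets x
#' taxa) and, optionally, per-item length/width measurements.
#'
#' Structural invariants (unique ids, aligned dimensions, non-negative
#' integer counts) are enforced here; range checks that depend on context
#' (month in 1-12, plant fraction in \[0,1\], trait coverage) are reported by
#' [validate_dataset()].
#'
#' @param info data.frame with columns `pellet_id`, `year`, `month`, `area`,
#'   `plant_fraction` (one row per pellet).
#' @param counts numeric matrix of non-negative integer prey counts, one row
#'   per pellet, one column per taxon (column names are the taxon list).
#' @param taxa character vector of taxon names; defaults to
#'   `colnames(counts)`.
#' @param measurements optional data.frame of per-item measurements with
#'   columns `pellet_id`, `taxon`, `length_mm`, `width_mm` (width may be NA).
#' @return an object of class `pellet_dataset`: a list with elements `info`,
#'   `counts`, `taxa`, `measurements`.
#' @export
#' @examples
#' info <- data.frame(pellet_id = c("p1", "p2"), year = 2009, month = 5,
#'                    area = "High", plant_fraction = c(0, 0.2))
#' counts <- matrix(c(3L, 0L, 1L, 2L), 2, 2,
#'                  dimnames = list(NULL, c("Formicidae", "Coleoptera")))
#' pellet_dataset(info, counts)
pellet_dataset <- function(info, counts, taxa = colnames(counts),
                           measurements = NULL) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  need <- setdiff(RESERVED_PELLET_COLS, names(info))
  if (length(need) > 0L) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "))
  }
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts matrix must have taxon column names")
  if (nrow(counts) != nrow(info)) stop("counts rows must match info rows")
  check_count_matrix(counts, info$pellet_id, "pellet")
  storage.mode(counts) <- "integer"
  rownames(counts) <- info$pellet_id
  if (anyDuplicated(info$pellet_id)) {
    stop("duplicate pellet_id: ",
         paste(unique(info$pellet_id[duplicated(info$pellet_id)]), collapse = ", "))
  }
  if (!is.null(measurements)) {
    measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
    mneed <- setdiff(c("pellet_id", "taxon", "length_mm"), names(measurements))
    if (length(mneed) > 0L) {
      stop("measurements missing column(s): ", paste(mneed, collapse = ", "))
    }
    if (!"width_mm" %in% names(measurements)) measurements$width_mm <- NA_real_
  }
  structure(list(info = info, counts = counts, taxa = as.character(taxa),
                 measurements = measurements),
            class = "pellet_dataset")
}

#' Construct an availability dataset
#'
#' Availability samples are counts of potential prey censused per taxon on a
#' given date and area (e.g. with a biocenometer, a bottomless 1 m mesh cube
#' dropped over a plot to trap epigeal and flying invertebrates).
#'
#' @param info data.frame with columns `sample_id`, `year`, `month`, `area`.
#' @param counts non-negative integer matrix, samples x taxa.
#' @param taxa taxon list; defaults to `colnames(counts)`.
#' @return an object of class `availability_dataset`.
#' @export
availability_dataset <- function(info, counts, taxa = colnames(counts)) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  need <- setdiff(RESERVED_AVAIL_COLS, names(info))
  if (length(need) > 0L) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "))
  }
  counts <- as.matrix(counts)
  if (nrow(info) == 0L) stop("no samples")
  if (is.null(colnames(counts)) || ncol(counts) == 0L) {
    stop("availability table must have at least one taxon column")
  }
  if (nrow(counts) != nrow(info)) stop("counts rows must match info rows")
  check_count_matrix(counts, info$sample_id, "sample")
  storage.mode(counts) <- "integer"
  rownames(counts) <- info$sample_id
  if (anyDuplicated(info$sample_id)) stop("duplicate sample_id")
  structure(list(info = info, counts = counts, taxa = as.character(taxa)),
            class = "availability_dataset")
}

check_count_matrix <- function(counts, ids, what) {
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) {
    bad <- ids[apply(is.na(counts), 1L, any)]
    stop("missing count for ", what, " row(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts < 0)) {
    bad <- ids[apply(counts < 0, 1L, any)]
    stop("negative count for ", what, " row(s): ", paste(bad, collapse = ", "))
  }
  if (any(counts != round(counts))) {
    bad <- ids[apply(counts != round(counts), 1L, any)]
    stop("non-integer count for ", what, " row(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a prey trait table
#'
#' One row per taxon, carrying everything needed to turn counts into volumes
#' and dry masses: the geometric volume model (`prolate_spheroid`,
#' `cylinder`, or `fixed_displacement`), mean body length/width in mm, a
#' fixed displacement volume in cm^3 where applicable, optional allometric
#' dry-mass regression coefficients (m = a * L^b, mass in mg, length in mm),
#' a per-group mean dry mass fallback, and two annotation flags.
#'
#' @param df data.frame with columns `name`, `shape_model`, and optionally
#'   `mean_length_mm`, `mean_width_mm`, `fixed_volume_cm3`, `mass_a`,
#'   `mass_b`, `group_mean_mass_mg`, `is_vertebrate_or_carrion`,
#'   `volume_overestimate`.
#' @return object of class `trait_table` (a validated data.frame).
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- setdiff(c("name", "shape_model"), names(df))
  if (length(need) > 0L) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "))
  }
  opt <- c(mean_length_mm = NA_real_, mean_width_mm = NA_real_,
           fixed_volume_cm3 = NA_real_, mass_a = NA_real_, mass_b = NA_real_,
           group_mean_mass_mg = NA_real_)
  for (nm in names(opt)) if (!nm %in% names(df)) df[[nm]] <- opt[[nm]]
  if (!"is_vertebrate_or_carrion" %in% names(df)) df$is_vertebrate_or_carrion <- FALSE
  if (!"volume_overestimate" %in% names(df)) df$volume_overestimate <- FALSE
  if (anyDuplicated(df$name)) {
    stop("duplicate taxon name: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$shape_model), SHAPE_MODELS)
  if (length(bad) > 0L) stop("unknown shape_model: ", paste(bad, collapse = ", "))
  fd <- df$shape_model == "fixed_displacement"
  if (any(fd & (is.na(df$fixed_volume_cm3) | df$fixed_volume_cm3 <= 0))) {
    stop("fixed_displacement taxa need fixed_volume_cm3 > 0: ",
         paste(df$name[fd & (is.na(df$fixed_volume_cm3) | df$fixed_volume_cm3 <= 0)],
               collapse = ", "))
  }
  geo <- df$shape_model != "fixed_displacement"
  used <- geo & (!is.na(df$mean_length_mm) | !is.na(df$mean_width_mm))
  if (any(used & (df$mean_length_mm <= 0 | df$mean_width_mm <= 0), na.rm = TRUE)) {
    stop("mean dimensions must be positive where given")
  }
  if (any(!is.na(df$mass_a) & df$mass_a <= 0)) stop("mass_a must be positive")
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Validate a dataset against a trait table
#'
#' Pure check (never mutates its inputs) producing a structured report:
#' errors for months outside 1-12, plant fractions outside \[0,1\],
#' unknown area labels, and pellets that carry no dietary information at all
#' (zero prey items and zero plant fraction); warnings for counted taxa
#' missing from the trait table (frequency metrics remain possible, volume
#' and biomass do not).
#'
#' @param dataset a [pellet_dataset()] or [availability_dataset()].
#' @param traits optional [trait_table()] to check taxon coverage against.
#' @param areas allowed area labels; default [AIRE_AREAS]. `NULL` skips the
#'   area check.
#' @return object of class `validation_report`: list with `errors` and
#'   `warnings` data.frames (`record_id`, `message`) and logical `is_valid`
#'   (`TRUE` iff no errors).
#' @export
validate_dataset <- function(dataset, traits = NULL, areas = AIRE_AREAS) {
  stopifnot(inherits(dataset, c("pellet_dataset", "availability_dataset")))
  info <- dataset$info
  ids <- info[[if (inherits(dataset, "pellet_dataset")) "pellet_id" else "sample_id"]]
  errors <- list()
  warnings <- list()
  note <- function(store, id, msg) {
    store[[length(store) + 1L]] <- data.frame(record_id = id, message = msg,
                                              stringsAsFactors = FALSE)
    store
  }
  bad_month <- !is.na(info$month) & (info$month < 1 | info$month > 12 |
                                       info$month != round(info$month))
  for (i in which(bad_month)) {
    errors <- note(errors, ids[i], sprintf("month %s outside 1-12", info$month[i]))
  }
  if (!is.null(areas)) {
    for (i in which(!info$area %in% areas)) {
      warnings <- note(warnings, ids[i],
                       sprintf("area '%s' not in configured label set", info$area[i]))
    }
  }
  if (inherits(dataset, "pellet_dataset")) {
    pf <- info$plant_fraction
    for (i in which(is.na(pf) | pf < 0 | pf > 1)) {
      errors <- note(errors, ids[i], sprintf("plant_fraction %s outside [0,1]", pf[i]))
    }
    empty <- rowSums(dataset$counts) == 0 & (!is.na(pf) & pf == 0)
    for (i in which(empty)) {
      errors <- note(errors, ids[i],
                     "pellet has zero prey items and zero plant fraction")
    }
  }
  extra <- setdiff(colnames(dataset$counts), dataset$taxa)
  if (length(extra) > 0L) {
    errors <- note(errors, NA_character_,
                   paste("count taxa absent from taxon list:",
                         paste(extra, collapse = ", ")))
  }
  if (!is.null(traits)) {
    counted <- colnames(dataset$counts)[colSums(dataset$counts) > 0]
    unknown <- setdiff(counted, traits$name)
    if (length(unknown) > 0L) {
      warnings <- note(warnings, NA_character_,
                       paste("counted taxa absent from trait table",
                             "(volume/biomass unavailable):",
                             paste(unknown, collapse = ", ")))
    }
  }
  errors <- if (length(errors)) do.call(rbind, errors) else
    data.frame(record_id = character(), message = character())
  warnings <- if (length(warnings)) do.call(rbind, warnings) else
    data.frame(record_id = character(), message = character())
  structure(list(errors = errors, warnings = warnings,
                 is_valid = nrow(errors) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation report:", if (x$is_valid) "VALID" else "INVALID", "\n")
  cat(" errors:  ", nrow(x$errors), "\n")
  cat(" warnings:", nrow(x$warnings), "\n")
  if (nrow(x$errors)) print(utils::head(x$errors, 10L))
  invisible(x)
}

#' @export
print.pellet_dataset <- function(x, ...) {
  cat("pellet_dataset:", nrow(x$info), "pellets,", length(x$taxa), "taxa,",
      sum(x$counts), "prey items\n")
  invisible(x)
}

#' @export
print.availability_dataset <- function(x, ...) {
  cat("availability_dataset:", nrow(x$info), "samples,", length(x$taxa),
      "taxa,", sum(x$counts), "individuals\n")
  invisible(x)
}
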