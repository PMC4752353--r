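# Tabular input/output. The canonical on-disk form is the "wide" table: one
# row per pellet (or availability sample), one column per taxon, plus the
# reserved covariate columns. A "long" form (one row per pellet x taxon) and
# an XLSX reader with a column-mapping config are also supported.

infer_sep <- function(path) {
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_file <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

write_delim_file <- function(df, path, sep) {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     qmethod = "double", fileEncoding = "UTF-8")
}

read_table_dialect <- function(path, dialect, sheet = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- switch(dialect,
    wide_csv = , long_csv = read_delim_file(path, infer_sep(path)),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("the xlsx dialect requires the 'readxl' package")
      }
      as.data.frame(readxl::read_excel(path, sheet = sheet %||% 1L),
                    stringsAsFactors = FALSE)
    },
    stop("unknown dialect: ", dialect)
  )
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(raw)) stop("mapped column not found in file: ", src)
      names(raw)[names(raw) == src] <- std
    }
  }
  raw
}

wide_to_dataset <- function(raw, reserved, metadata_cols, constructor, path) {
  need <- setdiff(reserved, names(raw))
  if (length(need) > 0L) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "))
  }
  taxa_cols <- setdiff(names(raw), c(reserved, metadata_cols))
  if (length(taxa_cols) == 0L) stop("no taxon columns found in ", path)
  counts <- as.matrix(raw[taxa_cols])
  if (!is.numeric(counts)) stop("non-numeric count column(s) in ", path)
  constructor(raw[c(reserved, intersect(metadata_cols, names(raw)))], counts)
}

#' Load a pellet table
#'
#' @param path path to the file.
#' @param dialect one of `"wide_csv"` (canonical: one row per pellet, one
#'   column per taxon; `.tsv` extension switches to tab separation),
#'   `"long_csv"` (columns `pellet_id, year, month, area, plant_fraction,
#'   taxon, count`), or `"xlsx"`.
#' @param metadata_cols columns to carry along as pellet metadata rather than
#'   taxon counts (wide dialect only).
#' @param sheet,col_map for `dialect = "xlsx"`: sheet name/index and a named
#'   list mapping the standard column names (`pellet_id`, `year`, ...) to the
#'   column names used in the workbook.
#' @param measurements optional path to a per-item measurement CSV with
#'   columns `pellet_id, taxon, length_mm, width_mm`.
#' @param quiet suppress the one-line load log.
#' @return a [pellet_dataset()].
#' @export
load_pellet_table <- function(path, dialect = c("wide_csv", "long_csv", "xlsx"),
                              metadata_cols = character(), sheet = NULL,
                              col_map = NULL, measurements = NULL,
                              quiet = FALSE) {
  dialect <- match.arg(dialect)
  raw <- read_table_dialect(path, dialect, sheet, col_map)
  if (dialect == "long_csv") {
    raw <- long_to_wide(raw, RESERVED_PELLET_COLS, "pellet_id")
  }
  meas <- if (!is.null(measurements)) {
    read_delim_file(measurements, infer_sep(measurements))
  }
  ds <- wide_to_dataset(raw, RESERVED_PELLET_COLS, metadata_cols,
                        function(info, counts) {
                          pellet_dataset(info, counts, measurements = meas)
                        }, path)
  if (!quiet) {
    message(sprintf("loaded %s: %d pellets, %d taxa, %d prey items",
                    path, nrow(ds$info), length(ds$taxa), sum(ds$counts)))
  }
  ds
}

long_to_wide <- function(raw, reserved, id_col) {
  need <- setdiff(c(reserved, "taxon", "count"), names(raw))
  if (length(need) > 0L) {
    stop("missing mandatory column(s): ", paste(need, collapse = ", "))
  }
  wide <- stats::reshape(raw, direction = "wide", idvar = reserved,
                         timevar = "taxon", v.names = "count")
  names(wide) <- sub("^count\\.", "", names(wide))
  taxa <- setdiff(names(wide), reserved)
  for (tx in taxa) wide[[tx]][is.na(wide[[tx]])] <- 0
  rownames(wide) <- NULL
  wide
}

#' Write a pellet table
#'
#' @param dataset a [pellet_dataset()].
#' @param path output path; a `.tsv` extension writes tab-separated output.
#' @param dialect `"wide_csv"` or `"long_csv"`.
#' @return `path`, invisibly.
#' @export
write_pellet_table <- function(dataset, path,
                               dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "pellet_dataset"))
  wide <- cbind(dataset$info[RESERVED_PELLET_COLS],
                as.data.frame(dataset$counts, check.names = FALSE))
  if (dialect == "long_csv") {
    long <- stats::reshape(wide, direction = "long",
                           varying = dataset$taxa, v.names = "count",
                           timevar = "taxon", times = dataset$taxa,
                           idvar = "pellet_id")
    rownames(long) <- NULL
    long <- long[order(long$pellet_id, long$taxon), ]
    write_delim_file(long, path, infer_sep(path))
  } else {
    write_delim_file(wide, path, infer_sep(path))
  }
  invisible(path)
}

#' Load an availability table
#'
#' Same dialects as [load_pellet_table()], with reserved columns
#' `sample_id, year, month, area` and no plant fraction.
#'
#' @inheritParams load_pellet_table
#' @return an [availability_dataset()].
#' @export
load_availability_table <- function(path,
                                    dialect = c("wide_csv", "long_csv", "xlsx"),
                                    metadata_cols = character(), sheet = NULL,
                                    col_map = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  raw <- read_table_dialect(path, dialect, sheet, col_map)
  if (nrow(raw) == 0L) stop("no samples in ", path)
  if (dialect == "long_csv") {
    raw <- long_to_wide(raw, RESERVED_AVAIL_COLS, "sample_id")
  }
  ds <- wide_to_dataset(raw, RESERVED_AVAIL_COLS, metadata_cols,
                        availability_dataset, path)
  if (!quiet) {
    message(sprintf("loaded %s: %d samples, %d taxa, %d individuals",
                    path, nrow(ds$info), length(ds$taxa), sum(ds$counts)))
  }
  ds
}

#' Write an availability table
#' @inheritParams write_pellet_table
#' @param dataset an [availability_dataset()].
#' @export
write_availability_table <- function(dataset, path,
                                     dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "availability_dataset"))
  wide <- cbind(dataset$info[RESERVED_AVAIL_COLS],
                as.data.frame(dataset$counts, check.names = FALSE))
  if (dialect == "long_csv") {
    long <- stats::reshape(wide, direction = "long",
                           varying = dataset$taxa, v.names = "count",
                           timevar = "taxon", times = dataset$taxa,
                           idvar = "sample_id")
    rownames(long) <- NULL
    long <- long[order(long$sample_id, long$taxon), ]
    write_delim_file(long, path, infer_sep(path))
  } else {
    write_delim_file(wide, path, infer_sep(path))
  }
  invisible(path)
}

#' Load a prey trait table
#'
#' One row per taxon; see [trait_table()] for the column contract.
#'
#' @param path CSV/TSV path.
#' @param quiet suppress the load log.
#' @return a [trait_table()].
#' @export
load_trait_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_delim_file(path, infer_sep(path))
  tt <- trait_table(raw)
  if (!quiet) message(sprintf("loaded %s: %d taxa", path, nrow(tt)))
  tt
}

#' Write a prey trait table
#' @param traits a [trait_table()].
#' @param path output CSV/TSV path.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  write_delim_file(as.data.frame(traits), path, infer_sep(path))
  invisible(path)
}

#' Built-in default prey trait table
#'
#' A small trait table for the common prey categories of an insular lacertid
#' diet (ants, beetles, woodlice, millipedes, snails, flies, ...), shipped in
#' `inst/extdata/default_traits.csv`. The allometric regression coefficients
#' in it are synthetic placeholders in the plausible range for arthropod
#' length-mass relations; replace them with regressions fitted to your own
#' study system before interpreting biomass output.
#'
#' @return a [trait_table()].
#' @export
default_trait_table <- function() {
  load_trait_table(system.file("extdata", "default_traits.csv",
                               package = "pelletdiet"), quiet = TRUE)
}
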