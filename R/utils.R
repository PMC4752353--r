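# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded routines do not perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Assemble a single grouping factor from covariate columns; group_by = character()
# pools everything into one group labelled "all".
group_factor <- function(info, group_by) {
  if (length(group_by) == 0L) {
    return(factor(rep("all", nrow(info))))
  }
  missing <- setdiff(group_by, names(info))
  if (length(missing) > 0L) {
    stop("unknown grouping variable(s): ", paste(missing, collapse = ", "))
  }
  interaction(info[group_by], drop = TRUE, sep = ".", lex.order = TRUE)
}

# Split the group labels back into a data.frame of covariate columns.
group_key_frame <- function(levels_chr, group_by) {
  if (length(group_by) == 0L) {
    return(data.frame(group = levels_chr, stringsAsFactors = FALSE))
  }
  parts <- strsplit(levels_chr, ".", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- group_by
  for (v in group_by) {
    suppressWarnings(num <- as.numeric(out[[v]]))
    if (!anyNA(num)) out[[v]] <- num
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
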