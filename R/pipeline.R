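# End-to-end orchestration: each analysis stage exposed as a subcommand
# that reads the canonical CSVs, writes its module's CSV outputs and a run
# manifest (inputs, parameters, seed, package version) for provenance.

PIPELINE_SUBCOMMANDS <- c("simulate", "summarize", "electivity", "diversity",
                          "permanova", "dispersion", "gtest", "fisher",
                          "kruskal")

#' Run one pipeline stage
#'
#' @param subcommand one of `simulate`, `summarize`, `electivity`,
#'   `diversity`, `permanova`, `dispersion`, `gtest`, `fisher`, `kruskal`.
#' @param config named list of options (or a path to a YAML file with the
#'   same structure). Common fields: `output_dir` (mandatory), `seed`,
#'   `pellets` / `availability` / `traits` (input CSV paths), `group_by`
#'   (character vector), `q_grid`, `q_set`, `B`, `n_perm`, `formula`,
#'   `distance`, `universe`, `preset`, `table` (inline count table for the
#'   classical tests), `values`/`groups` (for `kruskal`).
#' @return invisibly, a character vector of files written (including the
#'   manifest).
#' @export
run_pipeline <- function(subcommand, config) {
  subcommand <- match.arg(subcommand, PIPELINE_SUBCOMMANDS)
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- config$output_dir %||% stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stochastic <- subcommand %in% c("simulate", "diversity", "permanova",
                                  "dispersion", "fisher")
  if (stochastic && is.null(seed)) {
    stop("config$seed is required for stochastic stage '", subcommand, "'")
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_delim_file(as.data.frame(df), path, ",")
    files <<- c(files, path)
    path
  }
  need_pellets <- function() {
    if (is.null(config$pellets)) stop("config$pellets (CSV path) is required")
    load_pellet_table(config$pellets, config$dialect %||% "wide_csv",
                      quiet = TRUE)
  }

  result_summary <- switch(subcommand,
    simulate = {
      cfg_args <- config$scenario %||% list()
      sc <- if (!is.null(config$preset)) {
        do.call(preset_scenario, c(list(name = config$preset, seed = seed),
                                   cfg_args))
      } else {
        do.call(scenario_config, c(list(seed = seed), cfg_args))
      }
      sim <- generate_scenario(sc)
      write_pellet_table(sim$pellets, file.path(out_dir, "pellets.csv"))
      write_availability_table(sim$availability,
                               file.path(out_dir, "availability.csv"))
      write_trait_table(sim$traits, file.path(out_dir, "traits.csv"))
      jsonlite::write_json(
        list(diet_composition = as.data.frame(sim$truth$diet_composition),
             electivity = sim$truth$electivity, hill = sim$truth$hill,
             null_effect = sim$truth$null_effect),
        file.path(out_dir, "truth.json"), digits = NA, auto_unbox = TRUE)
      files <- c(files, file.path(out_dir, c("pellets.csv", "availability.csv",
                                             "traits.csv", "truth.json")))
      list(n_pellets = nrow(sim$pellets$info),
           n_samples = nrow(sim$availability$info))
    },
    summarize = {
      ds <- need_pellets()
      traits <- if (!is.null(config$traits)) load_trait_table(config$traits,
                                                              quiet = TRUE)
      gb <- as.character(config$group_by %||% character())
      sm <- if (is.null(traits)) diet_frequencies(ds, gb) else
        diet_summary(ds, traits, gb)
      emit(sm, "diet_summary.csv")
      emit(attr(sm, "groups"), "diet_groups.csv")
      list(n_groups = nrow(attr(sm, "groups")))
    },
    electivity = {
      ds <- need_pellets()
      if (is.null(config$availability)) stop("config$availability is required")
      av <- load_availability_table(config$availability, quiet = TRUE)
      et <- electivity_profile(colSums(ds$counts), av,
                               universe = config$universe %||% "union",
                               pool = config$pool %||% TRUE)
      emit(et, "electivity.csv")
      list(n_types = attr(et, "n_types"))
    },
    diversity = {
      ds <- need_pellets()
      gb <- as.character(config$group_by %||% character())
      prof <- diversity_profile(ds, gb, q_grid = config$q_grid %||% (-1:3))
      emit(prof, "diversity_profile.csv")
      emit(attr(prof, "groups"), "diversity_groups.csv")
      if (length(gb) > 0L) {
        ct <- bootstrap_hill_contrasts(ds, gb,
                                       q_set = config$q_set %||% c(0, 1, 2),
                                       B = config$B %||% 5000, seed = seed)
        emit(ct, "diversity_contrasts.csv")
      }
      list(n_groups = nrow(attr(prof, "groups")))
    },
    permanova = {
      if (is.null(config$formula)) stop("config$formula is required (e.g. 'year*month*area')")
      ds <- need_pellets()
      keep <- rowSums(ds$counts) > 0
      if (!all(keep)) {
        message(sprintf("excluding %d empty pellet(s) before distance computation",
                        sum(!keep)))
      }
      d <- diet_distance(ds$counts[keep, , drop = FALSE],
                         method = config$distance %||% "bray")
      pm <- permanova(d, stats::as.formula(paste("~", config$formula)),
                      ds$info[keep, , drop = FALSE],
                      n_perm = config$n_perm %||% 999, seed = seed)
      emit(pm$aov_tab, "permanova.csv")
      list(terms = nrow(pm$aov_tab) - 1L)
    },
    dispersion = {
      ds <- need_pellets()
      gb <- as.character(config$group_by %||% stop("config$group_by is required"))
      keep <- rowSums(ds$counts) > 0
      d <- diet_distance(ds$counts[keep, , drop = FALSE],
                         method = config$distance %||% "bray")
      dt <- dispersion_test(d, group_factor(ds$info[keep, , drop = FALSE], gb),
                            n_perm = config$n_perm %||% 999, seed = seed)
      emit(cbind(dt$group_stats, F = dt$F, p_perm = dt$p_perm),
           "dispersion.csv")
      list(F = dt$F, p = dt$p_perm)
    },
    gtest = {
      tab <- pipeline_table(config)
      if (nrow(tab) == 1L) tab <- tab[1L, ]  # one row: a one-way table
      ft <- g_test(tab, williams = config$williams %||% FALSE)
      emit(data.frame(method = ft$method, statistic = ft$statistic,
                      df = ft$df, p = ft$p.value), "gtest.csv")
      list(p = ft$p.value)
    },
    fisher = {
      tab <- pipeline_table(config)
      ft <- fisher_exact(tab, mc_reps = config$mc_reps %||% 10000, seed = seed)
      emit(data.frame(method = ft$method, p = ft$p.value), "fisher.csv")
      list(p = ft$p.value)
    },
    kruskal = {
      if (is.null(config$values) || is.null(config$groups)) {
        stop("config$values and config$groups are required")
      }
      ft <- kruskal_wallis(as.numeric(config$values),
                           as.character(config$groups))
      emit(data.frame(method = ft$method, statistic = ft$statistic,
                      df = ft$df, p = ft$p.value), "kruskal.csv")
      list(p = ft$p.value)
    }
  )

  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("pelletdiet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = config[setdiff(names(config), "output_dir")],
    outputs = basename(files),
    summary = result_summary
  )
  manifest_path <- file.path(out_dir, paste0("manifest_", subcommand, ".json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, manifest_path))
}

# Count table from config: inline rows (list of numeric vectors) or CSV.
pipeline_table <- function(config) {
  if (!is.null(config$table)) {
    if (is.character(config$table)) {
      as.matrix(read_delim_file(config$table, infer_sep(config$table)))
    } else {
      do.call(rbind, lapply(config$table, as.numeric))
    }
  } else {
    stop("config$table (inline rows or CSV path) is required")
  }
}
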