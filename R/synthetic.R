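# Synthetic data with known ground truth. The generator emulates the
# structure of a multi-year faecal-pellet study: a covariate grid of
# year x month x area cells, a per-cell availability composition, per-taxon
# selection coefficients linking availability to diet, Dirichlet-multinomial
# between-pellet heterogeneity, and a zero-inflated plant fraction.

#' Scenario configuration for the synthetic generator
#'
#' Diet composition per cell is `selection * availability`, renormalised;
#' every derived truth (per-cell diet composition, electivity, diversity)
#' is computable from the configuration alone, before any sampling.
#'
#' @param traits a [trait_table()]; its `name` column is the taxon list.
#' @param years,months,areas covariate grid (cells are the full cross).
#' @param availability per-area availability composition: a probability
#'   vector over taxa (recycled across areas) or a matrix with one row per
#'   area (rownames = areas). Rows are renormalised.
#' @param selection per-taxon selection coefficients s > 0: diet composition
#'   is proportional to `s * availability`. A vector (recycled across areas)
#'   or an area x taxon matrix.
#' @param pellets_per_cell pellets generated per (year, month, area) cell.
#' @param items_per_pellet mean of the Poisson count of prey items per
#'   pellet. The default 3.4 reflects the items-per-pellet ratio typical of
#'   insular lacertid pellet studies (tens of thousands of items over
#'   thousands of pellets).
#' @param dispersion Dirichlet precision controlling between-pellet
#'   compositional heterogeneity: pellet-level composition is drawn from
#'   Dirichlet(dispersion * diet_composition). Larger is more homogeneous;
#'   `Inf` removes heterogeneity (pure multinomial pellets).
#' @param plant_zero_prob probability that a pellet carries no plant matter.
#'   Default 0.56: plant matter present in a bit under half of pellets.
#' @param plant_shape1,plant_shape2 Beta parameters of the non-zero plant
#'   fraction component.
#' @param avail_samples_per_cell availability (biocenometer) replicates per
#'   cell; the classical design takes five per area.
#' @param avail_items_per_sample mean Poisson count of individuals per
#'   availability sample.
#' @param seed integer seed.
#' @return object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(traits = default_trait_table(),
                            years = c(2009, 2011, 2012),
                            months = 5:7,
                            areas = AIRE_AREAS,
                            availability = NULL,
                            selection = 1,
                            pellets_per_cell = 40,
                            items_per_pellet = 3.4,
                            dispersion = 15,
                            plant_zero_prob = 0.56,
                            plant_shape1 = 1.2,
                            plant_shape2 = 3,
                            avail_samples_per_cell = 5,
                            avail_items_per_sample = 20,
                            seed = 1) {
  taxa <- traits$name
  K <- length(taxa)
  if (length(years) == 0L || length(months) == 0L || length(areas) == 0L) {
    stop("empty covariate grid")
  }
  if (is.null(availability)) {
    # study-like skew: ants dominant, then beetles/flies/hymenopterans
    availability <- stats::setNames(rep(1, K), taxa)
    big <- intersect(c("Formicidae", "Coleoptera", "Diptera", "Hymenoptera",
                       "Heteroptera"), taxa)
    availability[big] <- c(30, 8, 6, 5, 3)[seq_along(big)]
  }
  avail <- to_area_matrix(availability, areas, taxa, "availability")
  avail <- sweep(avail, 1L, rowSums(avail), "/")
  sel <- to_area_matrix(selection, areas, taxa, "selection")
  if (any(sel <= 0)) stop("selection coefficients must be positive")
  if (any(avail < 0) || any(rowSums(avail) == 0)) {
    stop("availability must be non-negative with positive row sums")
  }
  stopifnot(pellets_per_cell >= 1, items_per_pellet > 0, dispersion > 0,
            plant_zero_prob >= 0, plant_zero_prob <= 1,
            plant_shape1 > 0, plant_shape2 > 0,
            avail_samples_per_cell >= 1, avail_items_per_sample > 0)
  structure(list(traits = traits, taxa = taxa, years = years, months = months,
                 areas = areas, availability = avail, selection = sel,
                 pellets_per_cell = pellets_per_cell,
                 items_per_pellet = items_per_pellet, dispersion = dispersion,
                 plant_zero_prob = plant_zero_prob,
                 plant_shape1 = plant_shape1, plant_shape2 = plant_shape2,
                 avail_samples_per_cell = avail_samples_per_cell,
                 avail_items_per_sample = avail_items_per_sample,
                 seed = seed),
            class = "scenario_config")
}

to_area_matrix <- function(x, areas, taxa, what) {
  if (is.matrix(x)) {
    if (ncol(x) != length(taxa)) stop(what, " matrix must have one column per taxon")
    if (nrow(x) != length(areas)) stop(what, " matrix must have one row per area")
    colnames(x) <- taxa
    rownames(x) <- areas
    return(x)
  }
  if (!is.null(names(x))) {
    v <- stats::setNames(rep(if (what == "selection") 1 else 0, length(taxa)),
                         taxa)
    v[intersect(names(x), taxa)] <- x[intersect(names(x), taxa)]
    x <- v
  } else if (length(x) == 1L) {
    x <- rep(x, length(taxa))
  }
  if (length(x) != length(taxa)) stop(what, " vector must have one entry per taxon")
  matrix(rep(x, each = length(areas)), nrow = length(areas),
         dimnames = list(areas, taxa))
}

# Ground truth derivable from the configuration alone.
scenario_truth <- function(config) {
  areas <- config$areas
  taxa <- config$taxa
  diet <- config$selection * config$availability
  diet <- sweep(diet, 1L, rowSums(diet), "/")
  truth_rows <- lapply(areas, function(a) {
    r <- diet[a, ]
    p <- config$availability[a, ]
    vs <- vanderploeg_scavia(r, p, n = length(taxa))
    data.frame(area = a, taxon = taxa, diet_prop = unname(r),
               avail_prop = unname(p), D = unname(jacobs_D(r, p)),
               E_star = unname(vs$E_star), stringsAsFactors = FALSE)
  })
  hill <- t(vapply(areas, function(a) hill_number(diet[a, ], c(0, 1, 2)),
                   numeric(3)))
  colnames(hill) <- c("q0", "q1", "q2")
  null_effect <- all(apply(diet, 2L, function(col) diff(range(col)) < 1e-12))
  list(diet_composition = diet, electivity = do.call(rbind, truth_rows),
       hill = data.frame(area = areas, hill, row.names = NULL),
       null_effect = null_effect)
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }
  g / sum(g)
}

#' Generate a synthetic pellet study
#'
#' Draws, per pellet: a pellet-level composition from a Dirichlet around the
#' cell's diet composition (precision = `dispersion`; skipped when
#' `dispersion = Inf`), a Poisson item count, multinomial prey counts, and a
#' zero-inflated Beta plant fraction. A pellet that drew zero items is
#' forced to carry plant matter, honouring the data-model rule that a
#' pellet must contain some dietary information. Availability samples are
#' multinomial draws from the cell's availability composition.
#'
#' @param config a [scenario_config()].
#' @return list with `pellets` ([pellet_dataset()]), `availability`
#'   ([availability_dataset()]), `traits` and `truth` (per-cell diet
#'   composition, true per-taxon D and E*, Hill numbers of the true
#'   compositions, and a `null_effect` flag).
#' @export
#' @examples
#' sim <- generate_scenario(preset_scenario("null_homogeneous",
#'                                          pellets_per_cell = 5, seed = 42))
#' sim$pellets
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  truth <- scenario_truth(config)
  taxa <- config$taxa
  K <- length(taxa)
  grid <- expand.grid(year = config$years, month = config$months,
                      area = config$areas, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(config$seed, {
    p_info <- list(); p_counts <- list()
    a_info <- list(); a_counts <- list()
    pid <- 0L; sid <- 0L
    for (ci in seq_len(nrow(grid))) {
      cell <- grid[ci, ]
      comp <- truth$diet_composition[cell$area, ]
      avail <- config$availability[cell$area, ]
      for (j in seq_len(config$pellets_per_cell)) {
        pid <- pid + 1L
        pi_j <- if (is.finite(config$dispersion)) {
          rdirichlet_one(config$dispersion * comp)
        } else comp
        n_items <- stats::rpois(1L, config$items_per_pellet)
        cnt <- if (n_items > 0) {
          as.integer(stats::rmultinom(1L, n_items, pi_j))
        } else integer(K)
        pf <- if (stats::runif(1L) < config$plant_zero_prob) 0 else
          stats::rbeta(1L, config$plant_shape1, config$plant_shape2)
        if (n_items == 0L && pf == 0) {
          pf <- stats::rbeta(1L, config$plant_shape1, config$plant_shape2)
        }
        p_info[[pid]] <- data.frame(pellet_id = sprintf("P%05d", pid),
                                    year = cell$year, month = cell$month,
                                    area = cell$area, plant_fraction = pf,
                                    stringsAsFactors = FALSE)
        p_counts[[pid]] <- cnt
      }
      for (j in seq_len(config$avail_samples_per_cell)) {
        sid <- sid + 1L
        n_ind <- stats::rpois(1L, config$avail_items_per_sample)
        if (n_ind == 0L) n_ind <- 1L
        a_info[[sid]] <- data.frame(sample_id = sprintf("A%05d", sid),
                                    year = cell$year, month = cell$month,
                                    area = cell$area, stringsAsFactors = FALSE)
        a_counts[[sid]] <- as.integer(stats::rmultinom(1L, n_ind, avail))
      }
    }
    pellets <- pellet_dataset(do.call(rbind, p_info),
                              matrix(unlist(p_counts), ncol = K, byrow = TRUE,
                                     dimnames = list(NULL, taxa)))
    availability <- availability_dataset(do.call(rbind, a_info),
                                         matrix(unlist(a_counts), ncol = K,
                                                byrow = TRUE,
                                                dimnames = list(NULL, taxa)))
    list(pellets = pellets, availability = availability,
         traits = config$traits, truth = truth)
  })
}

#' Preset scenarios
#'
#' Named configurations for the standard validation studies:
#'
#' * `null_homogeneous`: identical composition in every cell, selection = 1
#'   everywhere (type-I-error suites);
#' * `area_shift`: the last area's diet composition is a permutation of the
#'   others' (multivariate-test power);
#' * `strong_selection`: selection coefficients log-spaced over 0.1-10
#'   (electivity sign recovery);
#' * `diversity_gap`: two areas, one uniform over ten taxa, one with 90% of
#'   items in a single taxon (diversity-test power).
#'
#' @param name preset name.
#' @param ... overrides passed to [scenario_config()] (e.g.
#'   `pellets_per_cell`, `seed`).
#' @return a [scenario_config()].
#' @export
preset_scenario <- function(name = c("null_homogeneous", "area_shift",
                                     "strong_selection", "diversity_gap"),
                            ...) {
  name <- match.arg(name)
  dots <- list(...)
  traits <- dots$traits %||% default_trait_table()
  taxa <- traits$name
  K <- length(taxa)
  base <- switch(name,
    null_homogeneous = list(years = 2009, months = 6, areas = c("High", "Low"),
                            selection = 1),
    area_shift = {
      areas <- c("High", "Low", "North")
      sel <- matrix(1, length(areas), K, dimnames = list(areas, taxa))
      # permute the last area's diet composition by permuting its selection
      # so that s * availability lands on a shuffled composition
      avail <- stats::setNames(rep(1, K), taxa)
      big <- intersect(c("Formicidae", "Coleoptera", "Diptera", "Hymenoptera",
                         "Heteroptera"), taxa)
      avail[big] <- c(30, 8, 6, 5, 3)[seq_along(big)]
      perm <- c(seq_len(K)[-1], 1L)
      sel["North", ] <- avail[perm] / avail
      list(years = 2009, months = 6, areas = areas, availability = avail,
           selection = sel, pellets_per_cell = 30)
    },
    strong_selection = list(years = 2009, months = 5, areas = AIRE_AREAS,
                            selection = stats::setNames(
                              exp(seq(log(0.1), log(10), length.out = K)),
                              taxa),
                            pellets_per_cell = 100),
    diversity_gap = {
      areas <- c("Uniform", "Dominated")
      k10 <- min(10L, K)
      avail <- matrix(0, 2, K, dimnames = list(areas, taxa))
      avail["Uniform", seq_len(k10)] <- 1 / k10
      avail["Dominated", 1L] <- 0.9
      avail["Dominated", 2:k10] <- 0.1 / (k10 - 1)
      list(years = 2009, months = 6, areas = areas, availability = avail,
           selection = 1, pellets_per_cell = 50)
    })
  args <- utils::modifyList(c(list(traits = traits), base), dots)
  do.call(scenario_config, args)
}
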