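# Shared fixtures, built in code.

toy_pellet_dataset <- function() {
  info <- data.frame(pellet_id = c("p1", "p2"), year = c(2009L, 2009L),
                     month = c(5L, 5L), area = c("High", "High"),
                     plant_fraction = c(0.1, 0),
                     stringsAsFactors = FALSE)
  counts <- matrix(c(3L, 0L, 1L, 2L), nrow = 2,
                   dimnames = list(NULL, c("ants", "beetles")))
  pellet_dataset(info, counts)
}

toy_trait_table <- function() {
  trait_table(data.frame(
    name = c("ants", "beetles", "snails"),
    shape_model = c("prolate_spheroid", "prolate_spheroid",
                    "fixed_displacement"),
    mean_length_mm = c(4, 8, NA),
    mean_width_mm = c(1.2, 3, NA),
    fixed_volume_cm3 = c(NA, NA, 1.25),
    mass_a = c(0.05, NA, NA),
    mass_b = c(2.5, NA, NA),
    group_mean_mass_mg = c(1.1, 4.2, 35),
    stringsAsFactors = FALSE))
}

# Small multi-cell dataset with deterministic counts for grouping tests.
grid_pellet_dataset <- function() {
  grid <- expand.grid(year = c(2009L, 2011L), month = c(5L, 6L),
                      area = c("High", "Low"), stringsAsFactors = FALSE)
  info <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(pellet_id = sprintf("p%02d_%d", i, 1:3), year = grid$year[i],
               month = grid$month[i], area = grid$area[i],
               plant_fraction = 0.2, stringsAsFactors = FALSE)
  }))
  set.seed(99)
  counts <- matrix(rpois(nrow(info) * 3, 4), ncol = 3,
                   dimnames = list(NULL, c("ants", "beetles", "snails")))
  pellet_dataset(info, counts)
}

random_counts <- function(k, n = 200) {
  as.numeric(rmultinom(1, n, prob = rgamma(k, 1) + 0.05))
}
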