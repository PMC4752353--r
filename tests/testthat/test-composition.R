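# Composition metrics: per-prey volume and mass estimators, and the four
# percentage representations of the diet.

test_that("geometric volume models match hand arithmetic", {
  spheroid <- trait_table(data.frame(name = "x",
                                     shape_model = "prolate_spheroid",
                                     mean_length_mm = 10, mean_width_mm = 4))
  expect_equal(prey_volume(spheroid[1, ]), 0.083776, tolerance = 1e-5)
  cylinder <- trait_table(data.frame(name = "d", shape_model = "cylinder",
                                     mean_length_mm = 20, mean_width_mm = 3))
  expect_equal(prey_volume(cylinder[1, ]), 0.141372, tolerance = 1e-5)
  fixed <- trait_table(data.frame(name = "s",
                                  shape_model = "fixed_displacement",
                                  fixed_volume_cm3 = 1.25))
  expect_identical(prey_volume(fixed[1, ]), 1.25)
  # measured dimensions override taxon means
  expect_equal(prey_volume(spheroid[1, ], length = 20, width = 8),
               8 * 0.0837758, tolerance = 1e-5)
  nodims <- trait_table(data.frame(name = "y", shape_model = "cylinder"))
  expect_error(prey_volume(nodims[1, ]), "y")
})

test_that("dry-mass hierarchy fires exactly one rule per input", {
  traits <- toy_trait_table()
  means <- cohort_means(traits)
  # rule 1: regression on measured length
  expect_equal(prey_dry_mass(traits[1, ], length = 10, means),
               0.05 * 10^2.5, tolerance = 1e-9)
  # rule 2: identified but unmeasured -> group mean
  expect_equal(prey_dry_mass(traits[2, ], length = NA, means), 4.2)
  # measured but no regression -> still rule 2
  expect_equal(prey_dry_mass(traits[2, ], length = 12, means), 4.2)
  # rule 3: unidentified remains -> overall mean
  expect_equal(prey_dry_mass(NULL, length = NA, means),
               mean(c(1.1, 4.2, 35)))
  expect_error(prey_dry_mass(NULL, length = NA,
                             list(group = numeric(0), overall = NaN)),
               "cannot estimate")
})

test_that("numeric frequency and presence match hand counts", {
  ds <- toy_pellet_dataset()  # {ants 3, beetles 1}, {ants 0, beetles 2}
  fr <- diet_frequencies(ds)
  expect_equal(fr$pct_numeric, c(50, 50))
  expect_equal(fr$pct_presence, c(50, 100))
  groups <- attr(fr, "groups")
  expect_equal(groups$n_pellets, 2L)
  expect_equal(groups$n_items, 6)
  expect_equal(groups$plant_presence_pct, 50)

  one <- pellet_dataset(
    data.frame(pellet_id = "q", year = 2009L, month = 5L, area = "High",
               plant_fraction = 0),
    matrix(4L, 1, 1, dimnames = list(NULL, "ants")))
  fr1 <- diet_frequencies(one)
  expect_equal(fr1$pct_numeric, 100)
  expect_equal(fr1$pct_presence, 100)
})

test_that("grouping produces one summary per covariate combination", {
  ds <- grid_pellet_dataset()
  fr <- diet_frequencies(ds, group_by = c("year", "month", "area"))
  groups <- attr(fr, "groups")
  combos <- unique(ds$info[c("year", "month", "area")])
  expect_equal(nrow(groups), nrow(combos))
  expect_equal(nrow(fr), nrow(combos) * length(ds$taxa))
})

test_that("volume percentages weight counts by taxon mean volume", {
  info <- data.frame(pellet_id = c("a", "b"), year = 2009L, month = 5L,
                     area = "High", plant_fraction = 0.5)
  counts <- matrix(c(5L, 5L, 5L, 5L), 2,
                   dimnames = list(NULL, c("t1", "t2")))
  traits <- trait_table(data.frame(
    name = c("t1", "t2"), shape_model = "fixed_displacement",
    fixed_volume_cm3 = c(0.1, 0.3)))
  vol <- diet_volume_profile(pellet_dataset(info, counts), traits)
  expect_equal(vol$pct_volume, c(25, 75))

  # equal volumes: %vol collapses to %n
  traits_eq <- trait_table(data.frame(
    name = c("t1", "t2"), shape_model = "fixed_displacement",
    fixed_volume_cm3 = c(0.2, 0.2)))
  counts2 <- matrix(c(6L, 1L, 2L, 3L), 2,
                    dimnames = list(NULL, c("t1", "t2")))
  vol2 <- diet_volume_profile(pellet_dataset(info, counts2), traits_eq)
  expect_equal(vol2$pct_volume, vol2$pct_numeric)

  # single taxon
  counts3 <- matrix(c(2L, 3L), 2, dimnames = list(NULL, "t1"))
  vol3 <- diet_volume_profile(pellet_dataset(info, counts3), traits)
  expect_equal(vol3$pct_volume, 100)

  # unresolvable volume names the taxon
  bad <- trait_table(data.frame(name = c("t1", "t2"),
                                shape_model = "prolate_spheroid",
                                mean_length_mm = c(10, NA),
                                mean_width_mm = c(4, NA)))
  expect_error(diet_volume_profile(pellet_dataset(info, counts), bad), "t2")
})

test_that("biomass percentages follow the mass hierarchy", {
  info <- data.frame(pellet_id = "a", year = 2009L, month = 5L, area = "High",
                     plant_fraction = 0)
  counts <- matrix(c(1L, 1L), 1, dimnames = list(NULL, c("ants", "beetles")))
  traits <- toy_trait_table()
  meas <- data.frame(pellet_id = "a", taxon = "ants", length_mm = 10,
                     width_mm = NA)
  ds <- pellet_dataset(info, counts, measurements = meas)
  bio <- diet_biomass_profile(ds, traits)
  m <- c(0.05 * 10^2.5, 4.2)
  expect_equal(bio$pct_biomass, 100 * m / sum(m), tolerance = 1e-6)
  expect_equal(round(bio$pct_biomass, 1), c(79.0, 21.0))

  # all items one taxon -> 100
  ds1 <- pellet_dataset(info, matrix(5L, 1, 1, dimnames = list(NULL, "ants")))
  expect_equal(diet_biomass_profile(ds1, traits)$pct_biomass, 100)
})

test_that("measured and fallback mass paths agree when the measurement equals
           the calibration length", {
  # taxon whose group mean mass equals its regression at the mean length:
  # measuring an item at exactly that length must not change %b
  a <- 0.05; b <- 2.5; L <- 8
  traits <- trait_table(data.frame(
    name = c("x", "y"), shape_model = "prolate_spheroid",
    mean_length_mm = c(L, 5), mean_width_mm = c(2, 2),
    mass_a = c(a, NA), mass_b = c(b, NA),
    group_mean_mass_mg = c(a * L^b, 3)))
  info <- data.frame(pellet_id = "a", year = 2009L, month = 5L, area = "High",
                     plant_fraction = 0)
  counts <- matrix(c(2L, 1L), 1, dimnames = list(NULL, c("x", "y")))
  no_meas <- diet_biomass_profile(pellet_dataset(info, counts), traits)
  with_meas <- diet_biomass_profile(
    pellet_dataset(info, counts,
                   measurements = data.frame(pellet_id = "a", taxon = "x",
                                             length_mm = L, width_mm = NA)),
    traits)
  expect_equal(with_meas$pct_biomass, no_meas$pct_biomass, tolerance = 1e-12)
})

test_that("percentage vectors sum to 100 and respect order invariances", {
  sim <- generate_scenario(preset_scenario("null_homogeneous",
                                           pellets_per_cell = 15, seed = 11))
  sm <- diet_summary(sim$pellets, sim$traits, group_by = "area")
  for (col in c("pct_numeric", "pct_volume", "pct_biomass")) {
    sums <- tapply(sm[[col]], sm$area, sum)
    expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  }

  # %n invariant to pellet order and to splitting counts across pellets
  ds <- toy_pellet_dataset()
  rev_ds <- pellet_dataset(ds$info[2:1, ], ds$counts[2:1, ])
  expect_equal(diet_frequencies(rev_ds)$pct_numeric,
               diet_frequencies(ds)$pct_numeric)
  split_info <- rbind(ds$info, data.frame(pellet_id = "p3", year = 2009L,
                                          month = 5L, area = "High",
                                          plant_fraction = 0.1))
  split_counts <- rbind(ds$counts, ds$counts[1, , drop = FALSE])
  split_counts[1, ] <- 0L
  split_counts[1, "ants"] <- 1L
  split_counts[3, "ants"] <- 2L
  split_counts[3, "beetles"] <- 1L  # p1 (3 ants, 1 beetle) split into p1+p3
  split_ds <- pellet_dataset(split_info, split_counts)
  expect_equal(diet_frequencies(split_ds)$pct_numeric,
               diet_frequencies(ds)$pct_numeric)
  # ...but %p is not invariant to that split
  expect_false(isTRUE(all.equal(diet_frequencies(split_ds)$pct_presence,
                                diet_frequencies(ds)$pct_presence)))
})

test_that("inflating one taxon's volume raises its %vol and lowers others", {
  info <- data.frame(pellet_id = "a", year = 2009L, month = 5L, area = "High",
                     plant_fraction = 0)
  counts <- matrix(c(4L, 3L, 2L), 1, dimnames = list(NULL, c("u", "v", "w")))
  mk <- function(v1) trait_table(data.frame(
    name = c("u", "v", "w"), shape_model = "fixed_displacement",
    fixed_volume_cm3 = c(v1, 0.2, 0.3)))
  lo <- diet_volume_profile(pellet_dataset(info, counts), mk(0.1))
  hi <- diet_volume_profile(pellet_dataset(info, counts), mk(0.4))
  expect_gt(hi$pct_volume[1], lo$pct_volume[1])
  expect_lt(hi$pct_volume[2], lo$pct_volume[2])
  expect_lt(hi$pct_volume[3], lo$pct_volume[3])
})
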