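# Hill numbers, Simpson variance and bootstrap contrasts.

test_that("Hill numbers match hand arithmetic and closed forms", {
  expect_equal(hill_number(rep(5, 4), q = c(-1, 0, 0.5, 1, 2, 3)),
               rep(4, 6), tolerance = 1e-12)
  p <- c(80, 20)
  expect_equal(hill_number(p, 1), exp(-(0.8 * log(0.8) + 0.2 * log(0.2))),
               tolerance = 1e-12)
  expect_equal(round(hill_number(p, 1), 4), 1.6494)
  expect_equal(hill_number(p, 2), 1 / 0.68, tolerance = 1e-12)
  expect_equal(round(hill_number(p, 2), 5), 1.47059)
  expect_equal(hill_number(p, -1), sqrt(1.25 + 5), tolerance = 1e-12)
  expect_equal(hill_number(p, -1), 2.5)
  expect_error(hill_number(c(0, 0), 1), "zero")
})

test_that("Hill profile is continuous at q = 1 and non-increasing in q", {
  set.seed(5)
  for (i in 1:30) {
    x <- random_counts(sample(3:12, 1))
    h1 <- hill_number(x, 1)
    expect_lt(abs(hill_number(x, 1 + 1e-6) - h1), 1e-6 * h1 * 10)
    expect_lt(abs(hill_number(x, 1 - 1e-6) - h1), 1e-6 * h1 * 10)
    prof <- hill_number(x, seq(-1, 3, by = 0.25))
    expect_true(all(diff(prof) <= 1e-10))
    expect_true(all(prof >= 1 - 1e-12))
    # zero-count categories are ignored at every order
    expect_equal(hill_number(c(x, 0, 0), c(-1, 0, 1, 2)),
                 hill_number(x, c(-1, 0, 1, 2)))
  }
})

test_that("richness and inverse Simpson are exact special cases", {
  set.seed(6)
  for (i in 1:20) {
    x <- random_counts(sample(2:15, 1))
    expect_equal(hill_number(x, 0), sum(x > 0))
    expect_equal(hill_number(x, 2), 1 / simpson_with_variance(x)$lambda,
                 tolerance = 1e-12)
  }
})

test_that("Simpson index and variance match hand arithmetic", {
  sv <- simpson_with_variance(c(50, 50))
  expect_equal(sv$lambda, 0.5)
  expect_equal(sv$diversity, 0.5)
  expect_equal(sv$variance, 0, tolerance = 1e-12)

  sv2 <- simpson_with_variance(c(80, 20))
  expect_equal(sv2$lambda, 0.68)
  expect_equal(sv2$diversity, 0.32)
  expect_equal(sv2$variance, 0.002304, tolerance = 1e-12)

  expect_equal(simpson_with_variance(c(7, 0))$diversity, 0)
  expect_error(simpson_with_variance(c(1, 0)), "at least 2")
})

test_that("diversity profile equals Hill numbers of the pooled counts", {
  ds <- grid_pellet_dataset()
  prof <- diversity_profile(ds, group_by = "area", q_grid = c(0, 1, 2))
  for (a in unique(ds$info$area)) {
    pooled <- colSums(ds$counts[ds$info$area == a, , drop = FALSE])
    expect_equal(prof$hill[prof$area == a], hill_number(pooled, c(0, 1, 2)),
                 tolerance = 1e-12)
  }
  # one group = one pellet reduces to that pellet's counts
  one <- pellet_dataset(ds$info[1, , drop = FALSE],
                        ds$counts[1, , drop = FALSE])
  p1 <- diversity_profile(one, q_grid = 0:2)
  expect_equal(p1$hill, hill_number(ds$counts[1, ], 0:2))
  # identical groups give identical profiles
  dup_info <- rbind(ds$info, transform(ds$info,
                                       pellet_id = paste0(pellet_id, "b"),
                                       area = "Dup"))
  dup_info$area[seq_len(nrow(ds$info))] <- "Orig"
  dup <- pellet_dataset(dup_info, rbind(ds$counts, ds$counts))
  pd <- diversity_profile(dup, group_by = "area", q_grid = 0:2)
  expect_equal(pd$hill[pd$area == "Dup"], pd$hill[pd$area == "Orig"])
})

test_that("bootstrap contrasts: duplicated group is never declared different", {
  ds <- grid_pellet_dataset()
  dup_info <- rbind(ds$info, transform(ds$info,
                                       pellet_id = paste0(pellet_id, "b"),
                                       area = "Dup"))
  dup_info$area[seq_len(nrow(ds$info))] <- "Orig"
  dup <- pellet_dataset(dup_info, rbind(ds$counts, ds$counts))
  ct <- bootstrap_hill_contrasts(dup, "area", q_set = c(0, 1, 2), B = 400,
                                 seed = 21)
  expect_equal(ct$diff, rep(0, 3))
  expect_true(all(ct$p_raw >= 0.95))
  expect_true(all(ct$p_adj >= ct$p_raw))
})

test_that("bootstrap contrasts are seed-deterministic and validate inputs", {
  sim <- generate_scenario(preset_scenario("null_homogeneous",
                                           pellets_per_cell = 10, seed = 3))
  a <- bootstrap_hill_contrasts(sim$pellets, "area", B = 200, seed = 14)
  b <- bootstrap_hill_contrasts(sim$pellets, "area", B = 200, seed = 14)
  expect_identical(a, b)
  c2 <- bootstrap_hill_contrasts(sim$pellets, "area", B = 200, seed = 15)
  expect_false(identical(a$p_raw, c2$p_raw))
  expect_true(all(a$p_raw >= 0 & a$p_raw <= 1))

  tiny_info <- sim$pellets$info[1:3, ]
  tiny_info$area <- c("High", "High", "Low")  # a group of one pellet
  tiny <- pellet_dataset(tiny_info, sim$pellets$counts[1:3, ])
  expect_error(bootstrap_hill_contrasts(tiny, "area", B = 10, seed = 1),
               "fewer than 2")
  expect_error(bootstrap_hill_contrasts(sim$pellets, character(), B = 10,
                                        seed = 1),
               "at least 2 groups")
})

test_that("holm adjustment is an available alternative and bounds raw p", {
  sim <- generate_scenario(preset_scenario("null_homogeneous",
                                           pellets_per_cell = 8, seed = 5))
  sim$pellets$info$cellgrp <- rep(c("a", "b", "c"),
                                  length.out = nrow(sim$pellets$info))
  ct <- bootstrap_hill_contrasts(sim$pellets, "cellgrp", q_set = 2, B = 300,
                                 seed = 8, adjust = "holm")
  expect_equal(nrow(ct), 3L)
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-12))
})
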