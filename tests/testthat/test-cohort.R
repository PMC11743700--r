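test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_volumes = 3), "n_volumes")
  expect_error(cohort_spec(switch_rate = 1.5), "switch_rate")
  expect_error(cohort_spec(group_sizes = c(control = 1L, meditator = 5L)),
               "at least 2")
  expect_error(cohort_spec(occupancy_by_group = list(
    control = c(0.5, 0.2, 0.2, 0.2), meditator = c(0.4, 0.27, 0.2, 0.13))),
    "simplex")
  expect_error(planted_state(1, rep(TRUE, 10)), "fewer than half")
})

test_that("single-state library yields a constant sequence with occupancy 1", {
  lib <- disjoint_library(24, 0)
  spec <- cohort_spec(n_parcels = 24, n_volumes = 50,
                      group_sizes = c(control = 2L, meditator = 2L),
                      state_library = lib,
                      occupancy_by_group = list(control = 1, meditator = 1),
                      switch_rate = 0.7, covariate_links = NULL, seed = 5)
  sq <- sample_state_sequence(spec, "control", seed = 9)
  expect_equal(sq, rep(1L, 50))
  expect_equal(occurrence_probabilities(sq, 1), 1)
})

test_that("switch_rate = 1 draws i.i.d. states matching the stationary law", {
  lib <- disjoint_library(24, c(0, 6))
  spec <- cohort_spec(n_parcels = 24, n_volumes = 10000,
                      group_sizes = c(control = 2L, meditator = 2L),
                      state_library = lib,
                      occupancy_by_group = list(control = c(0.5, 0.5),
                                                meditator = c(0.5, 0.5)),
                      switch_rate = 1, covariate_links = NULL, seed = 5)
  sq <- sample_state_sequence(spec, "control", seed = 21)
  expect_lt(abs(mean(sq == 1) - 0.5), 0.02)
})

test_that("state sequences and cohorts are reproducible from the seed", {
  spec <- cohort_spec(n_parcels = 48, n_volumes = 40,
                      group_sizes = c(control = 2L, meditator = 2L),
                      state_library = disjoint_library(48, c(0, 12)),
                      occupancy_by_group = list(control = c(0.6, 0.4),
                                                meditator = c(0.4, 0.6)),
                      seed = 17)
  expect_identical(sample_state_sequence(spec, "control", 3),
                   sample_state_sequence(spec, "control", 3))
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$scans[[1]]$matrix, c2$scans[[1]]$matrix)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$ground_truth, c2$ground_truth)
})

test_that("noise-free scans realize the planted anti-phase geometry", {
  n <- 24
  lib <- list(planted_state(1L, rep(FALSE, n), "global"),
              planted_state(2L, c(TRUE, rep(FALSE, n - 1)), "solo"))
  spec <- cohort_spec(n_parcels = n, n_volumes = 30,
                      group_sizes = c(control = 2L, meditator = 2L),
                      state_library = lib,
                      occupancy_by_group = list(control = c(0.5, 0.5),
                                                meditator = c(0.5, 0.5)),
                      noise_sd = 0, covariate_links = NULL, seed = 3)
  glob <- synthesize_scan(spec, rep(1L, 30), seed = 1)
  expect_true(all(abs(sweep(glob$matrix, 2, glob$matrix[1, ])) < 1e-12))
  solo <- synthesize_scan(spec, rep(2L, 30), seed = 1)
  expect_equal(solo$matrix[1, ], -solo$matrix[2, ], tolerance = 1e-12)
  expect_error(synthesize_scan(spec, rep(9L, 30), seed = 1), "absent")
  expect_error(synthesize_scan(spec, rep(1L, 10), seed = 1), "length")
})

test_that("ground-truth occupancy is exactly the sequence histogram", {
  spec <- cohort_spec(n_parcels = 48, n_volumes = 60,
                      group_sizes = c(control = 3L, meditator = 2L),
                      state_library = disjoint_library(48, c(0, 10, 10)),
                      occupancy_by_group = list(control = c(0.4, 0.3, 0.3),
                                                meditator = c(0.3, 0.4, 0.3)),
                      seed = 29)
  co <- generate_cohort(spec)
  for (i in seq_len(5)) {
    sq <- co$ground_truth$sequences[i, ]
    expect_identical(co$ground_truth$occupancy[i, ],
                     c(state1 = mean(sq == 1), state2 = mean(sq == 2),
                       state3 = mean(sq == 3)))
  }
  expect_true(all(abs(rowSums(co$ground_truth$occupancy) - 1) < 1e-12))
})

test_that("cohort metadata respects group structure and covariate links", {
  links <- data.frame(covariate = "hood_unifying", state_id = 2L,
                      slope = 10, noise_sd = 0.1)
  spec <- cohort_spec(n_parcels = 48, n_volumes = 120,
                      group_sizes = c(control = 19L, meditator = 17L),
                      state_library = disjoint_library(48, c(0, 12)),
                      occupancy_by_group = list(control = c(0.6, 0.4),
                                                meditator = c(0.45, 0.55)),
                      covariate_links = links, seed = 41)
  co <- generate_cohort(spec)
  md <- co$metadata
  expect_length(co$scans, 36)
  expect_equal(dim(co$scans[[1]]$matrix), c(48, 120))
  expect_equal(table(md$group)[["control"]], 19)
  expect_equal(table(md$group)[["meditator"]], 17)
  expect_true(all(is.na(md$expertise_years[md$group == "control"])))
  expect_true(all(!is.na(md$expertise_years[md$group == "meditator"])))
  expect_equal(md$hood_mean,
               rowMeans(md[, grep("^hood_(?!mean)", names(md), perl = TRUE)]))
  # linked covariate tracks the true occupancy of its state
  rho <- cor(md$hood_unifying, co$ground_truth$occupancy[, "state2"],
             method = "spearman")
  expect_gt(rho, 0.6)
})

test_that("a slope-0 link leaves the covariate uncorrelated with occupancy", {
  links <- data.frame(covariate = "age", state_id = 2L, slope = 0,
                      noise_sd = 8)
  spec <- cohort_spec(n_parcels = 48, n_volumes = 120,
                      group_sizes = c(control = 19L, meditator = 17L),
                      state_library = disjoint_library(48, c(0, 12)),
                      occupancy_by_group = list(control = c(0.6, 0.4),
                                                meditator = c(0.6, 0.4)),
                      covariate_links = links, seed = 57)
  co <- generate_cohort(spec)
  rho <- cor(co$metadata$age, co$ground_truth$occupancy[, "state2"],
             method = "spearman")
  expect_lt(abs(rho), 0.4)
})
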