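make_series <- function(mat, subject_id, volumes = seq_len(nrow(mat)) + 1) {
  structure(list(vectors = mat, eigenvalues = rep(1, nrow(mat)),
                 degenerate = rep(FALSE, nrow(mat)), kept_volumes = volumes,
                 subject_id = subject_id, group = NA_character_),
            class = "eigenvector_series")
}

test_that("pooling concatenates series in subject-then-time order", {
  a <- normalize_rows_fixture(matrix(rnorm(6 * 5), 6, 5))
  b <- normalize_rows_fixture(matrix(rnorm(4 * 5), 4, 5))
  pool <- pool_eigenvectors(list(make_series(a, "s1"), make_series(b, "s2")))
  expect_equal(nrow(pool$matrix), 10)
  expect_equal(pool$provenance$subject_id, rep(c("s1", "s2"), c(6, 4)))
  expect_equal(pool$matrix[1:6, ], a)
  expect_error(pool_eigenvectors(list()), "no eigenvector series")
  wrong <- make_series(normalize_rows_fixture(matrix(rnorm(6), 2, 3)), "s3")
  expect_error(pool_eigenvectors(list(make_series(a, "s1"), wrong)),
               "disagree on parcel count")
})

test_that("two orthogonal planted clouds are separated exactly at k = 2", {
  n <- 8
  a <- c(1, rep(0, n - 1)); b <- c(0, 1, rep(0, n - 2))
  x <- rbind(matrix(a, 100, n, byrow = TRUE), matrix(b, 100, n, byrow = TRUE))
  pool <- pool_from_matrix(x)
  model <- cluster_partition(pool, 2, seed = 5, replicates = 5)
  groups <- split(model$assignments, rep(c("a", "b"), each = 100))
  expect_length(unique(groups$a), 1)
  expect_length(unique(groups$b), 1)
  expect_false(groups$a[1] == groups$b[1])
  ca <- model$centroids[groups$a[1], ]
  expect_equal(ca / sqrt(sum(ca^2)), a, tolerance = 1e-12)
})

test_that("identical rows trigger the documented degenerate-cluster path", {
  x <- matrix(rep(c(1, rep(0, 5)), 50), 50, 6, byrow = TRUE)
  model <- cluster_partition(pool_from_matrix(x), 2, seed = 1, replicates = 3)
  expect_true(model$degenerate)
  expect_equal(sort(model$sizes, decreasing = TRUE)[1], 50)
  expect_equal(sum(model$sizes), 50)
})

test_that("clustering is deterministic given the seed and respects k bounds", {
  set.seed(23)
  x <- normalize_rows_fixture(matrix(rnorm(60 * 6), 60, 6))
  pool <- pool_from_matrix(x)
  m1 <- cluster_partition(pool, 3, seed = 9, replicates = 5)
  m2 <- cluster_partition(pool, 3, seed = 9, replicates = 5)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$centroids, m2$centroids)
  expect_error(cluster_partition(pool, 1), "at least 2")
  expect_error(cluster_partition(pool, 61), "exceeds")
})

test_that("centroids equal the mean of their members at convergence", {
  set.seed(31)
  x <- normalize_rows_fixture(matrix(rnorm(80 * 5), 80, 5))
  model <- cluster_partition(pool_from_matrix(x), 4, seed = 2, replicates = 5)
  for (j in seq_len(4)) {
    members <- x[model$assignments == j, , drop = FALSE]
    expect_equal(unname(model$centroids[j, ]), colMeans(members),
                 tolerance = 1e-9)
  }
  expect_equal(sum(model$sizes), 80)
  expect_equal(order(model$sizes, decreasing = TRUE)[1], 1)  # label order
})

test_that("the sweep produces one model per granularity with independent seeds", {
  set.seed(37)
  x <- normalize_rows_fixture(matrix(rnorm(300 * 8), 300, 8))
  pool <- pool_from_matrix(x)
  models <- sweep_partitions(pool, 2, 20, seed = 4, replicates = 2)
  expect_length(models, 19)
  expect_equal(vapply(models, `[[`, integer(1), "k"), setNames(2:20, names(models)))
  one <- sweep_partitions(pool, 2, 2, seed = 4, replicates = 2)
  expect_length(one, 1)
  again <- sweep_partitions(pool, 2, 20, seed = 4, replicates = 2)
  expect_identical(lapply(models, `[[`, "assignments"),
                   lapply(again, `[[`, "assignments"))
})

test_that("global-mode detection follows the all-one-sign rule", {
  fake_model <- function(centroids, sizes) {
    structure(list(k = nrow(centroids), centroids = centroids,
                   sizes = sizes), class = "partition_model")
  }
  m <- fake_model(rbind(c(-0.3, -0.2, -0.5, -0.1), c(-0.1, 0.4, -0.2, 0.1)),
                  c(30, 20))
  expect_equal(flag_global_mode(m), 1L)
  m <- fake_model(rbind(c(-0.3, 0.01, -0.5, -0.1), c(-0.1, 0.4, -0.2, 0.1)),
                  c(30, 20))
  expect_true(is.na(flag_global_mode(m)))
  # several qualifying clusters: the most occupied wins
  m <- fake_model(rbind(c(-1, -1, -1, -1), c(-2, -1, -1, 0), c(0.5, -1, 1, 1)),
                  c(10, 40, 5))
  expect_equal(flag_global_mode(m), 2L)
})

test_that("noise-free planted states are recovered exactly by clustering", {
  n <- 48
  lib <- disjoint_library(n, c(10, 10, 10))
  spec <- cohort_spec(n_parcels = n, n_volumes = 40,
                      group_sizes = c(control = 3L, meditator = 3L),
                      state_library = lib,
                      occupancy_by_group = list(control = c(0.4, 0.3, 0.3),
                                                meditator = c(0.4, 0.3, 0.3)),
                      noise_sd = 0, covariate_links = NULL, seed = 6)
  # two constant-state scans per planted state: no transitions, no noise
  scans <- list()
  truth <- integer(0)
  for (s in 1:3) for (r in 1:2) {
    scans[[length(scans) + 1]] <-
      synthesize_scan(spec, rep(s, 40), seed = 10 * s + r,
                      subject_id = sprintf("s%d_%d", s, r))
    truth <- c(truth, rep(s, 38))
  }
  pool <- pool_eigenvectors(lapply(scans, eigenvector_series))
  model <- cluster_partition(pool, 3, seed = 8, replicates = 5)
  tab <- table(model$assignments, truth)
  expect_true(all(colSums(tab > 0) == 1), info = "one-to-one contingency")
  expect_equal(min(jaccard_by_state(model$assignments, truth, 3)), 1)
  # the cluster centroids match the planted eigenvectors
  for (s in 1:3) {
    planted <- planted_eigenvector(lib[[s]])
    sims <- model$centroids_norm %*% planted
    expect_gt(max(sims), 1 - 1e-9)
  }
})

test_that("state time courses reconstruct per-subject sequences", {
  set.seed(43)
  a <- normalize_rows_fixture(matrix(rnorm(20 * 4), 20, 4))
  pool <- pool_from_matrix(a, subject_id = "only")
  model <- cluster_partition(pool, 2, seed = 3, replicates = 3)
  tcs <- state_timecourses(model)
  expect_named(tcs, "only")
  expect_identical(tcs$only, model$assignments)
  model$provenance <- model$provenance[-1, ]
  expect_error(state_timecourses(model), "provenance")
})
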