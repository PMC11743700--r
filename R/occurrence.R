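#' Fractional occupancy of one state time course
#'
#' The probability of occurrence of each state: the number of volumes
#' assigned to it divided by the total number of volumes in the scan.
#'
#' @param sequence integer state sequence (values in `1..k`).
#' @param k number of states in the partition.
#' @return numeric length-`k` probability vector summing to 1.
#' @export
occurrence_probabilities <- function(sequence, k) {
  if (length(sequence) == 0) stop("empty state sequence")
  if (any(sequence < 1 | sequence > k)) stop("state ids outside 1..k")
  tabulate(sequence, k) / length(sequence)
}

#' Subjects-by-states occupancy table for one partition
#'
#' @param model a [partition_model].
#' @return numeric matrix (subjects x k, rownames = subject ids, rows sum
#'   to 1).
#' @export
occurrence_table <- function(model) {
  tcs <- state_timecourses(model)
  out <- t(vapply(tcs, occurrence_probabilities, numeric(model$k), k = model$k))
  colnames(out) <- paste0("state", seq_len(model$k))
  out
}

#' Occupancy tables for every partition in a sweep
#'
#' @param models list of [partition_model]s as returned by
#'   [sweep_partitions()].
#' @return named list of occupancy matrices.
#' @export
occurrence_tables <- function(models) lapply(models, occurrence_table)

# Pooled-variance two-sample t statistic; returns 0/NA handling to caller.
.t_pooled <- function(m1, m2, q1, q2, n1, n2) {
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q2 - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Permutation two-sample test on a t statistic
#'
#' Compares two groups with the pooled-variance Student t statistic while
#' estimating the null by random relabelings of the pooled values into
#' groups of the original sizes. The two-sided sampled p-value uses the
#' add-one estimator `(1 + b) / (M + 1)` where `b` counts permutations with
#' `|t| >= |t_obs|`. With `exact = TRUE` all distinct label splits are
#' enumerated instead and `p = b / n_splits` (the identity split counts).
#' Zero pooled variance returns `p = 1`.
#'
#' @param a,b numeric value vectors (each of length >= 2).
#' @param M number of sampled permutations.
#' @param seed integer seed for the label draws.
#' @param exact enumerate all `choose(n1+n2, n1)` splits instead of sampling.
#' @return list: `p_value`, `t_obs`, `M` (permutations or splits used),
#'   `exact`.
#' @export
permutation_test <- function(a, b, M = 10000L, seed = 1L, exact = FALSE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  y <- c(a, b); n <- n1 + n2
  if (var(y) < 1e-300)
    return(list(p_value = 1, t_obs = 0, M = if (exact) choose(n, n1) else M,
                exact = exact))
  S <- sum(y); Q <- sum(y^2)
  tfun <- function(idx1) {
    s1 <- sum(y[idx1]); q1 <- sum(y[idx1]^2)
    .t_pooled(s1 / n1, (S - s1) / n2, q1, Q - q1, n1, n2)
  }
  t_obs <- tfun(seq_len(n1))
  thr <- abs(t_obs) * (1 - 1e-12)  # guard against tie round-off
  if (exact) {
    splits <- combn(n, n1)
    tperm <- apply(splits, 2, tfun)
    tperm[is.na(tperm)] <- Inf  # zero within-split variance: maximal statistic
    b_cnt <- sum(abs(tperm) >= thr)
    return(list(p_value = b_cnt / ncol(splits), t_obs = t_obs,
                M = ncol(splits), exact = TRUE))
  }
  # the null is sampled from the sorted pool with the smaller group drawn,
  # so the sampled p is exactly invariant to swapping the group labels
  ysort <- sort(y)
  m1 <- min(n1, n2); m2 <- n - m1
  idx <- with_seed(seed,
                   vapply(seq_len(M), function(i) sample.int(n, m1),
                          integer(m1)))  # m1 x M
  ys <- matrix(ysort[idx], nrow = m1)
  s1 <- colSums(ys); q1 <- colSums(ys^2)
  tperm <- .t_pooled(s1 / m1, (S - s1) / m2, q1, Q - q1, m1, m2)
  tperm[is.na(tperm)] <- Inf
  b_cnt <- sum(abs(tperm) >= thr)
  list(p_value = (1 + b_cnt) / (M + 1), t_obs = t_obs, M = M, exact = FALSE)
}

#' Significance tier under per-partition Bonferroni correction
#'
#' Multiple comparisons within one partition model are handled by dividing
#' the significance threshold by the number of states `k`:
#' `p < alpha/k` is corrected-significant, `alpha/k <= p < alpha` nominal,
#' otherwise not significant.
#'
#' @param p p-value in (0, 1].
#' @param k number of states in the partition model.
#' @param alpha uncorrected significance level.
#' @return one of `"corrected"`, `"nominal"`, `"ns"`.
#' @export
significance_tier <- function(p, k, alpha = 0.05) {
  stopifnot(p > 0, p <= 1, k >= 2)
  if (p < alpha / k) "corrected" else if (p < alpha) "nominal" else "ns"
}

#' Hedges' g (biased form) with pooled standard deviation
#'
#' Standardized mean difference `g = |mean(a) - mean(b)| / s*` with
#' `s* = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` (sample
#' variances, n-1 denominator). The magnitude is returned together with the
#' direction (which group's mean is larger).
#'
#' @param a,b numeric value vectors.
#' @return list: `g` (>= 0), `direction` (`"a"`, `"b"`, or `"equal"`),
#'   `pooled_sd`.
#' @export
hedges_g <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 + n2 < 3) stop("need at least 3 values in total")
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  if (!is.finite(sp) || sp == 0) stop("pooled standard deviation is zero")
  d <- mean(a) - mean(b)
  list(g = abs(d) / sp,
       direction = if (d > 0) "a" else if (d < 0) "b" else "equal",
       pooled_sd = sp)
}

#' Between-group comparison of occupancies across all partitions
#'
#' For every state of every partition model, compares the two groups'
#' fractional occupancies by [permutation_test()], assigns the per-partition
#' Bonferroni tier, and computes Hedges' g for states reaching at least
#' nominal significance. Each (k, state) test draws its permutations from
#' its own seed substream, so results do not depend on evaluation order.
#'
#' @param occ named list of occupancy matrices from [occurrence_tables()].
#' @param metadata data frame with `subject_id` and `group` columns covering
#'   all subjects (exactly two groups).
#' @param M permutations per test.
#' @param seed master seed.
#' @param alpha uncorrected significance level.
#' @return data frame with one row per (k, state): `k`, `cluster`,
#'   `p_value`, `t_obs`, `tier`, `direction` (label of the larger-mean
#'   group), `g`, group means and SEMs, `n1`, `n2`, `M`.
#' @export
compare_groups <- function(occ, metadata, M = 10000L, seed = 1L,
                           alpha = 0.05) {
  stopifnot(is.list(occ), is.data.frame(metadata))
  glev <- unique(metadata$group)
  if (length(glev) != 2)
    stop("group comparison requires exactly two groups, got ",
         length(glev))
  rows <- list()
  for (nm in names(occ)) {
    P <- occ[[nm]]
    k <- ncol(P)
    miss <- setdiff(rownames(P), metadata$subject_id)
    if (length(miss)) stop("subjects missing from metadata: ",
                           paste(miss, collapse = ", "))
    grp <- metadata$group[match(rownames(P), metadata$subject_id)]
    ga <- P[grp == glev[1], , drop = FALSE]
    gb <- P[grp == glev[2], , drop = FALSE]
    for (cl in seq_len(k)) {
      a <- ga[, cl]; b <- gb[, cl]
      pt <- permutation_test(a, b, M = M,
                             seed = substream_seed(seed, 1000 * k + cl))
      tier <- significance_tier(pt$p_value, k, alpha)
      g <- NA_real_; dir <- NA_character_
      if (mean(a) != mean(b)) dir <- if (mean(a) > mean(b)) glev[1] else glev[2]
      if (tier != "ns") {
        hg <- tryCatch(hedges_g(a, b), error = function(e) NULL)
        if (!is.null(hg)) g <- hg$g
      }
      rows[[length(rows) + 1]] <- data.frame(
        k = k, cluster = cl, p_value = pt$p_value, t_obs = pt$t_obs,
        tier = tier, direction = dir, g = g,
        mean_1 = mean(a), sem_1 = sd(a) / sqrt(length(a)),
        mean_2 = mean(b), sem_2 = sd(b) / sqrt(length(b)),
        n1 = length(a), n2 = length(b), M = pt$M,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- glev
  out
}
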