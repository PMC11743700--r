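#' Spearman rank correlation with two-sided p-value
#'
#' Rank correlation with average ranks for ties. The p-value is exact
#' (permutation distribution) for n <= 10 without ties and uses the
#' t-approximation otherwise.
#'
#' @param x,y paired numeric vectors, n >= 4, no missing values.
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (anyNA(x) || anyNA(y)) stop("missing values in correlation input")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  ties <- anyDuplicated(x) || anyDuplicated(y)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 10 && !ties)))
  list(rho = unname(ct$estimate), p_value = min(ct$p.value, 1), n = n)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the m raw p-values ascending and takes
#' `adj_(i) = max_(j<=i) min(1, (m-j+1) p_(j))`, mapped back to the input
#' order. Controls the family-wise error rate at least as well as plain
#' Bonferroni while being uniformly more powerful.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "holm")
}

# Measures available per cohort subset.
covariate_measures <- function(metadata) {
  hood <- intersect(c(hood_subscales(), "hood_mean"), names(metadata))
  list(all_subsets = c(intersect("age", names(metadata)), hood),
       meditators_only = intersect(c("expertise_years", "expertise_hours"),
                                   names(metadata)))
}

#' Correlate state occupancies with subject covariates
#'
#' For each cohort subset (whole sample, each group) and each covariate
#' measure, computes the Spearman correlation between every state's
#' occupancy and the measure, applying Holm-Bonferroni correction within
#' the family of one partition model x one measure x one subset (the k
#' states of the model). Age and mysticism measures run on the whole sample
#' and on each group; meditation-expertise measures run only within the
#' meditator group. Subsets with fewer than 4 complete pairs are skipped
#' with a warning.
#'
#' @param occ named list of occupancy matrices from [occurrence_tables()].
#' @param metadata subject metadata data frame (`subject_id`, `group`,
#'   covariate columns).
#' @param meditator_group group label owning the expertise measures;
#'   defaults to the group whose name starts with "medit", else the second
#'   group level.
#' @param alpha significance level applied to the Holm-adjusted p-values.
#' @return data frame: `subset`, `measure`, `k`, `cluster`, `n`, `rho`,
#'   `p_raw`, `p_holm`, `significant`.
#' @export
covariate_scan <- function(occ, metadata, meditator_group = NULL,
                           alpha = 0.05) {
  stopifnot(is.list(occ), is.data.frame(metadata))
  glev <- unique(metadata$group)
  if (is.null(meditator_group)) {
    hit <- grep("^medit", glev, value = TRUE)
    meditator_group <- if (length(hit)) hit[1] else glev[min(2, length(glev))]
  }
  meas <- covariate_measures(metadata)
  subsets <- c(list(whole = metadata$subject_id),
               stats::setNames(lapply(glev, function(g)
                 metadata$subject_id[metadata$group == g]), glev))
  plan <- list()
  for (s in names(subsets)) for (m in meas$all_subsets)
    plan[[length(plan) + 1]] <- c(s, m)
  for (m in meas$meditators_only)
    plan[[length(plan) + 1]] <- c(meditator_group, m)

  rows <- list()
  for (pm in plan) {
    subset_name <- pm[1]; measure <- pm[2]
    ids <- subsets[[subset_name]]
    vals <- metadata[[measure]][match(ids, metadata$subject_id)]
    keep <- !is.na(vals)
    ids <- ids[keep]; vals <- vals[keep]
    if (length(ids) < 4) {
      warning("subset '", subset_name, "' too small for measure '", measure,
              "' (n = ", length(ids), "); skipped")
      next
    }
    for (nm in names(occ)) {
      P <- occ[[nm]][ids, , drop = FALSE]
      k <- ncol(P)
      res <- lapply(seq_len(k), function(cl) {
        r <- tryCatch(spearman_rho(vals, P[, cl]),
                      error = function(e) list(rho = NA_real_, p_value = NA_real_,
                                               n = length(ids)))
        r
      })
      praw <- vapply(res, `[[`, numeric(1), "p_value")
      ok <- !is.na(praw)
      pholm <- rep(NA_real_, k)
      if (any(ok)) pholm[ok] <- holm_adjust(praw[ok])
      rows[[length(rows) + 1]] <- data.frame(
        subset = subset_name, measure = measure, k = k,
        cluster = seq_len(k), n = length(ids),
        rho = vapply(res, `[[`, numeric(1), "rho"),
        p_raw = praw, p_holm = pholm,
        significant = !is.na(pholm) & pholm < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
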