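#' Correlation between two state centroids
#'
#' Product-moment (or rank) correlation across the N centroid elements; used
#' to decide whether phase-locking states from different partition models
#' describe the same coupling pattern.
#'
#' @param c1,c2 numeric centroid vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in `[-1, 1]`.
#' @export
centroid_similarity <- function(c1, c2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(c1) != length(c2)) stop("centroids differ in length")
  if (sd(c1) == 0 || sd(c2) == 0)
    stop("zero-variance centroid: correlation undefined")
  cor(c1, c2, method = method)
}

#' Group significant states into coupling modes
#'
#' Builds a graph over the significant states with an edge wherever the
#' centroid correlation reaches `threshold` and the two states share the
#' same group-difference direction, then takes single-linkage connected
#' components. Components with two or more members become coupling modes
#' (recurring coupling patterns independent of partition granularity);
#' isolated states are reported as partition-specific.
#'
#' @param states data frame with columns `k`, `cluster`, `direction`, plus
#'   any statistics to carry along (e.g. `p_value`, `g`).
#' @param centroids numeric matrix, one row per row of `states`.
#' @param threshold minimum centroid correlation for an edge (default 0.8).
#' @param method correlation type passed to [centroid_similarity()].
#' @return list with `modes` (list of coupling modes: `id`, `direction`,
#'   `members` data frame, `correlations` matrix) and `partition_specific`
#'   (data frame of ungrouped states).
#' @export
group_coupling_modes <- function(states, centroids, threshold = 0.8,
                                 method = "pearson") {
  if (is.null(states) || nrow(states) == 0)
    return(list(modes = list(), partition_specific = states))
  stopifnot(nrow(states) == nrow(centroids))
  n <- nrow(states)
  # stable canonical order so grouping cannot depend on input ordering
  ord <- order(states$k, states$cluster)
  states <- states[ord, , drop = FALSE]
  centroids <- centroids[ord, , drop = FALSE]
  rr <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      rr[i, j] <- rr[j, i] <- centroid_similarity(centroids[i, ],
                                                  centroids[j, ],
                                                  method = method)
  }
  adj <- rr >= threshold &
    outer(states$direction, states$direction, `==`)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  modes <- list()
  specific <- states[0, , drop = FALSE]
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    if (length(members) >= 2) {
      modes[[length(modes) + 1]] <- list(
        id = length(modes) + 1L,
        direction = states$direction[members[1]],
        members = states[members, , drop = FALSE],
        correlations = rr[members, members, drop = FALSE])
    } else {
      specific <- rbind(specific, states[members, , drop = FALSE])
    }
  }
  list(modes = modes, partition_specific = specific)
}
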