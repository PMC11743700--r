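#' Pool leading eigenvectors across scans
#'
#' Concatenates the eigenvector series of all scans, in subject-then-time
#' order, into the clustering substrate, keeping per-row provenance.
#'
#' @param series list of `eigenvector_series` objects sharing the same
#'   parcel count.
#' @return object of class `pooled_eigenvectors`: `matrix` (rows = kept
#'   volumes across all scans, unit-norm), `provenance` (data frame with
#'   `subject_id`, `group`, `volume`).
#' @export
pool_eigenvectors <- function(series) {
  if (length(series) == 0) stop("no eigenvector series to pool")
  ns <- vapply(series, function(s) ncol(s$vectors), integer(1))
  if (length(unique(ns)) != 1)
    stop("eigenvector series disagree on parcel count: ",
         paste(unique(ns), collapse = ", "))
  mat <- do.call(rbind, lapply(series, `[[`, "vectors"))
  prov <- do.call(rbind, lapply(series, function(s)
    data.frame(subject_id = s$subject_id, group = s$group,
               volume = s$kept_volumes, stringsAsFactors = FALSE)))
  structure(list(matrix = mat, provenance = prov),
            class = "pooled_eigenvectors")
}

#' @export
print.pooled_eigenvectors <- function(x, ...) {
  cat("Pooled eigenvectors:", nrow(x$matrix), "volumes from",
      length(unique(x$provenance$subject_id)), "scans,",
      ncol(x$matrix), "parcels\n")
  invisible(x)
}

# One spherical k-means replicate: assignment by maximal cosine similarity to
# renormalized centroids, update by arithmetic mean. Returns NULL when a
# cluster empties (caller re-seeds the replicate).
.kmeans_cosine_once <- function(X, k, seed, max_iter) {
  n <- nrow(X)
  init <- with_seed(seed, sample.int(n, k))
  Craw <- X[init, , drop = FALSE]
  assign_prev <- NULL
  for (it in seq_len(max_iter)) {
    Cn <- normalize_rows(Craw, "centroid")
    sim <- X %*% t(Cn)
    assign <- max.col(sim, ties.method = "first")
    if (length(unique(assign)) < k) return(NULL)
    if (!is.null(assign_prev) && all(assign == assign_prev)) break
    assign_prev <- assign
    Craw <- t(vapply(seq_len(k),
                     function(j) colMeans(X[assign == j, , drop = FALSE]),
                     numeric(ncol(X))))
  }
  inertia <- sum(1 - sim[cbind(seq_len(n), assign)])
  list(centroids = Craw, assignments = assign, inertia = inertia,
       iterations = it)
}

#' Cluster pooled eigenvectors into k phase-locking states
#'
#' k-means under cosine distance (1 - cosine similarity): rows are assigned
#' to the nearest renormalized centroid, while reported centroids `Vc` are
#' the raw arithmetic means of their members. The best of `replicates`
#' seeded restarts (lowest within-cluster cosine inertia) is kept. A restart
#' whose update empties a cluster is re-seeded with a fresh initialization;
#' if every attempt degenerates (e.g. all rows identical), the single
#' populated-cluster solution is returned with `degenerate = TRUE`. Cluster
#' labels are ordered by descending occupancy (member count), so the most
#' visited state is cluster 1.
#'
#' @param pool a [pooled_eigenvectors].
#' @param k number of clusters (>= 2, <= number of rows).
#' @param seed integer seed; each replicate derives a substream from it.
#' @param replicates number of seeded restarts.
#' @param max_iter Lloyd iteration cap per replicate.
#' @return object of class `partition_model`: `k`, `centroids` (k x N raw
#'   means), `centroids_norm`, `assignments`, `sizes`, `inertia`,
#'   `global_mode_id`, `provenance`, `seed`, `replicates`, `degenerate`.
#' @export
cluster_partition <- function(pool, k, seed = 1L, replicates = 50L,
                              max_iter = 500L) {
  stopifnot(inherits(pool, "pooled_eigenvectors"))
  X <- pool$matrix
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(X)) stop("k = ", k, " exceeds the number of pooled rows (",
                        nrow(X), ")")
  best <- NULL
  degenerate <- FALSE
  for (r in seq_len(replicates)) {
    fit <- NULL
    for (attempt in 0:19) {
      fit <- .kmeans_cosine_once(X, k, substream_seed(seed, 100 * r + attempt),
                                 max_iter)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      # data cannot sustain k populated clusters; collapse onto one centroid
      degenerate <- TRUE
      Cn <- normalize_rows(matrix(colMeans(X), 1))
      sim1 <- as.numeric(X %*% t(Cn))
      Craw <- matrix(0, k, ncol(X)); Craw[1, ] <- colMeans(X)
      fit <- list(centroids = Craw, assignments = rep(1L, nrow(X)),
                  inertia = sum(1 - sim1), iterations = 0L)
    }
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  # relabel by descending cluster size; ties by original label
  sizes <- tabulate(best$assignments, k)
  ord <- order(-sizes, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assignments <- relabel[best$assignments]
  centroids <- best$centroids[ord, , drop = FALSE]
  sizes <- sizes[ord]
  rownames(centroids) <- paste0("state", seq_len(k))
  norm_ok <- sqrt(rowSums(centroids^2)) > 0
  centroids_norm <- centroids
  centroids_norm[norm_ok, ] <- normalize_rows(centroids[norm_ok, , drop = FALSE])
  model <- structure(list(k = as.integer(k), centroids = centroids,
                          centroids_norm = centroids_norm,
                          assignments = assignments, sizes = sizes,
                          inertia = best$inertia,
                          global_mode_id = NA_integer_,
                          provenance = pool$provenance,
                          seed = as.integer(seed),
                          replicates = as.integer(replicates),
                          degenerate = degenerate),
                     class = "partition_model")
  model$global_mode_id <- flag_global_mode(model)
  model
}

#' @export
print.partition_model <- function(x, ...) {
  cat("Partition model k =", x$k, "(", length(x$assignments), "volumes )\n")
  cat("  cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat("  global mode:",
      if (is.na(x$global_mode_id)) "none" else x$global_mode_id, "\n")
  invisible(x)
}

#' Sweep partition granularities
#'
#' Fits one [cluster_partition()] per `k` in `k_min:k_max`, each with an
#' independent seed substream of `seed`.
#'
#' @inheritParams cluster_partition
#' @param k_min,k_max inclusive granularity range (defaults 2 and 20).
#' @return named list of `partition_model`s (`"k2"`, `"k3"`, ...).
#' @export
sweep_partitions <- function(pool, k_min = 2L, k_max = 20L, seed = 1L,
                             replicates = 50L, max_iter = 500L) {
  if (k_min < 2) stop("k_min must be at least 2")
  if (k_max < k_min) stop("k_max must be >= k_min")
  ks <- k_min:k_max
  models <- lapply(ks, function(k)
    cluster_partition(pool, k, seed = substream_seed(seed, k),
                      replicates = replicates, max_iter = max_iter))
  names(models) <- paste0("k", ks)
  models
}

#' Identify the global mode of a partition
#'
#' The global mode is the cluster whose centroid has no strictly positive
#' element: under the sign convention all parcels share one phase community,
#' i.e. the whole cortex is approximately phase-aligned. If several clusters
#' qualify, the most occupied one is returned; `NA` if none qualifies.
#'
#' @param model a [partition_model].
#' @return cluster id or `NA`.
#' @export
flag_global_mode <- function(model) {
  stopifnot(inherits(model, "partition_model"))
  cand <- which(apply(model$centroids, 1, function(v) all(v <= 0)) &
                  model$sizes > 0)
  if (!length(cand)) return(NA_integer_)
  as.integer(cand[which.max(model$sizes[cand])])
}

#' Per-subject state time courses
#'
#' Reconstructs, from the pooled assignments and their provenance, each
#' scan's sequence of phase-locking states over its kept volumes.
#'
#' @param model a [partition_model].
#' @return named list (by subject id) of integer state sequences.
#' @export
state_timecourses <- function(model) {
  stopifnot(inherits(model, "partition_model"))
  prov <- model$provenance
  if (is.null(prov) || nrow(prov) != length(model$assignments))
    stop("partition model provenance is missing or inconsistent")
  subjects <- unique(prov$subject_id)
  out <- lapply(subjects, function(s) {
    rows <- which(prov$subject_id == s)
    model$assignments[rows[order(prov$volume[rows])]]
  })
  names(out) <- subjects
  out
}
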