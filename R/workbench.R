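#' Read a parcellated scan matrix from delimited text
#'
#' Accepts tab- or comma-delimited rectangular numeric tables (rows =
#' parcels, columns = volumes, no header); the delimiter is auto-detected
#' from the first line.
#'
#' @param path file path.
#' @param subject_id subject id; defaults to the file name without
#'   extension.
#' @param group,tr_seconds scan metadata.
#' @return a [parcellated_scan].
#' @export
read_scan_matrix <- function(path, subject_id = NULL, group = NA_character_,
                             tr_seconds = 3) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("scan file is empty: ", path)
  delim <- if (grepl("\t", lines[1])) "\t" else ","
  cells <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1)
    stop("ragged scan file ", path, ": row ",
         which(widths != widths[1])[1], " has ", widths[widths != widths[1]][1],
         " cells, expected ", widths[1])
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1] / widths[1])
    stop("non-numeric cell in scan file ", path, " at row ", bad_row)
  }
  m <- matrix(vals, nrow = length(lines), byrow = TRUE)
  parcellated_scan(m, subject_id = subject_id %||%
                     sub("\\.[^.]*$", "", basename(path)),
                   group = group, tr_seconds = tr_seconds)
}

#' Write a scan matrix as TSV
#'
#' @param scan a [parcellated_scan] or plain numeric matrix.
#' @param path output path.
#' @export
write_scan_matrix <- function(scan, path) {
  m <- if (inherits(scan, "parcellated_scan")) scan$matrix else scan
  write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
}

#' Read the subject metadata table
#'
#' Expects a delimited table with at least `subject_id` and `group`
#' columns; covariate columns (age, expertise, mysticism subscales) are
#' optional. Missing expertise entries for controls are allowed. If the
#' eight mysticism subscales are present but `hood_mean` is absent, it is
#' computed.
#'
#' @param path file path (TSV or CSV, with header).
#' @param groups optional character vector of allowed group labels.
#' @return metadata data frame.
#' @export
read_metadata_table <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  md <- read.table(path, header = TRUE, sep = delim,
                   stringsAsFactors = FALSE)
  for (col in c("subject_id", "group"))
    if (!col %in% names(md)) stop("metadata is missing column '", col, "'")
  if (anyDuplicated(md$subject_id))
    stop("duplicate subject ids in metadata: ",
         paste(md$subject_id[duplicated(md$subject_id)], collapse = ", "))
  if (!is.null(groups) && !all(md$group %in% groups))
    stop("unknown group label(s): ",
         paste(setdiff(md$group, groups), collapse = ", "))
  if (!"hood_mean" %in% names(md) && all(hood_subscales() %in% names(md)))
    md$hood_mean <- rowMeans(md[, hood_subscales()])
  md
}

#' Write a synthetic cohort to a directory
#'
#' One TSV matrix per scan (`<subject_id>.tsv`, parcels x volumes, no
#' header), `metadata.tsv`, and the ground truth as
#' `ground_truth_sequences.tsv` (subjects x volumes state ids) and
#' `ground_truth_occupancy.tsv`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (scan in cohort$scans)
    write_scan_matrix(scan, file.path(dir, paste0(scan$subject_id, ".tsv")))
  write.table(cohort$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  write.table(cbind(subject_id = rownames(gt$sequences), gt$sequences),
              file.path(dir, "ground_truth_sequences.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cbind(subject_id = rownames(gt$occupancy), gt$occupancy),
              file.path(dir, "ground_truth_occupancy.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Assemble a pipeline run configuration
#'
#' @param data_dir directory of scan TSVs plus `metadata.tsv`, or `NULL` to
#'   simulate from `simulation` instead.
#' @param simulation a [cohort_spec] used when `data_dir` is `NULL`.
#' @param k_min,k_max clustering granularity range.
#' @param permutations permutations per group test.
#' @param replicates k-means restarts per granularity.
#' @param alpha significance level.
#' @param cm_threshold centroid-correlation threshold for coupling modes.
#' @param tr_seconds repetition time of read scans.
#' @param seed master seed for all stochastic stages.
#' @return object of class `run_config`.
#' @export
run_config <- function(data_dir = NULL, simulation = NULL, k_min = 2L,
                       k_max = 20L, permutations = 10000L, replicates = 50L,
                       alpha = 0.05, cm_threshold = 0.8, tr_seconds = 3,
                       seed = 1L) {
  if (is.null(data_dir) && is.null(simulation))
    stop("either data_dir or simulation must be given")
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stop("data directory does not exist: ", data_dir)
  structure(list(data_dir = data_dir, simulation = simulation,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 permutations = as.integer(permutations),
                 replicates = as.integer(replicates), alpha = alpha,
                 cm_threshold = cm_threshold, tr_seconds = tr_seconds,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; a `simulation`
#' block with `n_parcels`, `n_volumes`, `group_sizes` (named map),
#' `switch_rate`, `noise_sd`, `oscillation_freq_hz`, `tr_seconds` and
#' `seed` builds a [cohort_spec] with the default state library.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    args <- list()
    for (nm in c("n_parcels", "n_volumes", "tr_seconds", "switch_rate",
                 "noise_sd", "oscillation_freq_hz", "seed"))
      if (!is.null(s[[nm]])) args[[nm]] <- s[[nm]]
    if (!is.null(s$group_sizes))
      args$group_sizes <- unlist(s$group_sizes)
    sim <- do.call(cohort_spec, args)
  }
  args <- list(data_dir = y$data_dir, simulation = sim)
  for (nm in c("k_min", "k_max", "permutations", "replicates", "alpha",
               "cm_threshold", "tr_seconds", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(run_config, args)
}

read_cohort_dir <- function(dir, tr_seconds) {
  md_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(md_path))
    stop_stage("metadata", "metadata.tsv not found in ", dir)
  metadata <- read_metadata_table(md_path)
  scans <- lapply(metadata$subject_id, function(sid) {
    p <- file.path(dir, paste0(sid, ".tsv"))
    if (!file.exists(p)) stop_stage("scans", "scan file missing for ", sid)
    read_scan_matrix(p, subject_id = sid,
                     group = metadata$group[metadata$subject_id == sid],
                     tr_seconds = tr_seconds)
  })
  list(scans = scans, metadata = metadata)
}

#' Run the full phase-locking state pipeline
#'
#' Chains all stages: load (or simulate) the cohort, extract leading
#' eigenvectors, sweep k-means partitions, compute occupancies, compare
#' groups, group significant states into coupling modes, and correlate
#' occupancies with covariates. Result tables are written as TSV plus a
#' JSON manifest recording seeds, thresholds and row counts; the same
#' config and seed reproduce every output.
#'
#' @param config a [run_config].
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[plstate] ", ...)
  t0 <- proc.time()[3]

  if (!is.null(config$data_dir)) {
    say("reading cohort from ", config$data_dir)
    cohort <- read_cohort_dir(config$data_dir, config$tr_seconds)
  } else {
    say("simulating cohort (seed ", config$simulation$seed, ")")
    cohort <- generate_cohort(config$simulation)
  }
  metadata <- cohort$metadata

  say("extracting leading eigenvectors from ", length(cohort$scans), " scans")
  series <- lapply(cohort$scans, eigenvector_series)
  pool <- pool_eigenvectors(series)

  say("clustering k = ", config$k_min, "..", config$k_max,
      " (", config$replicates, " replicates)")
  models <- sweep_partitions(pool, config$k_min, config$k_max,
                             seed = substream_seed(config$seed, 1),
                             replicates = config$replicates)
  occ <- occurrence_tables(models)

  say("group comparison (", config$permutations, " permutations per state)")
  comparisons <- compare_groups(occ, metadata, M = config$permutations,
                                seed = substream_seed(config$seed, 2),
                                alpha = config$alpha)

  sig <- comparisons[comparisons$tier != "ns", , drop = FALSE]
  cm <- NULL
  if (nrow(sig)) {
    cents <- t(vapply(seq_len(nrow(sig)), function(i) {
      m <- models[[paste0("k", sig$k[i])]]
      m$centroids[sig$cluster[i], ]
    }, numeric(ncol(pool$matrix))))
    cm <- group_coupling_modes(sig, cents, threshold = config$cm_threshold)
    say("coupling modes: ", length(cm$modes), " mode(s), ",
        nrow(cm$partition_specific), " partition-specific state(s)")
  } else say("no significant states; skipping coupling modes")

  say("covariate correlations")
  covars <- withCallingHandlers(
    covariate_scan(occ, metadata, alpha = config$alpha),
    warning = function(w) { say("  ", conditionMessage(w))
      invokeRestart("muffleWarning") })

  # ---- write outputs ----
  for (nm in names(models)) {
    m <- models[[nm]]
    write.table(format(m$centroids, digits = 17, trim = TRUE),
                file.path(out_dir, paste0("centroids_", nm, ".tsv")),
                sep = "\t", quote = FALSE, col.names = FALSE)
    write.table(cbind(rownames(occ[[nm]]), format(occ[[nm]], digits = 10)),
                file.path(out_dir, paste0("occupancy_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = c("subject_id", colnames(occ[[nm]])))
  }
  assignments <- cbind(pool$provenance,
                       do.call(cbind, lapply(models, `[[`, "assignments")))
  names(assignments)[-(1:3)] <- names(models)
  write.table(assignments, file.path(out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary_df <- data.frame(
    k = vapply(models, `[[`, integer(1), "k"),
    inertia = vapply(models, `[[`, numeric(1), "inertia"),
    global_mode = vapply(models, `[[`, integer(1), "global_mode_id"),
    degenerate = vapply(models, `[[`, logical(1), "degenerate"))
  write.table(summary_df, file.path(out_dir, "partition_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(comparisons, file.path(out_dir, "group_comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cm)) {
    cm_rows <- do.call(rbind, lapply(cm$modes, function(m)
      cbind(mode = m$id, m$members)))
    if (!is.null(cm_rows))
      write.table(cm_rows, file.path(out_dir, "coupling_modes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(cm$partition_specific))
      write.table(cm$partition_specific,
                  file.path(out_dir, "partition_specific.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(covars, file.path(out_dir, "covariates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("plstate")),
    seed = config$seed, k_min = config$k_min, k_max = config$k_max,
    permutations = config$permutations, replicates = config$replicates,
    alpha = config$alpha, cm_threshold = config$cm_threshold,
    n_scans = length(cohort$scans),
    n_parcels = ncol(pool$matrix),
    pooled_eigenvectors = nrow(pool$matrix),
    n_comparisons = nrow(comparisons),
    n_coupling_modes = if (is.null(cm)) 0L else length(cm$modes),
    n_covariate_rows = if (is.null(covars)) 0L else nrow(covars),
    elapsed_seconds = unname(proc.time()[3] - t0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done in ", round(manifest$elapsed_seconds, 1), " s")

  invisible(list(cohort = cohort, pool = pool, models = models, occ = occ,
                 comparisons = comparisons, coupling_modes = cm,
                 covariates = covars, manifest = manifest))
}
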