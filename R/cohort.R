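#' Define a planted phase-locking state
#'
#' A planted state is described by the subset of parcels (the minority
#' community) that oscillates in anti-phase with the rest of the cortex. An
#' all-`FALSE` community describes a global state in which every parcel is in
#' phase.
#'
#' @param id integer state id (unique within a library).
#' @param community logical vector of length `n_parcels`; `TRUE` marks the
#'   minority (anti-phase) community.
#' @param label human-readable state name.
#' @return an object of class `planted_state`.
#' @export
planted_state <- function(id, community, label = paste0("state", id)) {
  stopifnot(is.logical(community), !anyNA(community))
  n <- length(community)
  m <- sum(community)
  if (m > 0 && m >= n / 2)
    stop("minority community of state ", id, " must contain fewer than half ",
         "of the parcels (got ", m, " of ", n, ")")
  structure(list(id = as.integer(id), community = community,
                 label = as.character(label)),
            class = "planted_state")
}

#' Default planted-state library
#'
#' Four states over `n_parcels` parcels emulating the qualitative repertoire
#' reported in resting-state phase-locking analyses: a dominant global mode
#' (all parcels in phase) plus three two-community states whose minority
#' communities are disjoint contiguous parcel blocks (posterior-sensory-like,
#' visual-like, and frontal-like, spanning 1/6, 1/12 and 1/6 of the cortex).
#'
#' @param n_parcels number of parcels.
#' @return list of [planted_state] objects.
#' @export
default_state_library <- function(n_parcels = 360) {
  stopifnot(n_parcels >= 24)
  blk <- function(idx) { z <- rep(FALSE, n_parcels); z[idx] <- TRUE; z }
  b1 <- seq_len(floor(n_parcels / 6))
  b2 <- max(b1) + seq_len(floor(n_parcels / 12))
  b3 <- max(b2) + seq_len(floor(n_parcels / 6))
  list(planted_state(1L, rep(FALSE, n_parcels), "global"),
       planted_state(2L, blk(b1), "posterior_sensory"),
       planted_state(3L, blk(b2), "visual"),
       planted_state(4L, blk(b3), "frontal"))
}

default_covariate_links <- function() {
  data.frame(covariate = c("age", "hood_unifying"),
             state_id  = c(1L, 2L),
             slope     = c(-80, 8),
             noise_sd  = c(6, 0.5),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. Defaults emulate
#' the study design the pipeline targets: 36 nine-minute scans (19 controls,
#' 17 meditators) of 360 cortical parcels at TR = 3 s (180 volumes), a shared
#' 0.05 Hz oscillation, a four-state library dominated by a global mode, and
#' a group occupancy difference on the posterior-sensory-like state.
#'
#' @param n_parcels,n_volumes scan dimensions (parcels x volumes).
#' @param tr_seconds repetition time in seconds.
#' @param group_sizes named integer vector of scans per group (>= 2 each).
#' @param state_library list of [planted_state] objects sharing `n_parcels`.
#' @param occupancy_by_group named list (one entry per group) of stationary
#'   occupancy distributions over the state library; each must sum to 1.
#' @param switch_rate per-volume probability of redrawing the active state
#'   from the group's occupancy distribution (the redraw may land on the
#'   current state, so the effective transition rate is lower).
#' @param oscillation_freq_hz shared carrier frequency of all parcels, Hz.
#' @param noise_sd standard deviation of additive Gaussian noise, in units of
#'   the unit-amplitude oscillation.
#' @param covariate_links data frame with columns `covariate`, `state_id`,
#'   `slope`, `noise_sd`: each row makes that subject covariate a linear
#'   function of the subject's true occupancy of the linked state plus
#'   Gaussian noise.
#' @param seed master integer seed; every random draw in the generator is
#'   taken from a substream derived from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_parcels = 360, n_volumes = 180, tr_seconds = 3,
                        group_sizes = c(control = 19L, meditator = 17L),
                        state_library = default_state_library(n_parcels),
                        occupancy_by_group = list(
                          control   = c(0.40, 0.15, 0.20, 0.25),
                          meditator = c(0.40, 0.27, 0.20, 0.13)),
                        switch_rate = 0.15,
                        oscillation_freq_hz = 0.05,
                        noise_sd = 0.2,
                        covariate_links = default_covariate_links(),
                        seed = 1L) {
  if (n_volumes < 4) stop("n_volumes must be >= 4")
  if (switch_rate < 0 || switch_rate > 1) stop("switch_rate must lie in [0, 1]")
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector")
  if (any(group_sizes < 2)) stop("every group needs at least 2 scans")
  for (st in state_library) {
    if (!inherits(st, "planted_state")) stop("state_library entries must be planted_state objects")
    if (length(st$community) != n_parcels)
      stop("state ", st$id, " community length does not match n_parcels")
  }
  ids <- vapply(state_library, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("duplicate state ids in library")
  if (!setequal(names(occupancy_by_group), names(group_sizes)))
    stop("occupancy_by_group names must match group_sizes names")
  for (g in names(occupancy_by_group)) {
    occ <- occupancy_by_group[[g]]
    if (length(occ) != length(state_library))
      stop("occupancy vector for group '", g, "' has wrong length")
    if (any(occ < 0) || abs(sum(occ) - 1) > 1e-9)
      stop("occupancy vector for group '", g, "' is not a probability simplex")
  }
  structure(list(n_parcels = as.integer(n_parcels),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 group_sizes = group_sizes,
                 state_library = state_library,
                 occupancy_by_group = occupancy_by_group,
                 switch_rate = switch_rate,
                 oscillation_freq_hz = oscillation_freq_hz,
                 noise_sd = noise_sd,
                 covariate_links = covariate_links,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", sum(x$group_sizes), "scans (",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      "), ", x$n_parcels, "parcels x", x$n_volumes, "volumes, TR",
      x$tr_seconds, "s\n")
  cat(" ", length(x$state_library), "planted states; switch_rate",
      x$switch_rate, "; noise_sd", x$noise_sd, "; seed", x$seed, "\n")
  invisible(x)
}

#' Sample a planted state sequence for one scan
#'
#' Markov switching: the scan starts in a state drawn from the group's
#' occupancy distribution; at each subsequent volume it stays put with
#' probability `1 - switch_rate`, otherwise the state is redrawn from the
#' occupancy distribution (independently of the current state), which makes
#' that distribution the chain's stationary law.
#'
#' @param spec a [cohort_spec].
#' @param group group name or index into `spec$group_sizes`.
#' @param seed integer seed for this draw.
#' @return integer vector of state ids, length `spec$n_volumes`.
#' @export
sample_state_sequence <- function(spec, group, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  gname <- if (is.character(group)) group else names(spec$group_sizes)[group]
  occ <- spec$occupancy_by_group[[gname]]
  if (is.null(occ)) stop("unknown group: ", group)
  if (any(occ < 0) || abs(sum(occ) - 1) > 1e-9)
    stop("occupancy distribution for group '", gname, "' is not a valid simplex")
  ids <- vapply(spec$state_library, `[[`, integer(1), "id")
  with_seed(seed, {
    n <- spec$n_volumes
    out <- integer(n)
    cur <- sample(ids, 1, prob = occ)
    out[1] <- cur
    if (n > 1) {
      sw <- runif(n - 1) < spec$switch_rate
      for (t in 2:n) {
        if (sw[t - 1]) cur <- sample(ids, 1, prob = occ)
        out[t] <- cur
      }
    }
    out
  })
}

#' Synthesize one parcellated scan from a planted state sequence
#'
#' Every parcel carries the shared oscillation
#' `x_n(t) = cos(2*pi*f*t*TR + phi_n(t)) + noise`, where `phi_n(t)` is `pi`
#' when parcel `n` belongs to the minority community of the state active at
#' volume `t` and `0` otherwise. With `noise_sd = 0`, parcels within a
#' community are exactly in phase and the two communities are in exact
#' anti-phase at every volume.
#'
#' @param spec a [cohort_spec].
#' @param sequence integer state-id sequence of length `spec$n_volumes`.
#' @param seed integer seed for the noise draw.
#' @param subject_id,group metadata attached to the resulting scan.
#' @return a [parcellated_scan].
#' @export
synthesize_scan <- function(spec, sequence, seed, subject_id = "scan",
                            group = NA_character_) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(sequence) != spec$n_volumes)
    stop("sequence length ", length(sequence), " does not match n_volumes ",
         spec$n_volumes)
  ids <- vapply(spec$state_library, `[[`, integer(1), "id")
  pos <- match(sequence, ids)
  if (anyNA(pos)) stop("sequence contains state ids absent from the library")
  N <- spec$n_parcels; T <- spec$n_volumes
  carrier <- 2 * pi * spec$oscillation_freq_hz * spec$tr_seconds * (seq_len(T) - 1)
  comm <- vapply(spec$state_library, `[[`, logical(N), "community")  # N x nstates
  phase_offset <- ifelse(comm[, pos, drop = FALSE], pi, 0)           # N x T
  x <- cos(sweep(phase_offset, 2, carrier, `+`))
  if (spec$noise_sd > 0)
    x <- x + with_seed(seed, matrix(rnorm(N * T, sd = spec$noise_sd), N, T))
  parcellated_scan(x, subject_id = subject_id, group = group,
                   tr_seconds = spec$tr_seconds)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws one state sequence and one scan per subject, builds the subject
#' metadata table (age, meditation expertise for meditators, eight mysticism
#' subscale scores and their mean), and records exact ground truth: each
#' scan's planted sequence and its occupancy (the normalized state histogram
#' of the sequence). Covariates listed in `spec$covariate_links` are linear
#' in the subject's true occupancy of the linked state plus Gaussian noise;
#' all other covariates are pure noise around a plausible baseline. All
#' randomness comes from per-subject substreams of `spec$seed`, so cohorts
#' are bitwise reproducible.
#'
#' @param spec a [cohort_spec].
#' @return list with elements `scans` (list of [parcellated_scan]),
#'   `metadata` (data frame), and `ground_truth` (list with `sequences`
#'   matrix, `occupancy` matrix, `state_ids`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  nsub <- length(groups)
  ids <- vapply(spec$state_library, `[[`, integer(1), "id")
  subject_ids <- sprintf("S%02d", seq_len(nsub))

  sequences <- matrix(NA_integer_, nsub, spec$n_volumes,
                      dimnames = list(subject_ids, NULL))
  occupancy <- matrix(NA_real_, nsub, length(ids),
                      dimnames = list(subject_ids, paste0("state", ids)))
  scans <- vector("list", nsub)
  for (i in seq_len(nsub)) {
    scan_seed <- substream_seed(spec$seed, i)
    sq <- sample_state_sequence(spec, groups[i], substream_seed(scan_seed, 1))
    sequences[i, ] <- sq
    occupancy[i, ] <- tabulate(match(sq, ids), length(ids)) / spec$n_volumes
    scans[[i]] <- synthesize_scan(spec, sq, substream_seed(scan_seed, 2),
                                  subject_id = subject_ids[i], group = groups[i])
  }
  metadata <- build_metadata(spec, subject_ids, groups, occupancy, ids)
  list(scans = scans, metadata = metadata,
       ground_truth = list(sequences = sequences, occupancy = occupancy,
                           state_ids = ids))
}

hood_subscales <- function() {
  c("hood_ego", "hood_unifying", "hood_inner_subjective",
    "hood_temporal_spatial", "hood_noetic", "hood_ineffability",
    "hood_positive_affect", "hood_religious")
}

# Covariate baselines: target centre and default (unlinked) noise SD.
covariate_baseline <- function(name) {
  if (name == "age") return(c(centre = 41, sd = 10))
  if (name == "expertise_years") return(c(centre = 15, sd = 5))
  c(centre = 2.5, sd = 0.8)  # mysticism subscales, 0-5 scale
}

build_metadata <- function(spec, subject_ids, groups, occupancy, state_ids) {
  nsub <- length(subject_ids)
  md <- data.frame(subject_id = subject_ids, group = groups,
                   stringsAsFactors = FALSE)
  links <- spec$covariate_links
  # Expected occupancy of each state (size-weighted over groups) centres the
  # linked covariates so baselines stay at their target values.
  w <- spec$group_sizes / sum(spec$group_sizes)
  exp_occ <- Reduce(`+`, Map(function(g, wt) wt * spec$occupancy_by_group[[g]],
                             names(w), w))
  names(exp_occ) <- paste0("state", state_ids)

  draw <- function(name, idx) {
    seed <- substream_seed(spec$seed, 100000 + idx)
    base <- covariate_baseline(name)
    link <- if (is.null(links) || !nrow(links))
      data.frame(covariate = character(), state_id = integer(),
                 slope = numeric(), noise_sd = numeric())
    else links[links$covariate == name, , drop = FALSE]
    with_seed(seed, {
      if (nrow(link) == 1) {
        col <- paste0("state", link$state_id)
        if (!col %in% colnames(occupancy)) stop("covariate link to unknown state id ", link$state_id)
        base[["centre"]] + link$slope * (occupancy[, col] - exp_occ[[col]]) +
          rnorm(nsub, 0, link$noise_sd)
      } else {
        rnorm(nsub, base[["centre"]], base[["sd"]])
      }
    })
  }

  md$age <- round(pmax(draw("age", 1), 20), 1)
  yrs <- pmax(draw("expertise_years", 2), 1)
  hrs <- with_seed(substream_seed(spec$seed, 100003),
                   round(yrs * 550 * exp(rnorm(nsub, 0, 0.4))))
  # expertise is defined only for the meditator-like group (missing-coded
  # otherwise); for generic group names the second group takes that role
  med_group <- if (any(grepl("^medit", names(spec$group_sizes))))
    grep("^medit", names(spec$group_sizes), value = TRUE)[1]
  else names(spec$group_sizes)[2]
  is_med <- groups == med_group
  md$expertise_years <- ifelse(is_med, round(yrs, 1), NA_real_)
  md$expertise_hours <- ifelse(is_med, hrs, NA_real_)
  for (j in seq_along(hood_subscales())) {
    nm <- hood_subscales()[j]
    md[[nm]] <- round(pmin(pmax(draw(nm, 10 + j), 0), 5), 2)
  }
  md$hood_mean <- rowMeans(md[, hood_subscales()])
  md
}
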