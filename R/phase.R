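#' Construct a parcellated scan
#'
#' The pipeline's raw input: one subject's parcels-by-volumes BOLD matrix
#' plus scan metadata.
#'
#' @param matrix numeric N x T matrix (rows = parcels, columns = volumes),
#'   N >= 2, T >= 4, no missing values.
#' @param subject_id subject identifier.
#' @param group group label (may be `NA`).
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `parcellated_scan`.
#' @export
parcellated_scan <- function(matrix, subject_id, group = NA_character_,
                             tr_seconds = 3) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("scan data must be a numeric matrix")
  if (anyNA(matrix)) stop("scan matrix contains missing values")
  if (nrow(matrix) < 2) stop("a scan needs at least 2 parcels")
  if (ncol(matrix) < 4) stop("a scan needs at least 4 volumes")
  structure(list(matrix = matrix, subject_id = as.character(subject_id),
                 group = group, tr_seconds = tr_seconds,
                 n_parcels = nrow(matrix), n_volumes = ncol(matrix)),
            class = "parcellated_scan")
}

#' @export
print.parcellated_scan <- function(x, ...) {
  cat("Parcellated scan", x$subject_id,
      if (!is.na(x$group)) paste0("(", x$group, ")") else "",
      ":", x$n_parcels, "parcels x", x$n_volumes, "volumes, TR",
      x$tr_seconds, "s\n")
  invisible(x)
}

# FFT-based analytic signal of one real series (positive-frequency doubling).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Extract instantaneous phases and amplitudes
#'
#' Demeans each parcel's series, computes its analytic signal over the full
#' scan, and keeps the instantaneous phase and amplitude of volumes
#' `2 ... T-1`; the first and last volumes are excluded because the analytic
#' signal is distorted at the series edges.
#'
#' @param scan a [parcellated_scan].
#' @return an object of class `phase_series` with fields `theta` (N x T-2
#'   radians in (-pi, pi]), `amplitude` (N x T-2), `kept_volumes` (original
#'   1-based volume indices), `subject_id`, `group`, `tr_seconds`.
#' @export
extract_phases <- function(scan) {
  stopifnot(inherits(scan, "parcellated_scan"))
  x <- scan$matrix
  centred <- x - rowMeans(x)
  flat <- which(apply(centred, 1, function(r) all(abs(r) < 1e-300)))
  if (length(flat))
    stop("constant signal in parcel(s) ", paste(flat, collapse = ", "),
         ": instantaneous phase is undefined")
  a <- t(apply(centred, 1, analytic_signal))
  keep <- 2:(scan$n_volumes - 1)
  structure(list(theta = Arg(a[, keep, drop = FALSE]),
                 amplitude = Mod(a[, keep, drop = FALSE]),
                 kept_volumes = keep,
                 subject_id = scan$subject_id, group = scan$group,
                 tr_seconds = scan$tr_seconds),
            class = "phase_series")
}

#' Dynamic phase-coherence matrix at one volume
#'
#' The cosine similarity of instantaneous phases:
#' `dPC[n, p] = cos(theta_n - theta_p)`. Entries are 1 for identical phases,
#' -1 for a half-cycle (180 degree) difference, and 0 for quadrature.
#'
#' @param phases a [phase_series] from [extract_phases()].
#' @param t index into the kept volumes (1 ... T-2).
#' @return symmetric N x N matrix with unit diagonal, entries in `[-1, 1]`.
#' @export
dpc_matrix <- function(phases, t) {
  stopifnot(inherits(phases, "phase_series"))
  Tp <- ncol(phases$theta)
  if (!is.numeric(t) || length(t) != 1 || t < 1 || t > Tp)
    stop("volume index ", t, " outside kept range 1..", Tp)
  th <- phases$theta[, t]
  m <- cos(outer(th, th, `-`))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Flip a vector so the strictly positive community is never the larger one;
# zeros are neutral. Exact ties on counts are broken by a non-positive sum.
canonicalize_sign <- function(v) {
  npos <- sum(v > 0); nneg <- sum(v < 0)
  if (npos > nneg || (npos == nneg && sum(v) > 0)) v <- -v
  v
}

#' Leading eigenvector of a phase-coherence matrix
#'
#' Extracts the unit-norm eigenvector of the algebraically largest eigenvalue
#' and applies the community sign convention: the sign is chosen so the
#' strictly positive community (the minority, anti-phase set) is never larger
#' than the negative one; an exact tie on counts is broken by making the
#' element sum non-positive. A leading-eigenvalue gap below `1e-8` marks the
#' decomposition degenerate; the deterministic LAPACK basis is then used
#' as the tie-break and the result is flagged.
#'
#' @param m symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return object of class `signed_eigenvector`: `v1`, `eigenvalue`,
#'   `n_positive`, `degenerate`.
#' @export
leading_eigenvector <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || !is.numeric(m)) stop("input must be a numeric matrix")
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol)
    stop("input matrix is not symmetric")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- canonicalize_sign(e$vectors[, 1])
  v <- v / sqrt(sum(v^2))
  degen <- length(e$values) > 1 && (e$values[1] - e$values[2]) < 1e-8
  structure(list(v1 = v, eigenvalue = e$values[1],
                 n_positive = sum(v > 0), degenerate = degen),
            class = "signed_eigenvector")
}

# Leading eigenvectors of all dPC matrices of one phase series, using the
# exact rank-2 structure dPC = c c' + s s' (c = cos theta, s = sin theta):
# the leading eigenvector lies in span{c, s} and solves the 2x2 Gram
# eigenproblem, so no N x N decomposition is needed.
leading_eigenvectors_rank2 <- function(theta) {
  N <- nrow(theta); Tp <- ncol(theta)
  C <- cos(theta); S <- sin(theta)
  V <- matrix(NA_real_, Tp, N)
  lambda <- numeric(Tp)
  degenerate <- logical(Tp)
  for (t in seq_len(Tp)) {
    c1 <- C[, t]; s1 <- S[, t]
    a <- sum(c1 * c1); b <- sum(c1 * s1); d <- sum(s1 * s1)
    disc <- sqrt(((a - d) / 2)^2 + b^2)
    lam <- (a + d) / 2 + disc
    degenerate[t] <- 2 * disc < 1e-8
    # eigenvector of [[a, b], [b, d]] for lam; pick the numerically larger
    # component formulation, fall back to the dominant axis when b ~ 0
    if (abs(b) < 1e-300) {
      w <- if (a >= d) c(1, 0) else c(0, 1)
    } else if (abs(lam - d) >= abs(lam - a)) {
      w <- c(lam - d, b)
    } else {
      w <- c(b, lam - a)
    }
    v <- c1 * w[1] + s1 * w[2]
    nv <- sqrt(sum(v^2))
    if (nv == 0) { v <- c1; nv <- sqrt(sum(v^2)) }  # fully degenerate input
    v <- canonicalize_sign(v / nv)
    V[t, ] <- v
    lambda[t] <- lam
  }
  list(vectors = V, eigenvalues = lambda, degenerate = degenerate)
}

#' Leading-eigenvector series of one scan
#'
#' Runs [extract_phases()] and computes the sign-canonicalized leading
#' eigenvector of the phase-coherence matrix at every kept volume. Because
#' each dPC matrix equals `cos(theta) cos(theta)' + sin(theta) sin(theta)'`
#' it has rank at most two, and the leading eigenvector is computed exactly
#' from the 2 x 2 Gram eigenproblem of that basis (equal, to numerical
#' precision, to a full eigendecomposition of the N x N matrix).
#'
#' @param scan a [parcellated_scan].
#' @return object of class `eigenvector_series`: `vectors` (T-2 x N matrix,
#'   one unit-norm row per kept volume), `eigenvalues`, `degenerate` flags,
#'   `kept_volumes`, `subject_id`, `group`.
#' @export
eigenvector_series <- function(scan) {
  phases <- extract_phases(scan)
  r <- leading_eigenvectors_rank2(phases$theta)
  if (any(r$degenerate))
    message("scan ", scan$subject_id, ": degenerate leading eigenvalue at ",
            sum(r$degenerate), " volume(s); deterministic tie-break applied")
  structure(list(vectors = r$vectors, eigenvalues = r$eigenvalues,
                 degenerate = r$degenerate,
                 kept_volumes = phases$kept_volumes,
                 subject_id = scan$subject_id, group = scan$group),
            class = "eigenvector_series")
}
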