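# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Leading eigenvector by plain power iteration (with a shift so the
# algebraically largest eigenvalue dominates even when negative eigenvalues
# are larger in magnitude).
power_iteration_leading <- function(m, iters = 200000, tol = 1e-11) {
  n <- nrow(m)
  shift <- max(rowSums(abs(m)))  # Gershgorin bound: m + shift*I is PSD
  ms <- m + diag(shift, n)
  set.seed(4242)
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  for (i in seq_len(iters)) {
    w <- as.numeric(ms %*% v)
    w <- w / sqrt(sum(w^2))
    v <- w
    if (i %% 25 == 0) {
      theta <- as.numeric(t(v) %*% ms %*% v)
      if (sqrt(sum((ms %*% v - theta * v)^2)) < tol * abs(theta)) break
    }
  }
  list(vector = v, value = as.numeric(t(v) %*% m %*% v))
}

# Holm step-down adjustment written directly from the formula.
holm_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[o[i]]))
    adj[o[i]] <- running
  }
  adj
}

# Pooled-variance two-sample t statistic, written independently.
t_stat_hand <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Exhaustive-enumeration permutation p-value for the two-sided t test.
perm_p_enumerated <- function(a, b) {
  y <- c(a, b); n1 <- length(a)
  splits <- combn(length(y), n1)
  tobs <- abs(t_stat_hand(a, b))
  tall <- apply(splits, 2, function(ix) {
    t <- t_stat_hand(y[ix], y[-ix])
    if (is.na(t)) Inf else abs(t)
  })
  sum(tall >= tobs * (1 - 1e-12)) / ncol(splits)
}

# Best one-to-one matching of cluster labels to planted states (k small:
# exhaustive over permutations), returning per-state Jaccard indices.
jaccard_by_state <- function(assigned, truth, k) {
  perms <- combinat_perms(k)
  agree <- apply(perms, 1, function(p) mean(p[assigned] == truth))
  p <- perms[which.max(agree), ]
  mapped <- p[assigned]
  vapply(seq_len(k), function(s) {
    a <- mapped == s; b <- truth == s
    sum(a & b) / sum(a | b)
  }, numeric(1))
}

combinat_perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

normalize_rows_fixture <- function(x) x / sqrt(rowSums(x^2))

# Build a phase_series object directly from a phase matrix (radians).
phase_series_from_theta <- function(theta) {
  structure(list(theta = theta, amplitude = matrix(1, nrow(theta), ncol(theta)),
                 kept_volumes = seq_len(ncol(theta)) + 1,
                 subject_id = "fixture", group = NA_character_, tr_seconds = 3),
            class = "phase_series")
}

# Build a pooled_eigenvectors object from a row matrix.
pool_from_matrix <- function(x, subject_id = "fixture") {
  structure(list(matrix = x,
                 provenance = data.frame(subject_id = subject_id,
                                         group = NA_character_,
                                         volume = seq_len(nrow(x)))),
            class = "pooled_eigenvectors")
}

# State library of disjoint contiguous minority communities (0 size = global).
disjoint_library <- function(n_parcels, sizes) {
  stopifnot(sum(sizes) <= n_parcels / 2 + max(sizes))
  out <- vector("list", length(sizes))
  at <- 0
  for (i in seq_along(sizes)) {
    comm <- rep(FALSE, n_parcels)
    if (sizes[i] > 0) { comm[at + seq_len(sizes[i])] <- TRUE; at <- at + sizes[i] }
    out[[i]] <- planted_state(i, comm, paste0("fixture", i))
  }
  out
}

# The exact leading eigenvector a planted two-community state produces
# (sign-canonicalized: minority positive).
planted_eigenvector <- function(state) {
  n <- length(state$community)
  v <- rep(-1, n)
  v[state$community] <- 1
  v / sqrt(n)
}
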