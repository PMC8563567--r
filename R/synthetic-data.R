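# Markov-switching multivariate Gaussian cohort simulator.
#
# Each subject follows a hidden state sequence (first-order Markov chain at
# TR resolution); at every volume the N-vector of network signals is drawn
# from a zero-mean Gaussian with the active state's covariance, plus i.i.d.
# observation noise. Group effects enter through per-group overrides of the
# transition matrix and/or state covariances. An oscillatory variant with
# state-dependent phase coupling provides ground truth for the
# phase-coherence (LEiDA) pathway.

#' Block-structured example state covariances
#'
#' K correlation matrices over N networks emulating recurring connectivity
#' regimes: state 1 is globally sparse (identity), and each further state
#' couples a different block of networks strongly (within-block correlation
#' `r`) while anticorrelating that block with the remaining networks
#' (`r_cross`), the kind of segregated-system pattern dynamic-connectivity
#' states typically show. Matrices are clipped to the nearest valid
#' correlation matrix if the raw construction is not positive-definite.
#'
#' @param n_networks number of networks N.
#' @param n_states number of planted states K (default 3).
#' @param r within-block correlation (default 0.7).
#' @param r_cross block-to-rest correlation (default -0.25).
#' @return list of K symmetric positive-definite N x N matrices.
#' @export
default_state_covariances <- function(n_networks, n_states = 3, r = 0.7,
                                      r_cross = -0.25) {
  n_blocks <- max(1, n_states - 1)
  blocks <- split(seq_len(n_networks),
                  cut(seq_len(n_networks), n_blocks, labels = FALSE))
  lapply(seq_len(n_states), function(s) {
    m <- diag(n_networks)
    if (s > 1) {                      # state 1 stays globally sparse
      b <- blocks[[s - 1]]
      m[b, b] <- r
      m[b, -b] <- r_cross
      m[-b, b] <- r_cross
      diag(m) <- 1
      ev <- eigen(m, symmetric = TRUE)
      if (min(ev$values) < 1e-6) {    # clip to the nearest PD correlation
        vals <- pmax(ev$values, 1e-3)
        m <- ev$vectors %*% (vals * t(ev$vectors))
        m <- stats::cov2cor(m)
      }
    }
    m
  })
}

#' Specification of a synthetic cohort
#'
#' @param n_subjects_per_group subjects per group (recycled over `groups`).
#' @param n_networks number of networks N.
#' @param n_volumes volumes T per subject (default 290).
#' @param tr_seconds repetition time in seconds (default 2.072).
#' @param state_covariances list of K symmetric positive-definite N x N
#'   matrices, one per planted state (default [default_state_covariances()]).
#' @param transition_matrix row-stochastic K x K per-volume state-switch
#'   matrix (default: stay-probability 0.9, uniform switching).
#' @param observation_noise_sd SD of i.i.d. Gaussian noise added after the
#'   state draw (default 0.5).
#' @param groups group names (default HC, MCI-AD, MCI-LB).
#' @param group_effects optional named list (by group) of overrides, each a
#'   list with elements `transition_matrix` and/or `state_covariances`.
#' @param age_range ages are drawn uniformly from this range (default 65-85).
#' @param seed integer seed controlling the whole cohort.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects_per_group = 10,
                           n_networks = 10,
                           n_volumes = 290,
                           tr_seconds = 2.072,
                           state_covariances = NULL,
                           transition_matrix = NULL,
                           observation_noise_sd = 0.5,
                           groups = c("HC", "MCI-AD", "MCI-LB"),
                           group_effects = NULL,
                           age_range = c(65, 85),
                           seed = 1) {
  check_scalar(n_networks, "n_networks", positive = TRUE, integer = TRUE)
  check_scalar(n_volumes, "n_volumes", positive = TRUE, integer = TRUE)
  check_scalar(tr_seconds, "tr_seconds", positive = TRUE)
  if (observation_noise_sd < 0) stopf("observation_noise_sd must be >= 0")
  if (length(groups) < 1) stopf("need at least one group")
  if (is.null(state_covariances))
    state_covariances <- default_state_covariances(n_networks)
  for (m in state_covariances) check_spd(m, "state covariance")
  if (any(vapply(state_covariances, nrow, 1L) != n_networks))
    stopf("every state covariance must be %d x %d", n_networks, n_networks)
  K <- length(state_covariances)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(0.05 / max(1, K - 1), K, K)
    diag(transition_matrix) <- if (K > 1) 0.95 else 1
  }
  validate_transition_matrix(transition_matrix)
  if (nrow(transition_matrix) != K)
    stopf("transition matrix is %d x %d but there are %d states",
          nrow(transition_matrix), ncol(transition_matrix), K)
  n_per <- rep_len(as.integer(n_subjects_per_group), length(groups))
  if (!is.null(group_effects)) {
    bad <- setdiff(names(group_effects), groups)
    if (length(bad)) stopf("group_effects for unknown group(s): %s",
                           paste(bad, collapse = ", "))
  }
  structure(list(n_subjects_per_group = n_per, n_networks = n_networks,
                 n_volumes = n_volumes, tr_seconds = tr_seconds,
                 state_covariances = state_covariances,
                 transition_matrix = transition_matrix,
                 observation_noise_sd = observation_noise_sd,
                 groups = groups, group_effects = group_effects,
                 age_range = age_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

validate_transition_matrix <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stopf("transition matrix must be square")
  if (any(P < 0)) stopf("transition probabilities must be nonnegative")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    stopf("transition-matrix rows must sum to 1 (max deviation %g)",
          max(abs(rs - 1)))
  invisible(P)
}

stationary_distribution <- function(P) {
  K <- nrow(P)
  if (K == 1) return(1)
  # Cesaro-averaged power iteration from the uniform distribution; handles
  # periodic and reducible chains (e.g. the identity matrix) gracefully
  p <- rep(1 / K, K)
  acc <- numeric(K)
  for (i in 1:512) {
    p <- as.vector(p %*% P)
    if (i > 12) acc <- acc + p
  }
  acc / sum(acc)
}

#' Simulate a Markov state sequence
#'
#' First-order Markov chain at volume (TR) resolution; the initial state is
#' drawn from the chain's stationary distribution. Dwell times per state are
#' geometric with mean 1/(1 - stay-probability).
#'
#' @param transition_matrix row-stochastic K x K matrix.
#' @param n_volumes sequence length.
#' @param seed integer seed.
#' @return integer vector of states in 1..K.
#' @export
generate_state_sequence <- function(transition_matrix, n_volumes, seed) {
  validate_transition_matrix(transition_matrix)
  check_scalar(n_volumes, "n_volumes", positive = TRUE, integer = TRUE)
  K <- nrow(transition_matrix)
  set.seed(seed)
  s <- integer(n_volumes)
  s[1] <- sample.int(K, 1, prob = stationary_distribution(transition_matrix))
  if (n_volumes > 1)
    for (t in 2:n_volumes)
      s[t] <- sample.int(K, 1, prob = transition_matrix[s[t - 1], ])
  s
}

#' Simulate one subject's network time courses
#'
#' At each volume, draws the N-vector from a zero-mean multivariate Gaussian
#' with the active state's covariance, then adds independent Gaussian
#' observation noise.
#'
#' @param state_sequence integer state per volume (1..K).
#' @param spec a `synthetic_spec` (its covariances, noise SD and TR are used).
#' @param seed integer seed.
#' @param subject_id identifier for the returned object.
#' @return a `network_timecourses` object (T x N).
#' @export
generate_subject_timecourses <- function(state_sequence, spec, seed,
                                         subject_id = "sim") {
  covs <- spec$state_covariances
  if (length(state_sequence) &&
      (min(state_sequence) < 1 || max(state_sequence) > length(covs)))
    stopf("state sequence refers to state %d but only %d covariances given",
          max(state_sequence), length(covs))
  T <- length(state_sequence)
  N <- spec$n_networks
  set.seed(seed)
  X <- matrix(0, T, N)
  if (T > 0) {
    Z <- matrix(rnorm(T * N), T, N)
    for (s in unique(state_sequence)) {
      rows <- state_sequence == s
      X[rows, ] <- Z[rows, , drop = FALSE] %*% chol(covs[[s]])
    }
    if (spec$observation_noise_sd > 0)
      X <- X + matrix(rnorm(T * N, sd = spec$observation_noise_sd), T, N)
  }
  network_timecourses(X, subject_id = subject_id, tr_seconds = spec$tr_seconds)
}

#' Simulate phase-coupled oscillatory time courses
#'
#' Networks are sinusoids at a common base frequency in the low-frequency
#' BOLD band. Each network n carries a fixed random phase offset; in state s
#' the realised offset is shrunk by the state's coupling to the reference
#' oscillator, `(1 - coupling) * offset`. Coupling 1 makes phases identical,
#' coupling 0 leaves the independent offsets untouched. This provides exact
#' phase ground truth for the phase-coherence pathway.
#'
#' @param state_sequence integer state per volume.
#' @param n_networks number of networks N.
#' @param base_freq_hz oscillation frequency, must lie below Nyquist
#'   (default 0.05 Hz).
#' @param coupling_per_state list of N x N matrices in `[0, 1]`, one per
#'   state; row 1 (coupling to the reference network) drives the model.
#' @param tr_seconds sampling interval in seconds.
#' @param seed integer seed (draws the per-network offsets).
#' @param phase_offsets optional fixed N-vector of offsets in radians,
#'   overriding the random draw (offset of network 1 is forced to 0).
#' @return a `network_timecourses` object.
#' @export
generate_phase_coupled <- function(state_sequence, n_networks,
                                   base_freq_hz = 0.05,
                                   coupling_per_state,
                                   tr_seconds = 2.072, seed = 1,
                                   phase_offsets = NULL) {
  check_scalar(base_freq_hz, "base_freq_hz", positive = TRUE)
  if (base_freq_hz >= 1 / (2 * tr_seconds))
    stopf("base frequency %.4f Hz is at or above Nyquist (%.4f Hz)",
          base_freq_hz, 1 / (2 * tr_seconds))
  K <- length(coupling_per_state)
  for (C in coupling_per_state)
    if (any(C < 0 | C > 1)) stopf("coupling entries must lie in [0, 1]")
  if (min(state_sequence) < 1 || max(state_sequence) > K)
    stopf("state sequence refers to a state with no coupling matrix")
  set.seed(seed)
  if (is.null(phase_offsets))
    phase_offsets <- runif(n_networks, -pi, pi)
  phase_offsets[1] <- 0
  T <- length(state_sequence)
  tt <- (seq_len(T) - 1) * tr_seconds
  base_phase <- 2 * pi * base_freq_hz * tt
  X <- matrix(0, T, n_networks)
  for (s in unique(state_sequence)) {
    rows <- which(state_sequence == s)
    cpl <- coupling_per_state[[s]][1, ]
    for (n in seq_len(n_networks))
      X[rows, n] <- cos(base_phase[rows] + (1 - cpl[n]) * phase_offsets[n])
  }
  network_timecourses(X, subject_id = "phase-sim", tr_seconds = tr_seconds)
}

#' Simulate a full multi-group cohort
#'
#' One state sequence and one time-course matrix per subject; group effects
#' (overridden transition matrices or covariances) apply per group. Ages are
#' uniform over `spec$age_range` and sexes Bernoulli(0.5).
#'
#' @param spec a `synthetic_spec`.
#' @param phase_coupled if TRUE, generate oscillatory phase-coupled signals
#'   (coupling matrices derived from the state covariances' correlations)
#'   instead of Gaussian draws.
#' @return list with `timecourses` (list of `network_timecourses`), `design`
#'   (data.frame: subject_id, group, age, sex) and `truth` (list with per-
#'   subject `state_sequences` and `group`).
#' @export
generate_cohort <- function(spec, phase_coupled = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_total <- sum(spec$n_subjects_per_group)
  subject_seeds <- sample.int(.Machine$integer.max, 2 * n_total)
  ages <- runif(n_total, spec$age_range[1], spec$age_range[2])
  sexes <- sample(c("F", "M"), n_total, replace = TRUE)

  timecourses <- vector("list", n_total)
  sequences <- vector("list", n_total)
  ids <- character(n_total)
  grp <- character(n_total)
  i <- 0
  for (g in seq_along(spec$groups)) {
    group <- spec$groups[g]
    P <- spec$transition_matrix
    covs <- spec$state_covariances
    ov <- spec$group_effects[[group]]
    if (!is.null(ov$transition_matrix)) {
      P <- ov$transition_matrix
      validate_transition_matrix(P)
    }
    if (!is.null(ov$state_covariances)) covs <- ov$state_covariances
    gspec <- spec
    gspec$state_covariances <- covs
    for (s in seq_len(spec$n_subjects_per_group[g])) {
      i <- i + 1
      ids[i] <- sprintf("sub-%03d", i)
      grp[i] <- group
      sequences[[i]] <- generate_state_sequence(P, spec$n_volumes,
                                                seed = subject_seeds[2 * i - 1])
      timecourses[[i]] <- if (phase_coupled) {
        cpl <- lapply(covs, function(m) pmin(pmax(abs(stats::cov2cor(m)), 0), 1))
        generate_phase_coupled(sequences[[i]], spec$n_networks,
                               coupling_per_state = cpl,
                               tr_seconds = spec$tr_seconds,
                               seed = subject_seeds[2 * i])
      } else {
        generate_subject_timecourses(sequences[[i]], gspec,
                                     seed = subject_seeds[2 * i],
                                     subject_id = ids[i])
      }
      timecourses[[i]]$subject_id <- ids[i]
    }
  }
  design <- data.frame(subject_id = ids, group = grp,
                       age = ages, sex = sexes, stringsAsFactors = FALSE)
  list(timecourses = timecourses, design = design,
       truth = list(state_sequences = stats::setNames(sequences, ids),
                    group = stats::setNames(grp, ids)))
}

#' Write a simulated cohort to disk
#'
#' Each subject's matrix is written as whitespace-delimited text (T rows x N
#' columns, no header); the design as TSV with header subject_id, group,
#' age, sex; the planted truth as TSV subject_id, volume_index (1-based),
#' state.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tc in cohort$timecourses) {
    p <- file.path(dir, paste0(tc$subject_id, "_timecourses.txt"))
    write_timecourses(tc, p)
    paths <- c(paths, p)
  }
  dp <- file.path(dir, "design.tsv")
  write.table(cohort$design, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, lapply(names(cohort$truth$state_sequences), function(id) {
    s <- cohort$truth$state_sequences[[id]]
    data.frame(subject_id = id, volume_index = seq_along(s), state = s)
  }))
  tp <- file.path(dir, "truth.tsv")
  write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, dp, tp))
}
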