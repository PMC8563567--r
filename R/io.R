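# Readers/writers for delimited time-course matrices and design tables,
# the component-filter bookkeeping utility, and the end-to-end pipeline
# driver with a reproducibility manifest.

#' Read a delimited time-course matrix
#'
#' Whitespace- or comma-delimited numeric text, T rows x N columns, no
#' header. Ragged rows and non-numeric cells are rejected with their 1-based
#' row/column coordinates.
#'
#' @param path file path.
#' @param tr_seconds repetition time attached to the result (default 2.072).
#' @param subject_id identifier; default is the file name without extension.
#' @return a `network_timecourses`.
#' @export
read_timecourses <- function(path, tr_seconds = 2.072, subject_id = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty time-course file: %s", path)
  tokens <- lapply(lines, function(l) strsplit(trimws(l), "[,[:space:]]+")[[1]])
  ncols <- lengths(tokens)
  if (length(unique(ncols)) != 1)
    stopf("ragged rows in %s: row %d has %d fields, row 1 has %d",
          path, which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1], ncols[1])
  vals <- suppressWarnings(lapply(tokens, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(is.na(vals[[i]]))
    if (length(bad))
      stopf("non-numeric value in %s at row %d, column %d ('%s')",
            path, i, bad[1], tokens[[i]][bad[1]])
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  network_timecourses(do.call(rbind, vals), subject_id = subject_id,
                      tr_seconds = tr_seconds)
}

#' Write a time-course matrix as delimited text
#'
#' T rows x N columns, space-delimited, no header (round-trips through
#' [read_timecourses()]).
#'
#' @param tc a `network_timecourses` (or matrix).
#' @param path output path.
#' @export
write_timecourses <- function(tc, path) {
  tc <- as_timecourses(tc)
  write.table(format(tc$data, digits = 17, scientific = TRUE, trim = TRUE),
              path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort design table
#'
#' TSV with header columns subject_id, group, age, sex (extra columns such
#' as medication flags are kept).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stopf("design file %s lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  if (anyDuplicated(d$subject_id))
    stopf("duplicate subject_id in design file")
  d
}

#' Filter ICA components to the retained network set
#'
#' Bookkeeping utility mirroring group-ICA cleanup: from `n_components`
#' candidate components, remove those classified as noise and those falling
#' outside the group mask; the remainder are the analysed networks. For
#' example, 25 components minus 4 noise leaves 21; 100 minus 45 noise minus
#' 4 out-of-mask leaves 51.
#'
#' @param n_components total number of candidate components.
#' @param noise integer ids of noise components.
#' @param out_of_mask integer ids of components outside the group mask.
#' @return integer vector of retained component ids.
#' @export
filter_components <- function(n_components, noise = integer(0),
                              out_of_mask = integer(0)) {
  check_scalar(n_components, "n_components", positive = TRUE, integer = TRUE)
  ids <- seq_len(n_components)
  drop <- union(as.integer(noise), as.integer(out_of_mask))
  if (length(drop) && (min(drop) < 1 || max(drop) > n_components))
    stopf("excluded component id outside 1..%d", n_components)
  setdiff(ids, drop)
}

#' Pipeline configuration
#'
#' Bundles the settings of every stage; all seeds are recorded in the run
#' manifest so reruns are bit-reproducible.
#'
#' @param timecourse_dir directory of per-subject delimited matrices
#'   (`<subject_id>_timecourses.txt`, as written by [write_cohort()]).
#' @param design_file TSV design table path.
#' @param output_dir output directory.
#' @param tr_seconds repetition time (default 2.072).
#' @param taper a `taper_spec` (default 22-TR window, sigma 3, step 1).
#' @param lambda `"cv"` or a fixed numeric L1 weight.
#' @param lambda_grid CV grid (default [lambda_grid_default()]).
#' @param n_folds CV folds (default 20).
#' @param k_range candidate state counts (default 2:6).
#' @param k fixed state count (default NULL: elbow).
#' @param n_restarts k-means restarts (default 500).
#' @param drop_edges Hilbert edge trim (default 1).
#' @param n_permutations permutations for the netmat test (default 500).
#' @param manova_permutations permutations for the rank MANOVA (default 5000).
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(timecourse_dir, design_file, output_dir,
                            tr_seconds = 2.072, taper = taper_spec(),
                            lambda = "cv", lambda_grid = lambda_grid_default(),
                            n_folds = 20, k_range = 2:6, k = NULL,
                            n_restarts = 500, drop_edges = 1,
                            n_permutations = 500, manova_permutations = 5000,
                            seed = 1) {
  stopifnot(inherits(taper, "taper_spec"))
  structure(list(timecourse_dir = timecourse_dir, design_file = design_file,
                 output_dir = output_dir, tr_seconds = tr_seconds,
                 taper = taper, lambda = lambda, lambda_grid = lambda_grid,
                 n_folds = n_folds, k_range = k_range, k = k,
                 n_restarts = n_restarts, drop_edges = drop_edges,
                 n_permutations = n_permutations,
                 manova_permutations = manova_permutations,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full connectivity pipeline
#'
#' Stage order: read + postprocess time courses, static netmats with the
#' permutation group test, sliding-window stacks with variability metrics
#' and the windowed state analysis, the LEiDA pathway, and the group
#' statistics (rank MANOVA on state frequencies, Kruskal-Wallis on
#' transition counts, intertransition times and FCD similarity). All
#' tabular outputs are TSV; a manifest lists every output file, the
#' configuration snapshot and the seeds.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, the manifest as a data.frame (key, value).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(fmt, ...)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$output_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }

  log_stage("prep: reading design and time courses")
  design <- read_design(config$design_file)
  files <- file.path(config$timecourse_dir,
                     paste0(design$subject_id, "_timecourses.txt"))
  missing_files <- !file.exists(files)
  if (any(missing_files))
    stopf("prep: no time-course file for subject(s): %s",
          paste(design$subject_id[missing_files], collapse = ", "))
  tcs <- lapply(seq_along(files), function(i)
    read_timecourses(files[i], tr_seconds = config$tr_seconds,
                     subject_id = design$subject_id[i]))
  tcs <- lapply(tcs, function(tc) despike(detrend_polynomial(tc))$timecourses)

  log_stage("static: netmats and permutation group test")
  netmats <- lapply(tcs, static_netmat)
  static_test <- permutation_group_test(netmats, design,
                                        n_permutations = config$n_permutations,
                                        seed = config$seed)
  emit(static_test$results, "netmat_group_test.tsv")

  log_stage("windows: sliding-window stacks (lambda = %s)",
            paste(config$lambda, collapse = ""))
  stacks <- lapply(tcs, function(tc)
    subject_window_stack(tc, spec = config$taper, lambda = config$lambda,
                         grid = config$lambda_grid, n_folds = config$n_folds))
  variability <- do.call(rbind, lapply(seq_along(stacks), function(i) {
    v <- connectivity_variability(stacks[[i]])
    idx <- upper_tri_index(nrow(v$per_edge_sd))
    data.frame(subject = design$subject_id[i],
               edge_i = idx[, 1], edge_j = idx[, 2],
               sd = vec_upper_tri(v$per_edge_sd))
  }))
  emit(variability, "variability_per_edge.tsv")
  global_var <- vapply(stacks, function(s)
    connectivity_variability(s)$global_mean_sd, 0)

  log_stage("states: windowed k-means (k %s)",
            if (is.null(config$k)) "by elbow" else config$k)
  states <- cohort_state_analysis(stacks, k_range = config$k_range,
                                  k = config$k,
                                  n_restarts = config$n_restarts,
                                  seed = config$seed)
  emit(states$metrics, "state_metrics.tsv")
  emit(states$subject_summary, "state_transitions.tsv")

  log_stage("leida: eigenvector states and FCD")
  leida <- leida_cohort_analysis(tcs, k_range = config$k_range, k = config$k,
                                 n_restarts = config$n_restarts,
                                 seed = config$seed,
                                 drop_edges = config$drop_edges)
  emit(leida$metrics, "leida_metrics.tsv")
  emit(leida$subject_summary, "leida_transitions.tsv")
  emit(data.frame(subject = names(leida$fcd_mean_similarity),
                  mean_fcd_similarity = unname(leida$fcd_mean_similarity)),
       "fcd_similarity.tsv")

  log_stage("stats: nonparametric group comparisons")
  freq_wide <- stats::reshape(states$metrics[c("subject", "state", "frequency")],
                              idvar = "subject", timevar = "state",
                              direction = "wide")
  ord <- match(design$subject_id, freq_wide$subject)
  man <- nonparametric_manova(as.matrix(freq_wide[ord, -1]), design$group,
                              n_permutations = config$manova_permutations,
                              seed = config$seed)
  kw_tr <- kruskal_wallis(states$subject_summary$n_transitions[
    match(design$subject_id, states$subject_summary$subject)], design$group)
  iti <- states$subject_summary$mean_intertransition_time[
    match(design$subject_id, states$subject_summary$subject)]
  kw_iti <- if (all(is.na(iti))) list(H = NA, df = NA, p = NA)
            else kruskal_wallis(iti[!is.na(iti)], design$group[!is.na(iti)])
  kw_fcd <- kruskal_wallis(leida$fcd_mean_similarity[
    match(design$subject_id, names(leida$fcd_mean_similarity))], design$group)
  kw_var <- kruskal_wallis(global_var, design$group)
  stats_tab <- data.frame(
    test = c("manova_state_frequency", "kw_n_transitions",
             "kw_intertransition_time", "kw_fcd_similarity",
             "kw_global_variability"),
    statistic = c(man$pillai, kw_tr$H, kw_iti$H, kw_fcd$H, kw_var$H),
    df = c(NA, kw_tr$df, kw_iti$df, kw_fcd$df, kw_var$df),
    p = c(man$p, kw_tr$p, kw_iti$p, kw_fcd$p, kw_var$p))
  emit(stats_tab, "group_stats.tsv")

  manifest <- data.frame(
    key = c("package_version", "seed", "window_length_tr", "gaussian_sigma_tr",
            "step_tr", "lambda", "n_folds", "k", "k_range", "n_restarts",
            "drop_edges", "n_permutations", "manova_permutations",
            "n_subjects", "input_checksums",
            paste0("output_", seq_along(outputs))),
    value = c(as.character(utils::packageVersion("dfcstates")),
              config$seed, config$taper$window_length_tr,
              config$taper$gaussian_sigma_tr, config$taper$step_tr,
              paste(config$lambda, collapse = ""), config$n_folds,
              if (is.null(config$k)) paste0("elbow:", states$k) else config$k,
              paste(config$k_range, collapse = ","), config$n_restarts,
              config$drop_edges, config$n_permutations,
              config$manova_permutations, nrow(design),
              paste(tools::md5sum(files), collapse = ","),
              outputs))
  write.table(manifest, file.path(config$output_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("done: %d output files", length(outputs) + 1)
  invisible(manifest)
}
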