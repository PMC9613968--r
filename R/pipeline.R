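#' Shared configuration for the full complexity pipeline
#'
#' @param threshold variance fraction for the dimensionality measure.
#' @param combiner GaitSD per-joint combiner (see [gait_sd()]).
#' @param n_phase phase points per normalized cycle.
#' @param min_cycle_duration minimum stride duration in seconds.
#' @param nld an [nld_config()] for the nonlinear measures.
#' @param nld_joints channels for the nonlinear measures; `NULL` = all
#'   sagittal channels.
#' @return A named list of class `analysis_config`.
#' @export
analysis_config <- function(threshold = 0.95,
                            combiner = "mean_of_sd",
                            n_phase = 101,
                            min_cycle_duration = 0.4,
                            nld = nld_config(),
                            nld_joints = NULL) {
  structure(list(threshold = threshold, combiner = combiner,
                 n_phase = n_phase,
                 min_cycle_duration = min_cycle_duration,
                 nld = nld, nld_joints = nld_joints),
            class = "analysis_config")
}

analyze_trial <- function(trial, contacts, config) {
  spec <- variance_spectrum(trial$samples)
  trial_n95 <- n95(spec, config$threshold)
  gv <- generalized_variance(trial$samples)
  cycles <- segment_cycles(trial, contacts,
                           min_duration = config$min_cycle_duration)
  cs <- time_normalize(cycles, T = config$n_phase)
  gs <- gait_sd(cs, combiner = config$combiner)
  nld <- joint_nld_summary(trial, joints = config$nld_joints,
                           config = config$nld)
  warns <- character(0)
  if (gv$rank_deficient)
    warns <- c(warns, sprintf("%s: rank-deficient covariance", trial$trial_id))
  for (ch in names(nld)) {
    if (nld[[ch]]$ami$fallback_used)
      warns <- c(warns, sprintf("%s/%s: AMI argmin fallback",
                                trial$trial_id, ch))
    if (nld[[ch]]$fnn$saturated)
      warns <- c(warns, sprintf("%s/%s: GFNN saturated at max_dim",
                                trial$trial_id, ch))
    if (any(nld[[ch]]$cmse$undefined_scales))
      warns <- c(warns, sprintf("%s/%s: undefined entropy at scale(s) %s",
                                trial$trial_id, ch,
                                paste(which(nld[[ch]]$cmse$undefined_scales),
                                      collapse = ",")))
  }
  list(trial_id = trial$trial_id, n95 = trial_n95, spectrum = spec,
       gv = gv, gait_sd = gs, n_cycles = gs$n_cycles, nld = nld,
       lye_per_joint = vapply(nld, function(e) e$lye$lye, numeric(1)),
       ci_per_joint = vapply(nld, function(e) e$cmse$ci, numeric(1)),
       warnings = warns)
}

agg <- function(v) {
  v <- v[is.finite(v)]
  list(mean = if (length(v)) mean(v) else NA_real_,
       sd = if (length(v) > 1) sd(v) else 0,
       n = length(v))
}

#' Run every complexity measure on the trials of one activity
#'
#' Per trial: PCA variance spectrum and its 95%-variance dimensionality;
#' generalized variance on the raw frames; stride segmentation,
#' 101-point time normalization and GaitSD; and the per-joint nonlinear
#' summary (delay embedding, largest Lyapunov exponent, composite
#' multiscale entropy). Trials that fail at any stage are reported in
#' `failures` and do not abort the rest.
#'
#' @param trials list of [kin_trial()] objects (>= 1).
#' @param contacts list of [foot_contacts()], parallel to `trials`.
#' @param activity_label label for the report.
#' @param config an [analysis_config()].
#' @return An object of class `activity_report`: per-trial results,
#'   aggregate mean/sd/n per measure, the configuration snapshot,
#'   accumulated warnings and failures.
#' @export
analyze_activity <- function(trials, contacts, activity_label = "",
                             config = analysis_config()) {
  if (length(trials) < 1) stop("need at least 1 trial")
  if (length(contacts) != length(trials))
    stop("need one contact series per trial")
  per_trial <- list()
  failures <- list()
  warns <- character(0)
  ids <- make.unique(vapply(trials, `[[`, character(1), "trial_id"))
  for (i in seq_along(trials)) {
    id <- ids[i]
    res <- tryCatch(
      withCallingHandlers(
        analyze_trial(trials[[i]], contacts[[i]], config),
        warning = function(w) {
          warns <<- c(warns, sprintf("%s: %s", id, conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      per_trial[[id]] <- res
      warns <- c(warns, res$warnings)
    }
  }
  if (length(per_trial) == 0)
    stop(sprintf("all trials failed: %s",
                 paste(unlist(failures), collapse = "; ")))
  n95s <- vapply(per_trial, `[[`, numeric(1), "n95")
  log_gvs <- vapply(per_trial, function(r) r$gv$log_gv, numeric(1))
  norm_gvs <- vapply(per_trial, function(r) r$gv$normalized_gv, numeric(1))
  gait_sds <- vapply(per_trial, function(r) r$gait_sd$gait_sd, numeric(1))
  lyes <- vapply(per_trial, function(r) mean(r$lye_per_joint), numeric(1))
  cis <- vapply(per_trial, function(r) mean(r$ci_per_joint), numeric(1))
  structure(list(
    activity_label = activity_label,
    per_trial = per_trial,
    aggregate = list(n95 = agg(n95s), log_gv = agg(log_gvs),
                     normalized_gv = agg(norm_gvs),
                     gait_sd = agg(gait_sds), lye = agg(lyes),
                     ci = agg(cis)),
    n_trials = length(per_trial),
    n_cycles = sum(vapply(per_trial, `[[`, numeric(1), "n_cycles")),
    config = config, warnings = warns, failures = failures),
    class = "activity_report")
}

#' @export
print.activity_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<activity_report> %s: %d trial(s), %d cycle(s)\n",
              x$activity_label, x$n_trials, x$n_cycles))
  cat(sprintf("  N95 %.2f +/- %.2f | GV^(1/p) %.3g deg^2 | GaitSD %.3g deg | LyE %.3g /s | CI %.3g\n",
              a$n95$mean, a$n95$sd, a$normalized_gv$mean, a$gait_sd$mean,
              a$lye$mean, a$ci$mean))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s)\n", length(x$warnings)))
  if (length(x$failures))
    cat(sprintf("  %d failed trial(s): %s\n", length(x$failures),
                paste(names(x$failures), collapse = ", ")))
  invisible(x)
}

ranking_measures <- c("n95", "normalized_gv", "gait_sd", "lye", "ci")

#' Kendall's coefficient of concordance for a matrix of rankings
#'
#' W in [0, 1]; 1 means all raters (rows) rank the objects (columns)
#' identically. Tied ranks use the standard tie correction.
#'
#' @param ranks numeric matrix, raters x objects, each row a (possibly
#'   tied, mean-rank) ranking of the columns.
#' @return Scalar W.
#' @export
kendall_w <- function(ranks) {
  ranks <- as.matrix(ranks)
  m <- nrow(ranks); n <- ncol(ranks)
  stopifnot(m >= 2, n >= 2)
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  Tcorr <- sum(apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) / 12 - m * Tcorr / 12
  if (denom <= 0) return(1)  # every rating fully tied
  S / denom
}

#' Cross-measure ranking of activities
#'
#' Ranks the activities under each complexity measure (rank 1 = most
#' complex, i.e. the largest value of that measure; ties share mean
#' ranks) and quantifies cross-measure agreement with Kendall's W. The
#' measures are the per-activity aggregates: N95 dimensionality,
#' normalized generalized variance, GaitSD, mean sagittal Lyapunov
#' exponent, and mean Complexity Index.
#'
#' @param reports list of >= 2 [analyze_activity()] reports.
#' @return An object of class `ranking_table` with fields `ranks`
#'   (measures x activities), `values`, `concordance` (Kendall's W).
#' @export
rank_activities <- function(reports) {
  if (length(reports) < 2) stop("need >= 2 activity reports to rank")
  labels <- vapply(reports, function(r) r$activity_label, character(1))
  vals <- matrix(NA_real_, length(ranking_measures), length(reports),
                 dimnames = list(ranking_measures, labels))
  for (j in seq_along(reports)) {
    a <- reports[[j]]$aggregate
    for (ms in ranking_measures) {
      if (is.null(a[[ms]]) || !is.finite(a[[ms]]$mean))
        stop(sprintf("report '%s' is missing measure '%s'",
                     labels[j], ms))
      vals[ms, j] <- a[[ms]]$mean
    }
  }
  ranks <- t(apply(vals, 1, function(v) rank(-v)))  # 1 = most complex
  structure(list(ranks = ranks, values = vals,
                 concordance = kendall_w(ranks)),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("<ranking_table> rank 1 = most complex\n")
  print(x$ranks)
  cat(sprintf("Kendall's W = %.3f\n", x$concordance))
  invisible(x)
}

report_to_list <- function(report) {
  list(
    activity_label = report$activity_label,
    n_trials = report$n_trials,
    n_cycles = report$n_cycles,
    aggregate = report$aggregate,
    per_trial = lapply(report$per_trial, function(r) list(
      trial_id = r$trial_id,
      n95 = r$n95,
      eigenvalues = r$spectrum$eigenvalues,
      gv = r$gv$gv, log_gv = r$gv$log_gv,
      normalized_gv = r$gv$normalized_gv,
      rank_deficient = r$gv$rank_deficient,
      gait_sd = r$gait_sd$gait_sd, n_cycles = r$n_cycles,
      lye_per_joint = as.list(r$lye_per_joint),
      ci_per_joint = as.list(r$ci_per_joint))),
    config = list(threshold = report$config$threshold,
                  combiner = report$config$combiner,
                  n_phase = report$config$n_phase,
                  min_cycle_duration = report$config$min_cycle_duration),
    warnings = report$warnings,
    failures = report$failures)
}

#' Write an activity report as JSON
#'
#' Serialization is deterministic: identical reports produce byte-identical
#' files.
#'
#' @param report an [analyze_activity()] report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_report <- function(report, path) {
  stopifnot(inherits(report, "activity_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, always_decimal = FALSE)
  invisible(path)
}

#' Write a ranking table as CSV
#'
#' One row per measure with the activity ranks, followed by a final row
#' holding Kendall's W.
#'
#' @param ranking a [rank_activities()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranking_table"))
  df <- data.frame(measure = rownames(ranking$ranks), ranking$ranks,
                   check.names = FALSE, row.names = NULL)
  df <- rbind(df, c("kendall_w", rep(ranking$concordance,
                                     ncol(ranking$ranks))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
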