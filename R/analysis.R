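#' Per-fly locomotor record
#'
#' Runs the full per-fly measurement stack on one trajectory and returns a
#' one-row data frame: mean speed (mm/s), yawing (mean |heading change|,
#' deg/frame), freezing fraction, raw AIM score, peak percent speed
#' deviation, and bookkeeping columns. \code{normalized_H} is NA here; it is
#' filled relative to a control group by \code{\link{add_normalized_aim}} or
#' \code{\link{summarize_cohort}}. For a fully stationary fly the AIM score
#' is 0 with \code{aim_all_skipped = TRUE} and the peak deviation is NA.
#'
#' @param traj a \code{\link{fly_trajectory}}.
#' @param params an \code{\link{aim_params}}.
#' @param epsilon_mm freezing displacement tolerance, mm
#'   (see \code{\link{freezing_fraction}}).
#' @param fly_id,group identifier and group label carried into the record.
#' @return a one-row \code{data.frame}.
#' @export
summarize_fly <- function(traj, params = aim_params(), epsilon_mm = 0.05,
                          fly_id = "fly1", group = "unlabeled") {
  if (!nzchar(as.character(group)))
    stop("group label must be non-empty", call. = FALSE)
  k <- kinematic_series(traj)
  aim <- aim_score(k, params)
  peak <- if (aim$scored_frame_count > 0L) peak_deviation(k, params) else NA_real_
  data.frame(fly_id = as.character(fly_id),
             group = as.character(group),
             mean_speed_mm_s = mean_speed(k),
             yawing_deg_per_frame = yawing_metric(k),
             freezing_fraction = freezing_fraction(k, epsilon_mm),
             raw_H = aim$raw_H,
             normalized_H = NA_real_,
             peak_deviation_pct = peak,
             aim_all_skipped = aim$all_skipped,
             n_frames = traj$n_frames,
             stringsAsFactors = FALSE)
}

#' Fill normalized AIM scores relative to a control group
#'
#' Sets \code{normalized_H = raw_H - mean(raw_H of the control group)} for
#' every record, so the control group's mean normalized score is exactly 0.
#'
#' @param records a data frame of per-fly records
#'   (\code{\link{summarize_fly}} rows).
#' @param control_label the \code{group} value designating control flies.
#' @return \code{records} with \code{normalized_H} filled.
#' @export
add_normalized_aim <- function(records, control_label) {
  if (!control_label %in% records$group)
    stop("control label '", control_label, "' not present among groups",
         call. = FALSE)
  ctrl <- records$raw_H[records$group == control_label]
  records$normalized_H <- normalize_aim(records$raw_H, ctrl)
  records
}

#' Score a simulated cohort
#'
#' Applies \code{\link{summarize_fly}} to every fly of a
#' \code{\link{simulate_cohort}} result and normalizes AIM scores against the
#' control dose (by default the smallest dose present). Group labels are
#' \code{"dose_<level>"}.
#'
#' @param cohort a \code{fly_cohort}.
#' @param params an \code{\link{aim_params}}.
#' @param epsilon_mm freezing tolerance, mm.
#' @param control_dose dose level serving as the control group.
#' @return a data frame with one row per fly, including a numeric
#'   \code{dose} column.
#' @export
summarize_cohort <- function(cohort, params = aim_params(),
                             epsilon_mm = 0.05, control_dose = NULL) {
  stopifnot(inherits(cohort, "fly_cohort"))
  rows <- lapply(cohort, function(fly) {
    rec <- summarize_fly(fly$trajectory, params, epsilon_mm,
                         fly_id = fly$fly_id,
                         group = sprintf("dose_%g", fly$dose))
    rec$dose <- fly$dose
    rec
  })
  records <- do.call(rbind, rows)
  if (is.null(control_dose)) control_dose <- min(records$dose)
  add_normalized_aim(records, sprintf("dose_%g", control_dose))
}

.metric_cols <- c("mean_speed_mm_s", "yawing_deg_per_frame",
                  "freezing_fraction", "raw_H", "normalized_H",
                  "peak_deviation_pct")

#' Group means, SEMs, and percent change versus control
#'
#' Aggregates per-fly records into per-group, per-metric summaries: n, mean,
#' SEM (sd/sqrt(n)), and percent change of the group mean relative to the
#' control-group mean, \code{(mean - control_mean)/control_mean * 100}. The
#' control group's percent change is exactly 0 for every metric. Single-fly
#' groups report SEM as 0 with \code{sem_degenerate = TRUE} rather than
#' erroring, so toy fixtures run end-to-end.
#'
#' @param records data frame of per-fly records with a \code{group} column.
#' @param control_label the group label of the control flies.
#' @param metrics metric column names to summarize (defaults to all standard
#'   metric columns present in \code{records}).
#' @return a \code{data.frame} of class \code{group_summary} in long format:
#'   \code{group, metric, n, mean, sem, sem_degenerate,
#'   pct_change_vs_control}.
#' @export
summarize_group <- function(records, control_label,
                            metrics = intersect(.metric_cols, names(records))) {
  if (!control_label %in% records$group)
    stop("control label '", control_label, "' not present among groups",
         call. = FALSE)
  if (!length(metrics)) stop("no metric columns to summarize", call. = FALSE)
  groups <- unique(records$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    n <- nrow(sub)
    do.call(rbind, lapply(metrics, function(m) {
      vals <- sub[[m]]
      data.frame(group = g, metric = m, n = n,
                 mean = mean(vals),
                 sem = if (n > 1L) stats::sd(vals) / sqrt(n) else 0,
                 sem_degenerate = n == 1L,
                 stringsAsFactors = FALSE)
    }))
  }))
  ctrl <- out[out$group == control_label, c("metric", "mean")]
  cmean <- ctrl$mean[match(out$metric, ctrl$metric)]
  out$pct_change_vs_control <- ifelse(
    out$group == control_label, 0,
    ifelse(cmean == 0, NA_real_, (out$mean - cmean) / cmean * 100))
  class(out) <- c("group_summary", "data.frame")
  attr(out, "control_label") <- control_label
  out
}

#' @export
print.group_summary <- function(x, digits = 4, ...) {
  cat("Group summary (control:", attr(x, "control_label"), "; mean ± SEM)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Dose-trend test by rank correlation with a permutation null
#'
#' Spearman rank correlation between dose and a per-fly metric, with a
#' two-sided permutation p-value obtained by shuffling the dose labels
#' (seeded; at least 999 permutations). Rank correlation is used because the
#' expected dose responses are monotone but not assumed linear.
#'
#' @param dose numeric vector of dose values, one per fly; at least 3
#'   distinct levels.
#' @param values numeric vector of the metric, same length.
#' @param n_permutations number of label permutations (>= 999 recommended).
#' @param seed integer seed for the permutation stream.
#' @return an object of class \code{dose_trend}: \code{rho}, \code{p_value},
#'   \code{n}, \code{n_permutations}, \code{n_dose_levels}.
#' @export
dose_trend <- function(dose, values, n_permutations = 999, seed = 1L) {
  if (length(dose) != length(values))
    stop("dose and values must have equal length", call. = FALSE)
  ok <- is.finite(dose) & is.finite(values)
  dose <- dose[ok]; values <- values[ok]
  n_levels <- length(unique(dose))
  if (n_levels < 3L)
    stop("need at least 3 distinct dose levels (got ", n_levels, ")",
         call. = FALSE)
  if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  rho <- stats::cor(dose, values, method = "spearman")
  perm <- .with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    stats::cor(dose, sample(values), method = "spearman")
  }, numeric(1L)))
  p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_permutations + 1)
  structure(list(rho = rho, p_value = p, n = length(dose),
                 n_permutations = n_permutations,
                 n_dose_levels = n_levels),
            class = "dose_trend")
}

#' @export
print.dose_trend <- function(x, ...) {
  cat(sprintf("Dose trend: Spearman rho = %.3f, permutation p = %.4f (n = %d flies, %d dose levels, %d permutations)\n",
              x$rho, x$p_value, x$n, x$n_dose_levels, x$n_permutations))
  invisible(x)
}

#' Group comparison by ANOVA with Tukey's HSD
#'
#' Pass-through to the standard one-way ANOVA plus Tukey multiple-comparison
#' routine for a per-fly metric across groups. This is routine inference
#' delegated to \code{stats::aov}/\code{stats::TukeyHSD}, exposed for report
#' convenience.
#'
#' @param records data frame of per-fly records with a \code{group} column.
#' @param metric metric column name.
#' @return a list with elements \code{anova} (the \code{aov} fit) and
#'   \code{tukey} (\code{TukeyHSD} result).
#' @export
group_anova <- function(records, metric) {
  if (!metric %in% names(records)) stop("unknown metric: ", metric, call. = FALSE)
  df <- data.frame(y = records[[metric]], group = factor(records$group))
  fit <- stats::aov(y ~ group, data = df)
  list(anova = fit, tukey = stats::TukeyHSD(fit))
}
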