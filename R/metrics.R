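#' Chemotactic index of a trajectory
#'
#' The chemotactic index (CI) measures accuracy: the cosine of the angle
#' between a cell's displacement and the gradient direction, i.e. the
#' displacement component along the gradient divided by the total
#' displacement. By default the net displacement over the whole track is
#' used, giving one CI value per cell; `method = "step"` instead averages
#' cos(theta) over the individual steps (a non-default variant some studies
#' report).
#'
#' @param traj a [trajectory()].
#' @param method `"net"` (default, whole-track net displacement) or
#'   `"step"` (mean over per-step angles; zero-length steps are skipped).
#' @return CI in \[-1, 1\]. 1 = perfectly up-gradient, 0 = unbiased,
#'   negative = down-gradient.
#' @export
#' @examples
#' chemotactic_index(trajectory(rbind(c(0, 0), c(3, 4))))  # 3/5
chemotactic_index <- function(traj, method = c("net", "step")) {
  method <- match.arg(method)
  stopifnot(is_trajectory(traj))
  ax <- traj$gradient_axis
  if (method == "net") {
    d <- traj$positions[nrow(traj$positions), ] - traj$positions[1, ]
    r <- sqrt(sum(d^2))
    if (r == 0) {
      stop("chemotactic index undefined: zero net displacement",
           call. = FALSE)
    }
    return(sum(d * ax) / r)
  }
  st <- traj_steps(traj)
  len <- sqrt(rowSums(st^2))
  keep <- len > 0
  if (!any(keep)) {
    stop("chemotactic index undefined: all steps have zero length",
         call. = FALSE)
  }
  mean((st[keep, 1] * ax[1] + st[keep, 2] * ax[2]) / len[keep])
}

#' Directional persistence of a trajectory
#'
#' DP is the ratio of the magnitude of the net displacement to the total
#' distance travelled (path length); it measures the tendency to move in a
#' straight line in *any* direction and is independent of the gradient.
#' DP = 1 for perfectly straight motion; DP tends to 0 for an infinitely
#' long non-persistent walk.
#'
#' @param traj a [trajectory()].
#' @return DP in \[0, 1\].
#' @export
directional_persistence <- function(traj) {
  stopifnot(is_trajectory(traj))
  st <- traj_steps(traj)
  path <- sum(sqrt(rowSums(st^2)))
  if (path == 0) {
    stop("directional persistence undefined: zero path length",
         call. = FALSE)
  }
  d <- traj$positions[nrow(traj$positions), ] - traj$positions[1, ]
  sqrt(sum(d^2)) / path
}

#' Mean instantaneous speed of a trajectory
#'
#' The distance travelled in each recording interval divided by the
#' interval, averaged over all intervals, reported in micrometres per hour.
#'
#' @param traj a [trajectory()].
#' @return mean speed in um/h.
#' @export
mean_speed <- function(traj) {
  stopifnot(is_trajectory(traj))
  st <- traj_steps(traj)
  dt_h <- traj_dt(traj) / 60
  mean(sqrt(rowSums(st^2)) / dt_h)
}

#' Directional autocorrelation time
#'
#' Integrates the directional autocorrelation function
#' C(t') = <cos(theta_(t+t') - theta_t)> over time lags, where theta_t is
#' the direction of the step taken at time t and the average runs over all
#' valid start times. C(0) = 1 by definition. The integral (trapezoidal
#' rule) is truncated at `max_lag` steps because tracks are finite; the
#' default is half the number of steps. Zero-length steps carry no
#' direction and are skipped.
#'
#' Unlike DP, tau_AC is robust to the observation window, but it carries
#' units (minutes) and is unbounded. On short, noisy tracks the truncated
#' integral can come out slightly negative; values are reported unclamped
#' so that ensemble averages stay unbiased.
#'
#' @param traj a [trajectory()].
#' @param max_lag maximum lag in steps (default: half the step count,
#'   rounded down, at least 1). Must be smaller than the number of steps.
#' @return autocorrelation time in minutes.
#' @export
autocorrelation_time <- function(traj, max_lag = NULL) {
  stopifnot(is_trajectory(traj))
  st <- traj_steps(traj)
  len <- sqrt(rowSums(st^2))
  ang <- atan2(st[, 2], st[, 1])[len > 0]
  n <- length(ang)
  if (n < 3) stop("need at least 3 non-zero steps", call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(1L, n %/% 2L)
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("`max_lag` must be < number of steps", call. = FALSE)
  corr <- c(1, vapply(seq_len(max_lag), function(k) {
    mean(cos(ang[(1 + k):n] - ang[1:(n - k)]))
  }, numeric(1)))
  dt <- traj_dt(traj)
  # trapezoid over lags 0..max_lag in units of dt
  dt * (sum(corr) - (corr[1] + corr[length(corr)]) / 2)
}

#' Stationary-cell filter
#'
#' Cells that never move farther than their own diameter from their
#' starting point are classed as stationary (typically pinned by the
#' matrix) and excluded from cohort metrics. The default diameter, 20 um,
#' is the side of a square with the relaxed cell area of 400 um^2.
#'
#' @param cohort list of [trajectory()] objects.
#' @param diameter_um exclusion threshold in micrometres (> 0).
#' @return list with elements `kept` and `excluded`, a disjoint exhaustive
#'   partition of the input (order preserved within each part).
#' @export
filter_stationary <- function(cohort, diameter_um = 20) {
  cohort <- assert_cohort(cohort)
  stopifnot(diameter_um > 0)
  stat <- vapply(cohort, function(tr) {
    disp <- sweep(tr$positions, 2, tr$positions[1, ])
    max(sqrt(rowSums(disp^2))) < diameter_um
  }, logical(1))
  list(kept = cohort[!stat], excluded = cohort[stat])
}

#' Mann-Whitney comparison of two metric distributions
#'
#' Two-sided Mann-Whitney U test (the non-parametric choice when metric
#' distributions are not normal, as for the cosine-shaped CI). Small
#' tie-free samples (both below 20) are tested by exact enumeration;
#' otherwise the normal approximation with tie correction is used.
#'
#' @param a,b numeric vectors of per-cell metric values (non-empty).
#' @return list with `statistic` (U for group `a`), `p_value`, `n1`, `n2`,
#'   `median1`, `median2`.
#' @export
compare_groups <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty",
                                     call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) < 20 && length(b) < 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n1 = length(a), n2 = length(b),
       median1 = stats::median(a), median2 = stats::median(b))
}

#' Per-cell metric table for a cohort
#'
#' Runs the stationary filter and computes CI, DP, speed and tau_AC for
#' every trajectory. Excluded (stationary) cells keep their row, flagged in
#' the `excluded` column, with metrics set to `NA` — mirroring the
#' convention that stationary cells are dropped from cohort statistics but
#' retained in the record.
#'
#' @param cohort list of [trajectory()] objects.
#' @param diameter_um stationary-filter threshold (see
#'   [filter_stationary()]).
#' @param max_lag passed to [autocorrelation_time()].
#' @return data.frame with columns
#'   `cell_id, ci, dp, speed_um_h, tau_ac_min, excluded`.
#' @export
cohort_metrics <- function(cohort, diameter_um = 20, max_lag = NULL) {
  cohort <- assert_cohort(cohort)
  parts <- filter_stationary(cohort, diameter_um)
  excluded_ids <- vapply(parts$excluded, `[[`, character(1), "cell_id")
  do.call(rbind, lapply(cohort, function(tr) {
    excl <- tr$cell_id %in% excluded_ids
    if (excl) {
      data.frame(cell_id = tr$cell_id, ci = NA_real_, dp = NA_real_,
                 speed_um_h = NA_real_, tau_ac_min = NA_real_,
                 excluded = TRUE)
    } else {
      tau <- tryCatch(autocorrelation_time(tr, max_lag),
                      error = function(e) NA_real_)  # tracks too short
      data.frame(cell_id = tr$cell_id,
                 ci = chemotactic_index(tr),
                 dp = directional_persistence(tr),
                 speed_um_h = mean_speed(tr),
                 tau_ac_min = tau,
                 excluded = FALSE)
    }
  }))
}

#' Cohort summary: medians of per-cell metrics
#'
#' @param cohort list of [trajectory()] objects.
#' @param diameter_um stationary-filter threshold.
#' @return list with `n_cells` (after filtering), `n_excluded_stationary`,
#'   `median_ci`, `median_dp`, `median_speed`, and the full per-cell
#'   `metrics` table of the kept cells.
#' @export
summarize_cohort <- function(cohort, diameter_um = 20) {
  m <- cohort_metrics(cohort, diameter_um)
  kept <- m[!m$excluded, , drop = FALSE]
  if (!nrow(kept)) stop("no motile cells left after filtering", call. = FALSE)
  list(n_cells = nrow(kept),
       n_excluded_stationary = sum(m$excluded),
       median_ci = stats::median(kept$ci),
       median_dp = stats::median(kept$dp),
       median_speed = stats::median(kept$speed_um_h),
       metrics = kept)
}

#' Replicate summary: mean of medians with SEM
#'
#' Experimental conditions are repeated as independent replicates; each
#' replicate is summarised by its median and the condition is reported as
#' the mean of the replicate medians +/- their standard error
#' (sd / sqrt(n_replicates)).
#'
#' @param medians numeric vector of per-replicate medians (length >= 2), or
#'   a list of cohorts, in which case the median of `metric` is taken per
#'   cohort.
#' @param metric one of `"ci"`, `"dp"`, `"speed_um_h"` when cohorts are
#'   given.
#' @param diameter_um stationary-filter threshold for the cohort path.
#' @return list with `medians`, `mean_of_medians`, `sem`, `n_replicates`.
#' @export
replicate_summary <- function(medians, metric = "ci", diameter_um = 20) {
  if (is.list(medians) && !is.numeric(medians)) {
    col <- match.arg(metric, c("ci", "dp", "speed_um_h"))
    medians <- vapply(medians, function(co) {
      m <- summarize_cohort(co, diameter_um)$metrics
      stats::median(m[[col]])
    }, numeric(1))
  }
  medians <- as.numeric(medians)
  if (length(medians) < 2) {
    stop("SEM undefined for a single replicate", call. = FALSE)
  }
  list(medians = medians,
       mean_of_medians = mean(medians),
       sem = stats::sd(medians) / sqrt(length(medians)),
       n_replicates = length(medians))
}
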