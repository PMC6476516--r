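#' Single-cell trajectory
#'
#' A trajectory is the unit of all metric computation: an ordered series of
#' 2-D positions (micrometres) recorded at a uniform time interval for one
#' tracked cell, together with the direction of the imposed chemical
#' gradient.
#'
#' @param positions numeric matrix with two columns (x, y), in micrometres;
#'   one row per recorded frame, at least two rows.
#' @param t_min numeric vector of time stamps in minutes, strictly
#'   increasing with constant spacing. Defaults to `0, dt_min, 2*dt_min, ...`.
#' @param cell_id identifier for the cell (coerced to character).
#' @param gradient_axis unit vector giving the gradient direction
#'   (normalised internally); defaults to +x.
#' @param dt_min recording interval in minutes, used only when `t_min` is
#'   missing. Default 15, the usual time-lapse interval for 9-h assays.
#'
#' @return An object of class `trajectory`: a list with elements `cell_id`,
#'   `t_min`, `positions` and `gradient_axis`.
#' @export
#' @examples
#' tr <- trajectory(rbind(c(0, 0), c(3, 4)))
#' chemotactic_index(tr)
trajectory <- function(positions, t_min = NULL, cell_id = "cell",
                       gradient_axis = c(1, 0), dt_min = 15) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) {
    stop("`positions` must have two columns (x, y)", call. = FALSE)
  }
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (n < 2L) stop("a trajectory needs at least 2 points", call. = FALSE)
  if (!all(is.finite(positions))) {
    stop("positions must be finite", call. = FALSE)
  }
  if (is.null(t_min)) t_min <- dt_min * (seq_len(n) - 1)
  t_min <- as.numeric(t_min)
  if (length(t_min) != n) {
    stop("`t_min` must match the number of positions", call. = FALSE)
  }
  dt <- diff(t_min)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt))) {
    stop("time spacing must be uniform", call. = FALSE)
  }
  gradient_axis <- as.numeric(gradient_axis)
  nr <- sqrt(sum(gradient_axis^2))
  if (!is.finite(nr) || nr == 0) {
    stop("`gradient_axis` must be a nonzero 2-D vector", call. = FALSE)
  }
  structure(
    list(cell_id = as.character(cell_id)[1], t_min = t_min,
         positions = positions, gradient_axis = gradient_axis / nr),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s': %d frames, dt = %g min, %.1f min total>\n",
              x$cell_id, nrow(x$positions), traj_dt(x),
              diff(range(x$t_min))))
  invisible(x)
}

## recording interval in minutes
traj_dt <- function(traj) {
  (traj$t_min[2] - traj$t_min[1])
}

## displacement vectors between consecutive frames (n-1 x 2)
traj_steps <- function(traj) {
  diff(traj$positions)
}

is_trajectory <- function(x) inherits(x, "trajectory")

assert_cohort <- function(cohort) {
  if (is_trajectory(cohort)) return(list(cohort))
  if (!is.list(cohort) || !length(cohort) ||
      !all(vapply(cohort, is_trajectory, logical(1)))) {
    stop("expected a trajectory or a list of trajectories", call. = FALSE)
  }
  cohort
}

#' Read trajectories from a tracking table
#'
#' Reads the plain-CSV tracking dialect
#' `cell_id,frame,t_min,x_um,y_um` (one row per cell per frame) and returns
#' a list of [trajectory()] objects, ordered by first appearance.
#'
#' @param path path to a CSV file.
#' @param gradient_axis gradient direction applied to every trajectory.
#' @return list of `trajectory` objects.
#' @export
read_trajectories <- function(path, gradient_axis = c(1, 0)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  ids <- unique(df$cell_id)
  lapply(ids, function(id) {
    d <- df[df$cell_id == id, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    trajectory(cbind(d$x_um, d$y_um), t_min = d$t_min, cell_id = id,
               gradient_axis = gradient_axis)
  })
}

#' Write trajectories to a tracking table
#'
#' Inverse of [read_trajectories()]: writes the
#' `cell_id,frame,t_min,x_um,y_um` CSV dialect.
#'
#' @param cohort a trajectory or list of trajectories.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(cohort, path) {
  cohort <- assert_cohort(cohort)
  rows <- lapply(cohort, function(tr) {
    data.frame(cell_id = tr$cell_id,
               frame = seq_len(nrow(tr$positions)) - 1L,
               t_min = tr$t_min,
               x_um = tr$positions[, 1],
               y_um = tr$positions[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
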