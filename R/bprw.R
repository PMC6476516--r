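#' Biased persistent random walk parameters
#'
#' The BPRW idealises a cell as a point taking `M` steps with exponential
#' lengths (mean 1). The angle of each step relative to the gradient has
#' density `b*cos(theta) + exp(p*cos(theta - theta'))/(2*pi*I0(p))`: a
#' gradient-aligned bias of strength `b` plus a von Mises persistence term
#' of strength `p` centred on the previous step angle `theta'`. The density
#' must be non-negative for all angles, which bounds the bias:
#' `b <= exp(-p) / (2*pi*I0(p))` (see [max_bias()]).
#'
#' @param b bias strength (>= 0, probability-density units).
#' @param p persistence strength (>= 0, dimensionless).
#' @param M steps per trajectory (integer >= 2). 36 matches a 9-h assay
#'   recorded every 15 min.
#' @return an object of class `bprw_params`.
#' @export
bprw_params <- function(b = 0, p = 0, M = 36) {
  stopifnot(is.numeric(b), is.numeric(p), b >= 0, p >= 0, M >= 2)
  if (b > max_bias(p) * (1 + 1e-12)) {
    stop(sprintf(
      "infeasible parameters: b = %g exceeds max_bias(p = %g) = %g (step-angle density would go negative)",
      b, p, max_bias(p)), call. = FALSE)
  }
  structure(list(b = b, p = p, M = as.integer(M)), class = "bprw_params")
}

#' Maximum feasible bias for a given persistence
#'
#' Non-negativity of the step-angle density requires that the sum of the
#' minimal values of the bias and persistence terms be non-negative, i.e.
#' `b <= exp(-p) / (2*pi*I0(p))`. At `p = 0` this is `1/(2*pi) ~ 0.16`; the
#' bound decreases strictly with `p`.
#'
#' @param p persistence strength (>= 0); vectorised.
#' @return the maximum feasible `b`.
#' @export
#' @examples
#' max_bias(0)  # 1 / (2 * pi)
max_bias <- function(p) {
  if (any(p < 0)) stop("p must be >= 0", call. = FALSE)
  # exp(-p)/(2 pi I0(p)) with exponentially scaled Bessel for large p:
  # I0(p) = besselI(p, 0, scaled) * exp(p)  =>  result = exp(-2p)/(2 pi I0e)
  exp(-2 * p) / (2 * pi * besselI(p, 0, expon.scaled = TRUE))
}

#' Step-angle density of the BPRW
#'
#' @param theta angle(s) in (-pi, pi] relative to the gradient direction.
#' @param theta_prev previous step angle (scalar).
#' @param params a [bprw_params()].
#' @return density values; non-negative for feasible parameters and
#'   normalised over (-pi, pi] for any `theta_prev`.
#' @export
step_density <- function(theta, theta_prev, params) {
  stopifnot(inherits(params, "bprw_params"))
  b <- params$b; p <- params$p
  i0e <- besselI(p, 0, expon.scaled = TRUE)
  b * cos(theta) + exp(p * (cos(theta - theta_prev) - 1)) / (2 * pi * i0e)
}

#' Sample step angles by rejection
#'
#' Rejection sampling from [step_density()] with a constant envelope equal
#' to the density's supremum, `b + exp(p)/(2*pi*I0(p))`.
#'
#' @param n number of draws.
#' @param theta_prev previous step angle.
#' @param params a [bprw_params()].
#' @return `n` angles in (-pi, pi].
#' @export
sample_angles <- function(n, theta_prev, params) {
  stopifnot(inherits(params, "bprw_params"))
  bprw_sample_angles_cpp(as.integer(n), theta_prev, params$b, params$p)
}

#' Sample a BPRW trajectory
#'
#' `M` steps with i.i.d. exponential(mean 1) lengths; the first step has no
#' previous angle, so its persistence term is replaced by the uniform
#' density `1/(2*pi)` (equivalently `p = 0` for step 1), making the bias
#' the only directional input initially. Positions are cumulative from the
#' origin, in units of the mean step length.
#'
#' @param params a [bprw_params()].
#' @param dt_min nominal recording interval attached to the returned
#'   trajectory (the walk itself is dimensionless).
#' @param cell_id identifier for the returned trajectory.
#' @return a [trajectory()] (positions in mean-step-length units).
#' @export
sample_bprw_trajectory <- function(params, dt_min = 15, cell_id = "bprw") {
  stopifnot(inherits(params, "bprw_params"))
  pos <- bprw_trajectory_cpp(params$M, params$b, params$p)
  trajectory(pos, cell_id = cell_id, dt_min = dt_min)
}

#' Ensemble of BPRW endpoints
#'
#' Simulates `n_traj` trajectories and returns per-trajectory net
#' displacement, squared displacement, path length, cos(theta) of the net
#' displacement (the per-cell CI) and DP. Used for Monte-Carlo checks of
#' the closed-form moments and for the crescent scan.
#'
#' Two stopping rules are available. `stop = "steps"` (default) is the
#' trajectory contract used everywhere else: exactly `M` discrete steps
#' with exponential lengths. `stop = "time"` is the velocity-jump reading
#' of the same walk — unit speed, exponential runs, *uniform* initial
#' direction, observed at a fixed elapsed time `M` with the last run
#' truncated (so the path length is exactly `M`). The closed-form moments
#' of [analytic_moments()] describe the fixed-time process exactly; the
#' fixed-step ensemble matches them only to O(1/M) (e.g. its mean drift is
#' `z*M` rather than `z*(M - 1 + exp(-M))` at `p = 0`), so moment
#' validation should use `stop = "time"`.
#'
#' @param params a [bprw_params()].
#' @param n_traj number of trajectories.
#' @param stop `"steps"` (M discrete steps) or `"time"` (fixed elapsed
#'   time M, the process the closed-form moments describe).
#' @return data.frame with columns `x, y, r2, path, ci, dp`.
#' @export
bprw_ensemble <- function(params, n_traj, stop = c("steps", "time")) {
  stop <- match.arg(stop)
  stopifnot(inherits(params, "bprw_params"), n_traj >= 1)
  m <- if (stop == "steps") {
    bprw_ensemble_cpp(as.integer(n_traj), params$M, params$b, params$p)
  } else {
    bprw_ensemble_time_cpp(as.integer(n_traj), as.numeric(params$M),
                           params$b, params$p)
  }
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  data.frame(x = m[, 1], y = m[, 2], r2 = r^2, path = m[, 3],
             ci = ifelse(r > 0, m[, 1] / r, NA_real_),
             dp = ifelse(m[, 3] > 0, r / m[, 3], NA_real_))
}

#' Closed-form BPRW displacement moments
#'
#' Evaluates the known mean squared displacement `<r^2>` and mean
#' displacement along the gradient `<x>` of the BPRW, in units of the mean
#' step length, exactly as given by the theory (exponential terms
#' included, no large-M truncation). The auxiliary quantities are
#' `psi = I1(p)/I0(p)` (mean cosine of the persistence term),
#' `chi = pi*b` (first cosine moment of the bias term),
#' `z = chi/(1 - psi)` and `M_tilde = M*(1 - psi)`.
#'
#' @param params a [bprw_params()].
#' @return list with `psi`, `chi`, `z`, `M_tilde`, `r2` (= `<r^2>`),
#'   `x` (= `<x>`).
#' @export
analytic_moments <- function(params) {
  stopifnot(inherits(params, "bprw_params"))
  b <- params$b; p <- params$p; M <- params$M
  psi <- besselI(p, 1, expon.scaled = TRUE) /
    besselI(p, 0, expon.scaled = TRUE)
  if (psi >= 1) stop("psi = I1/I0 must be < 1", call. = FALSE)
  chi <- pi * b
  z <- chi / (1 - psi)
  Mt <- M * (1 - psi)
  em <- exp(-Mt)
  r2 <- (z^2 * Mt^2 +
           2 * (1 - 2 * z^2 - z^2 * em) * Mt +
           2 * (2 * z^2 - 1) * (1 - em) +
           2 * z^2 * (1 - em)^2) / (1 - psi)^2
  x <- z / (1 - psi) * (Mt - 1 + em)
  list(psi = psi, chi = chi, z = z, M_tilde = Mt, r2 = r2, x = x)
}

#' Moment-based CI and DP approximations
#'
#' Approximates the ensemble chemotactic index and directional persistence
#' from the closed-form moments: `CI ~ <x>/sqrt(<r^2>)` and
#' `DP ~ sqrt(<r^2>)/M`. Because `sqrt(<r^2>) >= <r>`, these slightly
#' underestimate CI and overestimate DP relative to simulation.
#'
#' @param params a [bprw_params()].
#' @return named numeric vector `c(ci, dp)`.
#' @export
ci_dp_approx <- function(params) {
  mom <- analytic_moments(params)
  r <- sqrt(mom$r2)
  c(ci = if (mom$z == 0) 0 else mom$x / r, dp = r / params$M)
}

#' Left bounding curve of the accuracy-persistence crescent
#'
#' The zero-persistence (`p = 0`) limit of the moment approximations, with
#' the bias eliminated, gives the minimal DP attainable at a given CI for
#' a walk of `M` steps: `DP = [1 + M*(1 - CI^2)/2]^(-1/2)` (to first order
#' in 1/M). At CI = 0 this reduces to the simple random walk scaling
#' `DP ~ (M/2)^(-1/2)` for large M.
#'
#' @param M steps per trajectory.
#' @param ci_grid CI values in \[0, 1\].
#' @return DP values along the curve.
#' @export
left_bound_curve <- function(M, ci_grid) {
  stopifnot(all(ci_grid >= 0 & ci_grid <= 1))
  (1 + M * (1 - ci_grid^2) / 2)^(-1 / 2)
}

#' Right bounding curve of the crescent
#'
#' Traces the maximal-bias edge parametrically: for each persistence `p`
#' the bias is set to its feasibility limit [max_bias()] and the moment
#' approximations are evaluated. The `p = 0` endpoint (top corner,
#' maximal bias, no persistence) joins the left curve; increasing `p`
#' traces the edge toward high DP and low CI.
#'
#' @param M steps per trajectory.
#' @param p_grid ascending persistence values (>= 0).
#' @return data.frame with columns `p, b, ci, dp`.
#' @export
right_bound_curve <- function(M, p_grid) {
  stopifnot(all(p_grid >= 0), !is.unsorted(p_grid))
  rows <- lapply(p_grid, function(p) {
    b <- max_bias(p)
    cd <- ci_dp_approx(bprw_params(b = b, p = p, M = M))
    data.frame(p = p, b = b, ci = cd[["ci"]], dp = cd[["dp"]])
  })
  do.call(rbind, rows)
}

#' Scan the feasible (b, p) space and map the crescent
#'
#' Samples `n_pairs` feasible parameter pairs (`p` log-uniform over
#' \[1e-3, 20\], `b` uniform over \[0, max_bias(p)\]), simulates `n_traj`
#' trajectories for each, and computes the ensemble CI (mean cos(theta) of
#' net displacements) and mean DP. Returns the scanned points together
#' with the three analytic bounding curves: the bottom (CI = 0) segment,
#' the left minimal-DP curve and the parametric maximal-p curve.
#'
#' @param M steps per trajectory.
#' @param n_pairs number of (b, p) pairs.
#' @param n_traj trajectories per pair.
#' @param p_range range of the log-uniform persistence sampling.
#' @return list of class `crescent_scan` with elements `points`
#'   (data.frame `b, p, ci, dp, n_trajectories`) and `bounds` (list
#'   `bottom`, `left`, `right` of ordered curve points).
#' @export
crescent_scan <- function(M = 36, n_pairs = 500, n_traj = 300,
                          p_range = c(1e-3, 20)) {
  stopifnot(n_pairs >= 1, n_traj >= 1)
  p <- exp(stats::runif(n_pairs, log(p_range[1]), log(p_range[2])))
  b <- stats::runif(n_pairs) * max_bias(p)
  pts <- lapply(seq_len(n_pairs), function(i) {
    ens <- bprw_ensemble(bprw_params(b[i], p[i], M), n_traj)
    data.frame(b = b[i], p = p[i],
               ci = mean(ens$ci), dp = mean(ens$dp),
               n_trajectories = n_traj)
  })
  ci_grid <- seq(0, 1, length.out = 201)
  dp0 <- left_bound_curve(M, 0)
  structure(list(
    points = do.call(rbind, pts),
    bounds = list(
      bottom = data.frame(ci = ci_grid, dp = dp0),
      left = data.frame(ci = ci_grid, dp = left_bound_curve(M, ci_grid)),
      right = right_bound_curve(M, exp(seq(log(1e-3), log(50),
                                           length.out = 201)))
    ),
    M = M
  ), class = "crescent_scan")
}

#' @export
print.crescent_scan <- function(x, ...) {
  cat(sprintf("<crescent_scan: %d (b,p) points, M = %d>\n",
              nrow(x$points), x$M))
  invisible(x)
}
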