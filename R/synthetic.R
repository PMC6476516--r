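#' Synthetic cohort specification
#'
#' Recipe for an experiment-like trajectory cohort: `n_cells` tracks of
#' `M` steps at interval `dt_min`, generated from the biased persistent
#' random walk and scaled to a physical speed, with a fraction of
#' stationary (matrix-pinned) cells and additive centroid noise. Defaults
#' emulate the microfluidic cohorts: 40 cells, 36 steps at 15 min (9 h),
#' mean step 7.5 um (~30 um/h, i.e. tens of um/h), a quarter of cells
#' stationary, and 0.5 um position noise (sub-pixel centroid error).
#'
#' The speed scale is decoupled from (b, p): step lengths are scaled after
#' the angles are generated, treating speed as a third, largely
#' independent axis of performance.
#'
#' @param n_cells number of cells (>= 1).
#' @param M steps per trajectory.
#' @param dt_min recording interval (min).
#' @param mean_step_um mean step length (um).
#' @param b,p BPRW bias and persistence (must be feasible, see
#'   [max_bias()]).
#' @param stationary_fraction fraction of cells generated as stationary
#'   jitter (in \[0, 1)).
#' @param position_noise_um sd of isotropic Gaussian centroid noise (um).
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 40, M = 36, dt_min = 15,
                        mean_step_um = 7.5, b = 0, p = 0.3,
                        stationary_fraction = 0.25,
                        position_noise_um = 0.5, seed = 1) {
  stopifnot(n_cells >= 1, M >= 2, dt_min > 0, mean_step_um > 0,
            stationary_fraction >= 0, stationary_fraction < 1,
            position_noise_um >= 0)
  bp <- bprw_params(b = b, p = p, M = M)  # validates feasibility
  structure(list(n_cells = as.integer(n_cells), M = bp$M, dt_min = dt_min,
                 mean_step_um = mean_step_um, b = b, p = p,
                 stationary_fraction = stationary_fraction,
                 position_noise_um = position_noise_um,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic trajectory cohort
#'
#' Motile cells are BPRW tracks scaled by the mean step length; stationary
#' cells are isotropic jitter confined well inside the stationary-filter
#' threshold (maximum displacement below half the 20-um default diameter),
#' so the filter's threshold behaviour is exercised rather than trivially
#' satisfied. Isotropic Gaussian position noise is added to every frame
#' except the first. Ground-truth labels are attached as the
#' `ground_truth` attribute (data.frame `cell_id, stationary, b, p`).
#'
#' @param spec a [cohort_spec()].
#' @return list of [trajectory()] objects with a `ground_truth` attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_stat <- round(spec$stationary_fraction * spec$n_cells)
  n_mot <- spec$n_cells - n_stat
  params <- bprw_params(spec$b, spec$p, spec$M)
  cohort <- vector("list", spec$n_cells)
  stationary <- c(rep(FALSE, n_mot), rep(TRUE, n_stat))
  for (i in seq_len(spec$n_cells)) {
    id <- sprintf("cell_%03d", i)
    if (!stationary[i]) {
      pos <- bprw_trajectory_cpp(spec$M, spec$b, spec$p) * spec$mean_step_um
    } else {
      # pinned cell: jitter uniformly within a 4-um disc around the origin
      rr <- 4 * sqrt(stats::runif(spec$M))
      th <- stats::runif(spec$M, -pi, pi)
      pos <- rbind(c(0, 0), cbind(rr * cos(th), rr * sin(th)))
    }
    if (spec$position_noise_um > 0) {
      noise <- matrix(stats::rnorm(2 * spec$M, sd = spec$position_noise_um),
                      ncol = 2)
      pos[-1, ] <- pos[-1, ] + noise
    }
    cohort[[i]] <- trajectory(pos, cell_id = id, dt_min = spec$dt_min)
  }
  attr(cohort, "ground_truth") <- data.frame(
    cell_id = vapply(cohort, `[[`, character(1), "cell_id"),
    stationary = stationary, b = spec$b, p = spec$p)
  cohort
}

#' Gradient-condition series specification
#'
#' Emulates a gradient dose-response design: one cohort spec per gradient
#' strength, replicated. The bias follows a saturating map
#' `b(g) = b_inf * (1 - exp(-g / g_half))` — zero without a gradient,
#' rising and then saturating, so the accuracy saturates between the two
#' largest gradients — while the persistence `p` is held constant across
#' conditions (sensing and persistence decoupled).
#'
#' @param g_series gradient strengths (nM/mm).
#' @param b_inf asymptotic bias (must be feasible at `p`).
#' @param g_half gradient scale of the saturating map (nM/mm).
#' @param p constant persistence.
#' @param replicates replicate cohorts per condition.
#' @param base a [cohort_spec()] providing n_cells, M, dt, speed, noise.
#' @return an object of class `condition_series`.
#' @export
condition_series <- function(g_series = c(0, 1, 5, 50), b_inf = 0.03,
                             g_half = 1.2, p = 0.3, replicates = 3,
                             base = cohort_spec()) {
  stopifnot(all(g_series >= 0), replicates >= 1,
            inherits(base, "cohort_spec"))
  bprw_params(b_inf, p, base$M)  # feasibility of the asymptote
  b_map <- b_inf * (1 - exp(-g_series / g_half))
  structure(list(g_series = g_series, b = b_map, p = p,
                 replicates = as.integer(replicates), base = base),
            class = "condition_series")
}

#' Generate a condition series on disk
#'
#' Writes one trajectory CSV per condition per replicate (dialect of
#' [write_trajectories()]) plus a `manifest.json` recording the
#' ground-truth `(g, b, p)` and per-file seeds.
#'
#' @param series a [condition_series()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   `file.path(dir, "manifest.json")`).
#' @export
generate_condition_series <- function(series, dir) {
  stopifnot(inherits(series, "condition_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(p = series$p, conditions = list())
  k <- 0L
  for (ci in seq_along(series$g_series)) {
    for (rep in seq_len(series$replicates)) {
      k <- k + 1L
      spec <- series$base
      spec$b <- series$b[ci]
      spec$p <- series$p
      spec$seed <- derive_trial_seed(series$base$seed, k)
      fname <- sprintf("traj_g%g_rep%d.csv", series$g_series[ci], rep)
      write_trajectories(generate_cohort(spec), file.path(dir, fname))
      manifest$conditions[[k]] <- list(
        file = fname, g_nM_per_mm = series$g_series[ci],
        replicate = rep, b = series$b[ci], p = series$p,
        seed = spec$seed)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Recover BPRW parameters from an observed cohort
#'
#' Inverts the moment approximations numerically: the cohort's ensemble CI
#' (mean cos(theta) of net displacements) and mean DP are matched to
#' [ci_dp_approx()] by minimising the squared CI-DP distance over the
#' feasible (b, p) region (grid search followed by Nelder-Mead polish on
#' the transformed coordinates `b = fraction * max_bias(p)`,
#' `p = exp(log_p)`). Stationary cells are filtered out first.
#'
#' @param cohort list of [trajectory()] objects (>= 20 motile tracks).
#' @param M steps per trajectory used in the theory (defaults to the
#'   cohort's own step count).
#' @param diameter_um stationary-filter threshold.
#' @return list with `b_hat`, `p_hat`, `ci_obs`, `dp_obs`, `distance`
#'   (residual CI-DP distance) and `warning` (TRUE when the observed point
#'   lies farther than 0.2 from the crescent, i.e. outside the model's
#'   reach).
#' @export
recover_parameters <- function(cohort, M = NULL, diameter_um = 20) {
  cohort <- filter_stationary(assert_cohort(cohort), diameter_um)$kept
  if (length(cohort) < 20) {
    stop("need at least 20 motile tracks for parameter recovery",
         call. = FALSE)
  }
  if (is.null(M)) M <- nrow(cohort[[1]]$positions) - 1L
  ci_obs <- mean(vapply(cohort, chemotactic_index, numeric(1)))
  dp_obs <- mean(vapply(cohort, directional_persistence, numeric(1)))
  obj <- function(par) {
    par <- unname(as.numeric(par))
    frac <- stats::plogis(par[1])
    p <- exp(par[2])
    b <- frac * max_bias(p)
    cd <- ci_dp_approx(bprw_params(b, p, M))
    (cd[["ci"]] - ci_obs)^2 + (cd[["dp"]] - dp_obs)^2
  }
  # coarse grid, then polish
  grid <- expand.grid(lf = stats::qlogis(seq(0.02, 0.98, length.out = 25)),
                      lp = log(exp(seq(log(1e-3), log(30),
                                       length.out = 25))))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  p_hat <- exp(opt$par[2])
  b_hat <- stats::plogis(opt$par[1]) * max_bias(p_hat)
  dist <- sqrt(opt$value)
  list(b_hat = b_hat, p_hat = p_hat, ci_obs = ci_obs, dp_obs = dp_obs,
       distance = dist, warning = dist > 0.2)
}
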