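test_that("trajectory constructor enforces its invariants", {
  expect_error(trajectory(matrix(c(0, 0), 1, 2)), "at least 2")
  expect_error(trajectory(rbind(c(0, 0), c(1, NA))), "finite")
  expect_error(trajectory(rbind(c(0, 0), c(1, 0)), t_min = c(0, 0)),
               "increasing")
  expect_error(trajectory(rbind(c(0, 0), c(1, 0), c(2, 0)),
                          t_min = c(0, 15, 40)), "uniform")
  tr <- trajectory(rbind(c(0, 0), c(1, 0)), gradient_axis = c(3, 0))
  expect_equal(tr$gradient_axis, c(1, 0))  # normalised
})

test_that("chemotactic index matches hand-computed displacements", {
  expect_equal(chemotactic_index(traj_from_points(c(0, 0), c(10, 0))), 1)
  expect_equal(chemotactic_index(traj_from_points(c(0, 0), c(3, 4))), 0.6)
  # four symmetric endpoints average to zero
  d <- 5
  ends <- list(c(d, 0), c(-d, 0), c(0, d), c(0, -d))
  cis <- vapply(ends, function(e) {
    chemotactic_index(traj_from_points(c(0, 0), e))
  }, numeric(1))
  expect_equal(mean(cis), 0)
  expect_error(chemotactic_index(traj_from_points(c(0, 0), c(1, 0), c(0, 0))),
               "zero net displacement")
})

test_that("directional persistence is displacement over path length", {
  expect_equal(directional_persistence(
    traj_from_points(c(0, 0), c(1, 0), c(2, 0))), 1)
  expect_equal(directional_persistence(
    traj_from_points(c(0, 0), c(1, 0), c(0, 0))), 0)
  expect_error(directional_persistence(
    traj_from_points(c(0, 0), c(0, 0), c(0, 0))), "zero path")
})

test_that("random-walk ensemble DP matches the Monte-Carlo oracle", {
  # independent oracle: mean DP of 1e4 plain-R simple random walks (M = 36)
  set.seed(101)
  M <- 36
  oracle_dp <- replicate(1e4, {
    pos <- oracle_random_walk(M)
    st <- diff(pos)
    sqrt(sum(pos[M + 1, ]^2)) / sum(sqrt(rowSums(st^2)))
  })
  # package pipeline on package-sampled unbiased walks
  set.seed(202)
  pp <- bprw_params(0, 0, M)
  dp <- vapply(seq_len(1e4), function(i) {
    directional_persistence(sample_bprw_trajectory(pp))
  }, numeric(1))
  se <- sqrt(stats::var(oracle_dp) / 1e4 + stats::var(dp) / 1e4)
  expect_lt(abs(mean(dp) - mean(oracle_dp)), 3 * se)
  # the large-M asymptote (M/2)^(-1/2) is approached with a finite-M
  # offset; at M = 36 the oracle sits above it by order 1/sqrt(M)
  expect_lt(abs(mean(oracle_dp) - (M / 2)^(-1 / 2)) / (M / 2)^(-1 / 2),
            0.15)
  # mean CI of an unbiased ensemble is 0 within 3 SE
  set.seed(303)
  ci <- vapply(seq_len(1e4), function(i) {
    chemotactic_index(sample_bprw_trajectory(pp))
  }, numeric(1))
  expect_lt(abs(mean(ci)), 3 * sd(ci) / sqrt(length(ci)))
})

test_that("mean speed averages per-interval speeds in um/h", {
  expect_equal(mean_speed(traj_from_points(c(0, 0), c(10, 0), c(20, 0))), 40)
  expect_equal(mean_speed(traj_from_points(c(0, 0), c(5, 0), c(20, 0))), 40)
  expect_equal(mean_speed(traj_from_points(c(1, 1), c(1, 1), c(1, 1))), 0)
})

test_that("autocorrelation time integrates the direction correlation", {
  # straight line: correlation is identically 1, integral = max_lag * dt
  straight <- trajectory(cbind(0:10 * 3, 0), dt_min = 15)
  expect_equal(autocorrelation_time(straight, max_lag = 4), 4 * 15)
  expect_equal(autocorrelation_time(straight), 5 * 15)  # default M/2
  expect_error(autocorrelation_time(straight, max_lag = 10), "max_lag")
  # i.i.d. directions: only lag 0 contributes; trapezoid gives dt/2.
  # Oracle: expectation over resampled angle sets, computed directly.
  set.seed(11)
  taus <- replicate(400, {
    th <- stats::runif(30, -pi, pi)
    pos <- rbind(c(0, 0), cbind(cumsum(cos(th)), cumsum(sin(th))))
    autocorrelation_time(trajectory(pos, dt_min = 15), max_lag = 10)
  })
  expect_lt(abs(mean(taus) - 15 / 2), 3 * sd(taus) / sqrt(length(taus)))
})

test_that("tau_AC increases with DP across persistence levels", {
  set.seed(21)
  mean_tau_dp <- vapply(c(0, 1, 3), function(p) {
    pp <- bprw_params(0, p, 36)
    vals <- vapply(seq_len(300), function(i) {
      tr <- sample_bprw_trajectory(pp)
      c(autocorrelation_time(tr), directional_persistence(tr))
    }, numeric(2))
    rowMeans(vals)
  }, numeric(2))
  expect_true(all(diff(mean_tau_dp[1, ]) > 0))  # tau_AC rises with p
  expect_true(all(diff(mean_tau_dp[2, ]) > 0))  # and so does DP
})

test_that("stationary filter partitions by maximum displacement", {
  near <- traj_from_points(c(0, 0), c(5, 0), c(0, 3))    # max disp 5
  far <- traj_from_points(c(0, 0), c(25, 0), c(10, 0))   # max disp 25
  parts <- filter_stationary(list(near, far), diameter_um = 20)
  expect_length(parts$excluded, 1)
  expect_length(parts$kept, 1)
  expect_identical(parts$kept[[1]]$cell_id, far$cell_id)
  # max displacement matters even if the track returns home
  roam <- traj_from_points(c(0, 0), c(30, 0), c(0, 0))
  expect_length(filter_stationary(list(roam), 20)$kept, 1)
  # partition reconstitutes the input exactly
  set.seed(31)
  cohort <- generate_cohort(cohort_spec(n_cells = 30, seed = 5))
  parts <- filter_stationary(cohort, 20)
  expect_equal(length(parts$kept) + length(parts$excluded), length(cohort))
  ids <- sort(vapply(c(parts$kept, parts$excluded), `[[`, character(1),
                     "cell_id"))
  expect_equal(ids, sort(vapply(cohort, `[[`, character(1), "cell_id")))
})

test_that("group comparison reproduces Mann-Whitney behaviour", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  sep <- compare_groups(c(1, 2, 3), c(101, 102, 103))
  expect_equal(unname(sep$statistic), 0)  # complete separation, U = 0
  expect_lte(sep$statistic, sep$n1 * sep$n2)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
  # shifted generators are detected reliably: two n = 40 samples two
  # pooled SDs apart reject at 5% in at least 95% of 200 seeded repeats
  set.seed(41)
  hits <- vapply(seq_len(200), function(i) {
    a <- stats::rnorm(40)
    b <- stats::rnorm(40, mean = 2)
    compare_groups(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cohort and replicate summaries compute medians and SEM", {
  rs <- replicate_summary(c(0.1, 0.2, 0.3))
  expect_equal(rs$mean_of_medians, 0.2)
  expect_equal(rs$sem, sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_error(replicate_summary(0.5), "single replicate")
  # identical trajectories: median equals the common value
  tr <- traj_from_points(c(0, 0), c(30, 0), c(60, 5), c(85, 10), c(110, 2))
  cohort <- lapply(1:5, function(i) {
    tr$cell_id <- paste0("c", i); tr
  })
  s <- summarize_cohort(cohort)
  expect_equal(s$median_ci, chemotactic_index(tr))
  expect_equal(s$n_cells, 5)
  expect_true(s$median_dp >= min(s$metrics$dp) &&
                s$median_dp <= max(s$metrics$dp))
})

test_that("metrics are invariant under the expected rigid rotations", {
  set.seed(51)
  for (i in 1:10) {
    pos <- oracle_random_walk(12) * 5
    ang <- stats::runif(1, -pi, pi)
    tr <- trajectory(pos)
    rot <- trajectory(rotate2(pos, ang))
    rot_both <- trajectory(rotate2(pos, ang),
                           gradient_axis = rotate2(rbind(c(1, 0)), ang))
    # CI invariant when trajectory and axis rotate together
    expect_equal(chemotactic_index(rot_both), chemotactic_index(tr))
    # DP, speed, tau_AC invariant under rotating the trajectory alone
    expect_equal(directional_persistence(rot), directional_persistence(tr))
    expect_equal(mean_speed(rot), mean_speed(tr))
    expect_equal(autocorrelation_time(rot, 5), autocorrelation_time(tr, 5))
    # DP * path length equals net displacement to machine precision
    st <- diff(pos)
    expect_equal(directional_persistence(tr) * sum(sqrt(rowSums(st^2))),
                 sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)))
    expect_lte(chemotactic_index(tr)^2, 1)
  }
})

test_that("trajectory CSV round-trips and metrics table is complete", {
  cohort <- generate_cohort(cohort_spec(n_cells = 8, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_trajectories(cohort, path)
  back <- read_trajectories(path)
  expect_equal(length(back), length(cohort))
  expect_equal(back[[1]]$positions, cohort[[1]]$positions,
               ignore_attr = TRUE)
  expect_equal(back[[3]]$t_min, cohort[[3]]$t_min)
  m <- cohort_metrics(cohort)
  expect_named(m, c("cell_id", "ci", "dp", "speed_um_h", "tau_ac_min",
                    "excluded"))
  expect_equal(nrow(m), length(cohort))
  expect_true(all(is.na(m$ci[m$excluded])))
  expect_true(all(!is.na(m$ci[!m$excluded])))
})
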