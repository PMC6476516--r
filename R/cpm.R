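#' Cellular Potts model parameters
#'
#' Parameter set for the single-cell lattice Monte Carlo simulator. The
#' defaults are the calibrated values for MDA-MB-231 cells chemotaxing up
#' a TGF-beta gradient in a 3-D collagen assay: a 9-h run recorded every
#' 15 min, background concentration 2.5 nM, gradient 5 nM/mm, relaxed area
#' 400 um^2 on a 2-um lattice (~100 sites per cell), contact energy
#' alpha = 2 um^-1 (of order 1/ell, the mobile-but-cohesive crossover),
#' area stiffness lambda = 0.01 um^-4 (typical area fluctuations
#' lambda^(-1/2)/A0 = 2.5%), update interval tau = 100 s (well above the
#' ~0.4 s site-diffusion time at D ~ 10 um^2/s, below the recording
#' interval), 10,000 receptors (sets where the accuracy saturates with
#' gradient strength), sensing strength eps = 56 and persistence strength
#' eta = 107 (calibrated against the measured CI and DP at 5 nM/mm), and
#' polarization decay rate r = 0.01 s^-1, i.e. a memory time equal to tau.
#'
#' @param T_h total simulated time (h).
#' @param dt_min recording interval (min); must be a multiple of `tau_s`
#'   in seconds.
#' @param c_nM background concentration at the domain centre (nM).
#' @param g_nM_per_mm gradient along +x (nM/mm, >= 0).
#' @param A0_um2 relaxed cell area (um^2).
#' @param ell_um lattice spacing (um).
#' @param alpha_per_um cell-environment contact energy (um^-1).
#' @param lambda_per_um4 area-deviation energy (um^-4).
#' @param tau_s Monte Carlo update interval (s).
#' @param N_receptors total receptor number.
#' @param eps gradient-sensing (bias) strength.
#' @param eta persistence (alignment) strength.
#' @param r_per_s polarization decay rate (s^-1); `r_per_s * tau_s` must
#'   not exceed 1 (larger values overshoot the decay).
#' @param domain lattice width/height in sites.
#' @param margin boundary margin in sites; the run aborts if the cell
#'   comes within `margin` sites of the domain edge.
#' @param neighborhood 4 (default) or 8, the copy-attempt neighbourhood.
#' @return an object of class `cpm_params`.
#' @export
cpm_params <- function(T_h = 9, dt_min = 15, c_nM = 2.5, g_nM_per_mm = 5,
                       A0_um2 = 400, ell_um = 2, alpha_per_um = 2,
                       lambda_per_um4 = 0.01, tau_s = 100,
                       N_receptors = 10000, eps = 56, eta = 107,
                       r_per_s = 0.01, domain = c(100, 100), margin = 5,
                       neighborhood = 4) {
  stopifnot(T_h > 0, dt_min > 0, c_nM > 0, g_nM_per_mm >= 0, A0_um2 > 0,
            ell_um > 0, alpha_per_um > 0, lambda_per_um4 > 0, tau_s > 0,
            N_receptors > 0, r_per_s > 0, margin >= 1,
            length(domain) == 2, all(domain > 2 * margin),
            neighborhood %in% c(4, 8))
  if (tau_s >= dt_min * 60) {
    stop("`tau_s` must be smaller than the recording interval", call. = FALSE)
  }
  if (abs((dt_min * 60) %% tau_s) > 1e-9) {
    stop("recording interval must be a multiple of `tau_s`", call. = FALSE)
  }
  if (r_per_s * tau_s > 1 + 1e-12) {
    stop("r * tau > 1 is unstable (polarization decay would overshoot)",
         call. = FALSE)
  }
  side <- sqrt(A0_um2 / ell_um^2)
  if (abs(side - round(side)) > 1e-9) {
    stop("A0/ell^2 must be a perfect square for the initial square cell",
         call. = FALSE)
  }
  structure(list(
    T_h = T_h, dt_min = dt_min, c_nM = c_nM, g_nM_per_mm = g_nM_per_mm,
    A0_um2 = A0_um2, ell_um = ell_um, alpha_per_um = alpha_per_um,
    lambda_per_um4 = lambda_per_um4, tau_s = tau_s,
    N_receptors = N_receptors, eps = eps, eta = eta, r_per_s = r_per_s,
    domain = as.integer(domain), margin = as.integer(margin),
    neighborhood = as.integer(neighborhood)
  ), class = "cpm_params")
}

#' Read CPM parameters from a JSON config
#'
#' The config keys mirror the [cpm_params()] argument names (units in the
#' names, e.g. `tau_s`, `g_nM_per_mm`); missing keys take the defaults.
#'
#' @param path path to a JSON file.
#' @return a `cpm_params` object.
#' @export
read_cpm_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cpm_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(cpm_params, cfg)
}

#' Parameter sets for a gradient dose-response series
#'
#' In the source-sink microfluidic device the background concentration at
#' the cell channel's middle is tied to the gradient: a source at
#' `g * L` nM and a sink at 0 across a channel of width `L` give
#' `c = g * L / 2` at the middle (for the reference gradient 5 nM/mm and
#' the 1-mm channel this is the 2.5 nM default of [cpm_params()]).
#' Sweeping `g` while holding `c` fixed would break that coupling — and
#' with it the receptor-saturation mechanism, which needs the ambient
#' ligand density to approach the per-site receptor number at strong
#' gradients. This helper builds one [cpm_params()] per gradient with the
#' coupled background (floored at a tiny positive value for `g = 0`, the
#' attractant-free control).
#'
#' @param g_series gradient strengths (nM/mm).
#' @param device_width_mm width of the channel along the gradient (mm).
#' @param ... further arguments passed to [cpm_params()] (e.g. `r_per_s`,
#'   `domain`).
#' @return list of `cpm_params`, one per gradient.
#' @export
cpm_gradient_series <- function(g_series = c(0, 1, 5, 50),
                                device_width_mm = 1, ...) {
  lapply(g_series, function(g) {
    cpm_params(g_nM_per_mm = g,
               c_nM = max(g * device_width_mm / 2, 1e-9), ...)
  })
}

#' Initial CPM state
#'
#' A square cell of `sqrt(A0/ell^2)` sites a side at the domain centre,
#' with zero polarization. Positions are measured in micrometres from the
#' domain centre (where the background concentration applies).
#'
#' @param params a [cpm_params()].
#' @return an object of class `cpm_state`: list with `grid` (integer
#'   matrix, 1 = cell), `p_vec`, `com_um`, `t_s`.
#' @export
cpm_init_state <- function(params) {
  stopifnot(inherits(params, "cpm_params"))
  W <- params$domain[1]; H <- params$domain[2]
  side <- round(sqrt(params$A0_um2 / params$ell_um^2))
  grid <- matrix(0L, W, H)
  x0 <- floor((W - side) / 2) + 1
  y0 <- floor((H - side) / 2) + 1
  grid[x0:(x0 + side - 1), y0:(y0 + side - 1)] <- 1L
  structure(list(grid = grid, p_vec = c(0, 0),
                 com_um = cpm_com(grid, params$ell_um), t_s = 0),
            class = "cpm_state")
}

## centre of mass of the cell in um relative to the domain centre
cpm_com <- function(grid, ell_um) {
  w <- which(grid == 1L, arr.ind = TRUE)
  centre <- (dim(grid) + 1) / 2
  c(mean(w[, 1]) - centre[1], mean(w[, 2]) - centre[2]) * ell_um
}

#' CPM energy of a state
#'
#' `u = alpha*L + lambda*(A - A0)^2`, with `L` the number of cell-medium
#' boundary edges under 4-adjacency times the lattice spacing (um) and `A`
#' the cell site count times `ell^2` (um^2).
#'
#' @param state a [cpm_init_state()] state (or any list with a `grid`).
#' @param params a [cpm_params()].
#' @return the (dimensionless) energy.
#' @export
cpm_energy <- function(state, params) {
  g <- state$grid
  if (!sum(g)) stop("cell is empty", call. = FALSE)
  W <- nrow(g); H <- ncol(g)
  gp <- matrix(0L, W + 2, H + 2)
  gp[2:(W + 1), 2:(H + 1)] <- g
  edges <- sum(gp[2:(W + 1), 2:(H + 1)] != gp[1:W, 2:(H + 1)]) +
    sum(gp[2:(W + 1), 2:(H + 1)] != gp[3:(W + 2), 2:(H + 1)]) +
    sum(gp[2:(W + 1), 2:(H + 1)] != gp[2:(W + 1), 1:H]) +
    sum(gp[2:(W + 1), 2:(H + 1)] != gp[2:(W + 1), 3:(H + 2)])
  L <- edges / 2 * params$ell_um  # each boundary edge counted twice
  A <- sum(g) * params$ell_um^2
  params$alpha_per_um * L + params$lambda_per_um4 * (A - params$A0_um2)^2
}

#' Copy-attempt acceptance probability
#'
#' `P = exp(-(du - w))` when `du - w > 0`, and 1 otherwise.
#'
#' @param delta_u energy change of the attempt.
#' @param w polarization bias term (see [cpm_bias_term()]).
#' @return acceptance probability; vectorised.
#' @export
cpm_acceptance_probability <- function(delta_u, w) {
  d <- delta_u - w
  ifelse(d > 0, exp(-d), 1)
}

#' Polarization bias of a copy attempt
#'
#' `w = dx . p`: movement parallel to the polarization vector raises the
#' acceptance probability.
#'
#' @param delta_x 2-D centre-of-mass change the attempt would cause (um).
#' @param p_vec polarization vector.
#' @return the scalar bias term.
#' @export
cpm_bias_term <- function(delta_x, p_vec) {
  sum(as.numeric(delta_x) * as.numeric(p_vec))
}

#' Stochastic gradient-sensing sample
#'
#' For each cell site, the number of detected molecules `n_i` is the
#' minimum of a Poisson receptor count (mean `N` / site count) and a
#' Poisson ligand count (mean `(c + g*x_i) * ell^3` converted to
#' molecules; `x_i` in um from the domain centre, concentrations clamped
#' at 0). The sensing vector is the site average
#' `q = <(n_i - n_bar) * r_hat_i>`, with `r_hat_i` the unit vector from
#' the centre of mass to the site (a site at the centre of mass
#' contributes 0). Taking the minimum encodes receptor saturation: sites
#' whose receptors are outnumbered by ligand report the receptor count,
#' which carries no positional information. The subtraction of the mean
#' makes the readout adaptive.
#'
#' @param state a CPM state.
#' @param params a [cpm_params()].
#' @param n number of independent draws.
#' @return for `n = 1`, list with `n_i`, `n_bar`, `q_vec`, `r_hat`,
#'   `site_um`; for `n > 1` the same list but with `q_vec` an `n x 2`
#'   matrix of sensing vectors (and per-site fields from the last draw).
#' @export
cpm_sample_sensing <- function(state, params, n = 1) {
  stopifnot(inherits(params, "cpm_params"), n >= 1)
  res <- cpm_sense_cpp(state$grid, params$ell_um, params$c_nM,
                       params$g_nM_per_mm, params$N_receptors,
                       as.integer(n))
  q <- res$q
  list(n_i = as.numeric(res$n_i), n_bar = res$n_bar,
       q_vec = if (n == 1) as.numeric(q[1, ]) else q,
       r_hat = res$r_hat, site_um = res$site_um)
}

#' Polarization-vector update
#'
#' Applied once per update interval `tau`:
#' `p <- p + r*tau*(-p + eta*dx_hat + eps*q)`, i.e. exponential decay at
#' rate `r` plus alignment with the last interval's displacement direction
#' (strength `eta`) and with the sensing vector (strength `eps`). When the
#' interval displacement is zero the direction is undefined and the `eta`
#' term is skipped. With the default `r*tau = 1` the memory is fully reset
#' each interval: `p = eta*dx_hat + eps*q`.
#'
#' @param p_vec current polarization vector.
#' @param step_displacement centre-of-mass displacement over the last
#'   interval (um); only its direction is used.
#' @param q_vec sensing vector.
#' @param params a [cpm_params()].
#' @return the updated polarization vector.
#' @export
cpm_update_polarization <- function(p_vec, step_displacement, q_vec,
                                    params) {
  stopifnot(inherits(params, "cpm_params"))
  rt <- params$r_per_s * params$tau_s
  if (rt > 1 + 1e-12) {
    stop("r * tau > 1 is unstable (polarization decay would overshoot)",
         call. = FALSE)
  }
  nrm <- sqrt(sum(step_displacement^2))
  u <- if (nrm > 0) step_displacement / nrm else c(0, 0)
  p_vec + rt * (-p_vec + params$eta * u + params$eps * q_vec)
}

#' Advance a CPM state
#'
#' Runs `n_steps` Monte Carlo update steps. Each step performs S copy
#' attempts (S = domain site count): a random site and a random neighbour
#' are chosen and the source label is proposed onto the target; flips that
#' would break the cell's simple connectivity (or empty it) are rejected
#' outright, the rest are accepted with [cpm_acceptance_probability()].
#' Time then advances by `tau`, the sensing vector is resampled and the
#' polarization updated. Uses R's global RNG (seed with [set.seed()] for
#' reproducibility). Aborts with an error if the cell reaches the domain
#' boundary margin.
#'
#' @param state a [cpm_init_state()] state.
#' @param params a [cpm_params()].
#' @param n_steps number of update steps.
#' @param engine `"event"` (default) or `"exhaustive"`. Both execute the
#'   same S-attempt process: the exhaustive engine loops over every
#'   attempt literally, while the event engine jumps over the no-op
#'   attempts (both labels equal) with exact geometric gap sampling —
#'   only attempts that pick a cell-medium boundary edge can change the
#'   state, and between such attempts the crossing probability is
#'   constant. The event engine's cost scales with the cell boundary, not
#'   the domain, and the two are statistically indistinguishable.
#' @return the advanced `cpm_state`, with extra fields `area_um2` (area
#'   after each step) recording the run.
#' @export
cpm_step <- function(state, params, n_steps = 1,
                     engine = c("event", "exhaustive")) {
  engine <- match.arg(engine)
  stopifnot(inherits(state, "cpm_state"), inherits(params, "cpm_params"),
            n_steps >= 1)
  res <- cpm_run_cpp(state$grid, state$p_vec, as.integer(n_steps), 0L,
                     params$ell_um, params$alpha_per_um,
                     params$lambda_per_um4, params$A0_um2, params$c_nM,
                     params$g_nM_per_mm, params$N_receptors, params$eps,
                     params$eta, params$r_per_s, params$tau_s,
                     params$margin, params$neighborhood,
                     engine == "event")
  structure(list(grid = res$grid, p_vec = as.numeric(res$p_vec),
                 com_um = as.numeric(res$com_um),
                 t_s = state$t_s + n_steps * params$tau_s,
                 area_um2 = as.numeric(res$area_um2)),
            class = "cpm_state")
}

#' Deterministic per-trial seed derivation
#'
#' Trial `i` of a run with master seed `s` uses seed
#' `(s + 9973 * i) mod (2^31 - 1)`, so any single trial can be reproduced
#' independently.
#'
#' @param master_seed integer master seed.
#' @param trial trial index (1-based).
#' @return the derived seed.
#' @export
derive_trial_seed <- function(master_seed, trial) {
  as.integer((as.numeric(master_seed) + 9973 * as.numeric(trial)) %%
               (2^31 - 1))
}

#' Run CPM chemotaxis trials
#'
#' Each trial starts a square cell of area `A0` at the domain centre with
#' zero polarization, runs `T/tau` update steps and records the centre of
#' mass every `dt`. Returns the recorded tracks as [trajectory()] objects
#' (um, gradient along +x).
#'
#' @param params a [cpm_params()].
#' @param n_trials number of independent trials.
#' @param seed optional master seed; per-trial seeds are derived with
#'   [derive_trial_seed()]. When `NULL` the current RNG state is used and
#'   trials follow one another on the same stream.
#' @param engine attempt engine, see [cpm_step()].
#' @return list of `trajectory` objects (one per trial).
#' @export
run_cpm <- function(params, n_trials = 1, seed = NULL,
                    engine = c("event", "exhaustive")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "cpm_params"), n_trials >= 1)
  n_steps <- round(params$T_h * 3600 / params$tau_s)
  record_every <- round(params$dt_min * 60 / params$tau_s)
  init <- cpm_init_state(params)
  lapply(seq_len(n_trials), function(i) {
    if (!is.null(seed)) set.seed(derive_trial_seed(seed, i))
    res <- cpm_run_cpp(init$grid, c(0, 0), as.integer(n_steps),
                       as.integer(record_every), params$ell_um,
                       params$alpha_per_um, params$lambda_per_um4,
                       params$A0_um2, params$c_nM, params$g_nM_per_mm,
                       params$N_receptors, params$eps, params$eta,
                       params$r_per_s, params$tau_s, params$margin,
                       params$neighborhood, engine == "event")
    trajectory(res$path, cell_id = sprintf("trial_%d", i),
               dt_min = params$dt_min)
  })
}
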