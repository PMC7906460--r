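#' Coupling-radius schedule for flocking experiments
#'
#' Builds the interaction-radius protocol r(t) as a vectorized function of the
#' step index. Three kinds are supported: `"constant"` (r = r0 throughout);
#' `"ramp"` (r0 for `t_low` steps, then a linear increase to r1 over `t_ramp`
#' steps, then r1); and `"chirp"` (sinusoidal oscillation between r0 and r1
#' with linearly increasing frequency, for probing the response speed of
#' order to parameter change).
#'
#' @param kind schedule type.
#' @param r0 low radius (default 0.0065, torus units).
#' @param r1 high radius (default 0.06).
#' @param t_low steps held at r0 before the ramp (default 800).
#' @param t_ramp ramp duration in steps (default 400).
#' @param f0 chirp starting frequency in cycles/step (default 1/2000).
#' @param chirp_rate linear growth of the chirp frequency per step
#'   (default 2e-6).
#' @return function mapping integer step (1-based) to radius.
#' @export
radius_schedule <- function(kind = c("ramp", "constant", "chirp"),
                            r0 = 0.0065, r1 = 0.06,
                            t_low = 800L, t_ramp = 400L,
                            f0 = 1 / 2000, chirp_rate = 2e-6) {
  kind <- match.arg(kind)
  force(r0); force(r1); force(t_low); force(t_ramp); force(f0); force(chirp_rate)
  f <- switch(kind,
    constant = function(t) rep_len(r0, length(t)),
    ramp = function(t) {
      frac <- pmin(pmax((t - t_low) / t_ramp, 0), 1)
      r0 + (r1 - r0) * frac
    },
    chirp = function(t) {
      phase <- 2 * pi * (f0 * t + 0.5 * chirp_rate * t^2)
      (r0 + r1) / 2 - (r1 - r0) / 2 * cos(phase)
    }
  )
  attr(f, "kind") <- kind
  attr(f, "params") <- list(r0 = r0, r1 = r1, t_low = t_low, t_ramp = t_ramp,
                            f0 = f0, chirp_rate = chirp_rate)
  f
}

#' Configuration for a flocking simulation
#'
#' @param n number of agents (default 500).
#' @param speed fixed agent speed in torus units per step (default 1/320).
#' @param noise standard deviation of the gaussian heading noise, radians
#'   (default pi/5).
#' @param schedule radius schedule from [radius_schedule()], or a single
#'   number for a constant radius.
#' @param steps number of time steps (default 2000).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param aligned_start if `TRUE` all agents start with heading 0 instead of
#'   uniform random headings.
#' @return list of class `flock_config`.
#' @export
flock_config <- function(n = 500L, speed = 1 / 320, noise = pi / 5,
                         schedule = radius_schedule("ramp"),
                         steps = 2000L, seed = NULL, aligned_start = FALSE) {
  if (is.numeric(schedule) && length(schedule) == 1) {
    schedule <- radius_schedule("constant", r0 = schedule)
  }
  stopifnot(n >= 2, speed > 0, noise >= 0, steps >= 1)
  structure(
    list(n = as.integer(n), speed = speed, noise = noise,
         schedule = schedule, steps = as.integer(steps),
         seed = seed, aligned_start = isTRUE(aligned_start)),
    class = "flock_config"
  )
}

#' One synchronous update of the Vicsek flocking model
#'
#' Every agent adopts the circular mean heading (angle of the summed unit
#' heading vectors) of all agents within toroidal distance `r`, itself
#' included, plus an independent gaussian perturbation, then advances by
#' `speed` along its new heading; positions wrap on the unit torus. All
#' agents update from the previous state simultaneously.
#'
#' @param pos n x 2 matrix of positions in `[0, 1)^2`.
#' @param theta headings in radians.
#' @param r interaction radius.
#' @param noise heading noise SD (radians).
#' @param speed step length.
#' @return list with updated `pos` and `theta` (wrapped to `[0, 2*pi)`).
#' @export
flock_step <- function(pos, theta, r, noise, speed) {
  Dm <- position_distance(pos, geometry = "torus", period = 1)
  A <- Dm <= r
  ux <- cos(theta); uy <- sin(theta)
  sx <- A %*% ux; sy <- A %*% uy
  new_theta <- atan2(sy, sx) + stats::rnorm(length(theta), 0, noise)
  new_theta <- as.numeric(new_theta) %% (2 * pi)
  new_pos <- (pos + speed * cbind(cos(new_theta), sin(new_theta))) %% 1
  list(pos = new_pos, theta = new_theta)
}

#' Mean velocity of a flock
#'
#' The average of the agents' unit heading vectors scaled by the common
#' speed; its magnitude (in `[0, speed]`) is the standard order parameter of
#' the flocking model, near `speed` for coherent motion and near zero for
#' incoherent motion.
#'
#' @param theta headings in radians.
#' @param speed common agent speed.
#' @return list with `vector` (length 2) and `magnitude`.
#' @export
mean_velocity <- function(theta, speed = 1) {
  v <- speed * c(mean(cos(theta)), mean(sin(theta)))
  list(vector = v, magnitude = sqrt(sum(v^2)))
}

#' Simulate the flocking model
#'
#' Runs the Vicsek-type model under the configured radius schedule and
#' returns a tidy trajectory. Velocities stored per frame are the
#' displacement actually taken into that frame (`speed` times the heading
#' unit vector), so downstream velocity-profile metrics see the motion the
#' model generated.
#'
#' @param cfg a [flock_config()].
#' @return tibble with columns `frame`, `agent_id`, `x`, `y`, `vx`, `vy`, of
#'   class `flock_trajectory`, with attributes `headings` (steps x n matrix),
#'   `radius` (per-step r) and `config`.
#' @export
simulate_flock <- function(cfg) {
  stopifnot(inherits(cfg, "flock_config"))
  runner <- function() {
    n <- cfg$n
    pos <- matrix(stats::runif(2 * n), n, 2)
    theta <- if (cfg$aligned_start) rep(0, n) else stats::runif(n, 0, 2 * pi)
    r_t <- cfg$schedule(seq_len(cfg$steps))
    TH <- matrix(NA_real_, cfg$steps, n)
    X <- matrix(NA_real_, cfg$steps, n)
    Y <- matrix(NA_real_, cfg$steps, n)
    for (s in seq_len(cfg$steps)) {
      st <- flock_step(pos, theta, r_t[s], cfg$noise, cfg$speed)
      pos <- st$pos; theta <- st$theta
      TH[s, ] <- theta; X[s, ] <- pos[, 1]; Y[s, ] <- pos[, 2]
    }
    list(TH = TH, X = X, Y = Y, r_t = r_t)
  }
  res <- if (is.null(cfg$seed)) runner() else withr::with_seed(as.integer(cfg$seed), runner())
  n <- cfg$n
  traj <- tibble::tibble(
    frame = rep(seq_len(cfg$steps), each = n),
    agent_id = rep(sprintf("a%03d", seq_len(n)), times = cfg$steps),
    x = as.vector(t(res$X)),
    y = as.vector(t(res$Y)),
    vx = cfg$speed * cos(as.vector(t(res$TH))),
    vy = cfg$speed * sin(as.vector(t(res$TH)))
  )
  class(traj) <- c("flock_trajectory", class(traj))
  attr(traj, "headings") <- res$TH
  attr(traj, "radius") <- res$r_t
  attr(traj, "config") <- cfg
  traj
}

#' Run a flocking experiment: simulate, then track order and alignment
#'
#' Simulates the model and, at a configurable stride once enough history
#' exists for the velocity-profile window, computes the map alignment
#' statistic Z_k(p, v) between the spatial-proximity geometry and the
#' velocity-profile geometry, alongside the mean-velocity order parameter and
#' the scheduled radius.
#'
#' @param cfg a [flock_config()].
#' @param k alignment subspace size (default 10).
#' @param k_nn kernel nearest-neighbor index (default 7).
#' @param w,tau velocity-profile window and decay (defaults 10 and 5 frames).
#' @param stride compute Z every `stride` steps (default 10).
#' @param eval_steps optional integer vector of steps at which to evaluate Z
#'   (overrides `stride`); steps without sufficient history report `NA`.
#' @return tibble of class `flock_experiment`: `step`, `r`, `order_param`
#'   (mean-velocity magnitude divided by speed, in `[0, 1]`), `z` (NA where
#'   not evaluated).
#' @export
run_flock_experiment <- function(cfg, k = 10L, k_nn = 7L, w = 10L, tau = 5,
                                 stride = 10L, eval_steps = NULL) {
  traj <- simulate_flock(cfg)
  TH <- attr(traj, "headings")
  r_t <- attr(traj, "radius")
  steps <- cfg$steps
  op <- vapply(seq_len(steps), function(s) {
    mean_velocity(TH[s, ], cfg$speed)$magnitude / cfg$speed
  }, numeric(1))
  if (is.null(eval_steps)) {
    eval_steps <- seq(w, steps, by = as.integer(stride))
  }
  eval_steps <- eval_steps[eval_steps >= w & eval_steps <= steps]
  z <- rep(NA_real_, steps)
  for (s in eval_steps) {
    z[s] <- frame_alignment_z(traj, s, k = k, k_nn = k_nn, w = w, tau = tau,
                              geometry = "torus", period = 1)
  }
  out <- tibble::tibble(step = seq_len(steps), r = r_t, order_param = op, z = z)
  class(out) <- c("flock_experiment", class(out))
  attr(out, "config") <- cfg
  out
}

# Z_k(p, v) for one frame of a trajectory table
frame_alignment_z <- function(traj, at_frame, k, k_nn, w, tau,
                              geometry = "planar", period = 1, lag_max = 0L) {
  win <- trajectory_window(traj, at_frame, w = w, lag_max = lag_max)
  D1 <- position_distance(win$pos, geometry = geometry, period = period)
  D2 <- if (lag_max > 0) {
    lagged_velocity_distance(win$vel, w = w, tau = tau, lag_max = lag_max)
  } else {
    velocity_profile_distance(win$vel, w = w, tau = tau)
  }
  B1 <- diffusion_map_frame(D1, k_nn = k_nn)
  B2 <- diffusion_map_frame(D2, k_nn = k_nn, dist_floor = TRUE)
  map_alignment(B1, B2, k)$statistic
}

#' Ensemble of flocking experiments across seeds
#'
#' Repeats [run_flock_experiment()] over independent seeds and aggregates the
#' per-step alignment statistic and order parameter: mean and empirical 90%
#' band (5th and 95th percentiles) across trials.
#'
#' @param cfg a [flock_config()]; its `seed` field is replaced per trial by
#'   `seed + trial index`.
#' @param n_trials number of independent runs.
#' @param seed base seed.
#' @param ... passed to [run_flock_experiment()].
#' @return list of class `flock_ensemble`: `trials` (tibble with `trial`
#'   column binding all runs) and `summary` (per-step mean and 90% band of
#'   `z` and `order_param`).
#' @export
flock_ensemble <- function(cfg, n_trials = 10L, seed = 1L, ...) {
  runs <- purrr::map(seq_len(n_trials), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seed) + i
    dplyr::mutate(run_flock_experiment(cfg_i, ...), trial = i)
  })
  trials <- dplyr::bind_rows(runs)
  summary <- dplyr::summarise(
    dplyr::group_by(trials, .data$step),
    r = .data$r[1],
    order_mean = mean(.data$order_param),
    order_lo = stats::quantile(.data$order_param, 0.05, names = FALSE),
    order_hi = stats::quantile(.data$order_param, 0.95, names = FALSE),
    z_mean = mean(.data$z),
    z_lo = stats::quantile(.data$z, 0.05, na.rm = TRUE, names = FALSE),
    z_hi = stats::quantile(.data$z, 0.95, na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
  structure(list(trials = trials, summary = summary), class = "flock_ensemble")
}

#' @export
tidy.flock_ensemble <- function(x, ...) x$summary

#' Alignment and order-parameter traces for a flocking ensemble
#'
#' Mean Z with its empirical 90% band, the mean order parameter, and the
#' radius schedule, against simulation step.
#'
#' @param object a `flock_ensemble`.
#' @param ... unused.
#' @export
autoplot.flock_ensemble <- function(object, ...) {
  s <- object$summary
  sz <- s[!is.na(s$z_mean), ]
  ggplot2::ggplot(sz, ggplot2::aes(x = .data$step)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$z_lo, ymax = .data$z_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$z_mean), color = "steelblue") +
    ggplot2::geom_line(
      data = s,
      ggplot2::aes(y = .data$order_mean * max(sz$z_hi, na.rm = TRUE)),
      color = "darkorange"
    ) +
    ggplot2::labs(
      x = "step", y = "map alignment Z",
      title = "MAS (blue, 90% band) and scaled order parameter (orange)"
    ) +
    ggplot2::theme_minimal()
}
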