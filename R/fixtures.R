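#' Specification of a synthetic schooling regime
#'
#' Parameters for one segment of synthetic fish-school-like data. The
#' generators are deliberately simple kinematic constructions — not the
#' flocking simulator — so each segment's ground-truth regime is unambiguous
#' and independent of the analysis method: milling agents orbit a common
#' centroid, swarming agents jitter around fixed home points with no net
#' motion, polarized agents translate with a common heading plus a smooth
#' spatial velocity field, and split-polarized agents form 2--3 spatially
#' interleaved subgroups with well-separated headings.
#'
#' @param regime one of `"milling"`, `"swarm"`, `"polarized-single"`,
#'   `"polarized-split"`.
#' @param n number of agents; `NULL` (default) samples uniformly from
#'   `n_range` at generation time, emulating the fluctuating group size of
#'   tracked schools.
#' @param duration segment length in frames (default 120, i.e. 4 s at the
#'   fixed 30 fps of the fixtures).
#' @param n_range admissible group sizes (default `c(70, 280)`).
#' @param angular_speed milling angular speed, rad/frame (default 0.12).
#' @param speed translation speed of polarized regimes, units/frame
#'   (default 1.2; one unit is roughly a body length).
#' @param n_subgroups subgroups in the split regime (2 or 3, default 2).
#' @param heading_offset angular separation between subgroup headings,
#'   radians (default `2*pi/3`).
#' @return list of class `regime_spec`.
#' @export
regime_spec <- function(regime = c("milling", "swarm", "polarized-single",
                                   "polarized-split"),
                        n = NULL, duration = 120L, n_range = c(70L, 280L),
                        angular_speed = 0.12, speed = 1.2,
                        n_subgroups = 2L, heading_offset = 2 * pi / 3) {
  regime <- match.arg(regime)
  if (!is.null(n) && (n < n_range[1] || n > n_range[2])) {
    stop("`n` must lie in [", n_range[1], ", ", n_range[2], "]")
  }
  if (duration < 12) stop("`duration` must cover at least the metric window")
  if (!n_subgroups %in% 2:3) stop("`n_subgroups` must be 2 or 3")
  structure(
    list(regime = regime, n = n, duration = as.integer(duration),
         n_range = as.integer(n_range), angular_speed = angular_speed,
         speed = speed, n_subgroups = as.integer(n_subgroups),
         heading_offset = heading_offset),
    class = "regime_spec"
  )
}

#' Generate one labeled regime segment
#'
#' Produces a tidy trajectory realizing the regime of `spec`, self-checked at
#' generation: at least 90% of frames must fall in the regime's polarization/
#' rotation box (milling: `o_p <= 0.35, o_r >= 0.65`; swarm: both `<= 0.35`;
#' polarized-single: `o_p >= 0.65, o_r <= 0.35`; for the split regime each
#' subgroup individually must be polarized). A segment failing the check is
#' regenerated with a fresh derived seed, up to `max_retries` times.
#'
#' Stored velocities are backward differences of the stored positions
#' (`v(t) = p(t) - p(t-1)`, first frame copying the second), so
#' finite-differencing the positions reproduces them exactly.
#'
#' @param spec a [regime_spec()].
#' @param seed integer seed.
#' @param max_retries regeneration budget (default 5).
#' @return tibble `frame`, `agent_id`, `x`, `y`, `vx`, `vy` with attributes
#'   `regime`, `box_fraction` (fraction of frames passing the self-check) and
#'   for the split regime `subgroup` (named membership vector).
#' @export
make_regime <- function(spec, seed = 1L, max_retries = 5L) {
  stopifnot(inherits(spec, "regime_spec"))
  achieved <- numeric(0)
  for (try in 0:max_retries) {
    out <- withr::with_seed(as.integer(seed) + 1000L * try, generate_regime(spec))
    frac <- regime_box_fraction(out, spec)
    if (frac >= 0.9) {
      attr(out, "box_fraction") <- frac
      return(out)
    }
    achieved <- c(achieved, frac)
  }
  stop("regime '", spec$regime, "' failed its order-parameter self-check after ",
       max_retries + 1, " attempts; achieved in-box fractions: ",
       paste(signif(achieved, 3), collapse = ", "))
}

regime_box_fraction <- function(traj, spec) {
  frames <- sort(unique(traj$frame))[-1]  # first frame's velocity is a copy
  sub <- attr(traj, "subgroup")
  ok <- vapply(frames, function(f) {
    d <- traj[traj$frame == f, ]
    if (spec$regime == "polarized-split") {
      g <- sub[d$agent_id]
      all(vapply(split(seq_len(nrow(d)), g), function(ix) {
        op <- order_parameters(d[ix, c("x", "y")], d[ix, c("vx", "vy")])
        op$o_p >= 0.65 && op$o_r <= 0.35
      }, logical(1)))
    } else {
      op <- order_parameters(d[, c("x", "y")], d[, c("vx", "vy")])
      switch(spec$regime,
        "milling" = op$o_p <= 0.35 && op$o_r >= 0.65,
        "swarm" = op$o_p <= 0.35 && op$o_r <= 0.35,
        "polarized-single" = op$o_p >= 0.65 && op$o_r <= 0.35
      )
    }
  }, logical(1))
  mean(ok)
}

# Positions for all frames -> tidy tibble with backward-difference velocities
positions_to_traj <- function(X, Y, ids) {
  Tn <- nrow(X); n <- ncol(X)
  VX <- rbind(X[2, ] - X[1, ], diff(X))
  VY <- rbind(Y[2, ] - Y[1, ], diff(Y))
  tibble::tibble(
    frame = rep(seq_len(Tn), each = n),
    agent_id = rep(ids, times = Tn),
    x = as.vector(t(X)), y = as.vector(t(Y)),
    vx = as.vector(t(VX)), vy = as.vector(t(VY))
  )
}

# smooth vector field over agent offsets: gives spatially correlated velocity
# perturbations, mimicking the coherent internal motion (turning waves, shear)
# of a real school
smooth_field <- function(off, scale) {
  cbind(sin(off[, 2] / scale), sin(off[, 1] / scale))
}

generate_regime <- function(spec) {
  n <- if (is.null(spec$n)) {
    sample(seq(spec$n_range[1], spec$n_range[2]), 1)
  } else {
    spec$n
  }
  Tn <- spec$duration
  ids <- sprintf("a%03d", seq_len(n))
  X <- matrix(NA_real_, Tn, n); Y <- matrix(NA_real_, Tn, n)
  sub <- NULL

  if (spec$regime == "milling") {
    radius <- stats::runif(n, 6, 10)
    alpha0 <- stats::runif(n, 0, 2 * pi)
    ang_noise <- matrix(stats::rnorm(Tn * n, 0, 0.02), Tn, n)
    rad_noise <- matrix(stats::rnorm(Tn * n, 0, 0.05), Tn, n)
    for (t in seq_len(Tn)) {
      a <- alpha0 + spec$angular_speed * t + colSums(ang_noise[seq_len(t), , drop = FALSE])
      r <- radius + colSums(rad_noise[seq_len(t), , drop = FALSE]) * 0.2
      X[t, ] <- r * cos(a); Y[t, ] <- r * sin(a)
    }
  } else if (spec$regime == "swarm") {
    home <- cbind(stats::rnorm(n, 0, 4), stats::rnorm(n, 0, 4))
    e <- matrix(0, n, 2)
    for (t in seq_len(Tn)) {
      e <- 0.9 * e + matrix(stats::rnorm(2 * n, 0, 0.3), n, 2)
      X[t, ] <- home[, 1] + e[, 1]; Y[t, ] <- home[, 2] + e[, 2]
    }
  } else if (spec$regime == "polarized-single") {
    mu <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(Tn - 1, 0, 0.01)))
    off <- cbind(stats::rnorm(n, 0, 6), stats::rnorm(n, 0, 3))
    drift <- matrix(0, n, 2)
    cen <- c(0, 0)
    field <- 0.15 * smooth_field(off, 4)
    for (t in seq_len(Tn)) {
      cen <- cen + spec$speed * c(cos(mu[t]), sin(mu[t]))
      drift <- drift + field + matrix(stats::rnorm(2 * n, 0, 0.03), n, 2)
      X[t, ] <- cen[1] + off[, 1] + drift[, 1]
      Y[t, ] <- cen[2] + off[, 2] + drift[, 2]
    }
  } else {  # polarized-split
    m <- spec$n_subgroups
    g <- rep(seq_len(m), length.out = n)
    sub <- stats::setNames(g, ids)
    base <- stats::runif(1, 0, 2 * pi)
    headings <- base + (seq_len(m) - 1) * spec$heading_offset
    # subgroups launched so their paths cross near the segment midpoint,
    # keeping them spatially interleaved while velocities split; internal
    # velocity coherence is weaker than the single-group state (smaller
    # smooth-field amplitude, more individual noise), reflecting the lower
    # organization of multi-group motion
    cen0 <- -0.5 * (Tn / 2) * spec$speed * cbind(cos(headings), sin(headings))
    off <- cbind(stats::rnorm(n, 0, 6), stats::rnorm(n, 0, 4))
    drift <- matrix(0, n, 2)
    field <- 0.04 * smooth_field(off, 4)
    for (t in seq_len(Tn)) {
      cg <- cen0 + t * spec$speed * cbind(cos(headings), sin(headings))
      drift <- drift + field + matrix(stats::rnorm(2 * n, 0, 0.06), n, 2)
      X[t, ] <- cg[g, 1] + off[, 1] + drift[, 1]
      Y[t, ] <- cg[g, 2] + off[, 2] + drift[, 2]
    }
  }

  out <- positions_to_traj(X, Y, ids)
  attr(out, "regime") <- spec$regime
  if (!is.null(sub)) attr(out, "subgroup") <- sub
  out
}

#' Concatenate regime segments into a labeled session
#'
#' Builds a session from a list of regime specs. Each segment gets a fresh
#' agent set (ids prefixed by segment), emulating fish entering and leaving
#' the tracked area; frame numbering runs continuously across segments.
#'
#' A session models one school: for specs without an explicit `n`, a
#' session-level base size is drawn uniformly from 80--240 and each segment's
#' size fluctuates within 15% of it (clipped to the 70--280 range), so group
#' size is autocorrelated within a session while spanning the full range
#' across sessions.
#'
#' @param specs list of [regime_spec()] objects.
#' @param seed integer seed; segment s uses `seed + s`.
#' @return list of class `school_session`: `trajectories` (tidy tibble),
#'   `labels` (tibble `frame`, `true_regime`), `segments` (tibble `segment`,
#'   `regime`, `start`, `end`, `n`).
#' @export
make_session <- function(specs, seed = 1L) {
  if (length(specs) < 1) stop("need at least one regime spec")
  seg_n <- withr::with_seed(as.integer(seed), {
    base <- sample(80:240, 1)
    vapply(specs, function(sp) {
      if (!is.null(sp$n)) return(as.integer(sp$n))
      as.integer(pmin(pmax(round(base * stats::runif(1, 0.85, 1.15)),
                           sp$n_range[1]), sp$n_range[2]))
    }, integer(1))
  })
  offset <- 0L
  trajs <- list(); labs <- list(); segs <- list()
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    sp$n <- seg_n[s]
    seg <- make_regime(sp, seed = as.integer(seed) + s)
    seg$frame <- seg$frame + offset
    seg$agent_id <- paste0("s", s, "_", seg$agent_id)
    frames <- sort(unique(seg$frame))
    trajs[[s]] <- seg
    labs[[s]] <- tibble::tibble(frame = frames, true_regime = specs[[s]]$regime)
    segs[[s]] <- tibble::tibble(
      segment = s, regime = specs[[s]]$regime,
      start = frames[1], end = frames[length(frames)],
      n = length(unique(seg$agent_id))
    )
    offset <- offset + specs[[s]]$duration
  }
  structure(
    list(
      trajectories = dplyr::bind_rows(lapply(trajs, function(tr) {
        attr(tr, "regime") <- NULL
        attr(tr, "subgroup") <- NULL
        attr(tr, "box_fraction") <- NULL
        tr
      })),
      labels = dplyr::bind_rows(labs),
      segments = dplyr::bind_rows(segs)
    ),
    class = "school_session"
  )
}

#' @export
print.school_session <- function(x, ...) {
  cat("<school_session>", nrow(x$segments), "segments,",
      max(x$labels$frame), "frames\n")
  print(x$segments)
  invisible(x)
}
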