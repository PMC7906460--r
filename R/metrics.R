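#' Pairwise spatial distance matrix for one frame
#'
#' Euclidean distances between agent positions, either in the plane or on a
#' square torus of side `period` (geodesic: per-axis minimum of the direct and
#' wrap-around separations, combined in quadrature).
#'
#' @param pos numeric matrix (n x 2) of positions, or a data frame with
#'   columns `x` and `y`; row order defines agent order.
#' @param geometry `"planar"` or `"torus"`.
#' @param period torus side length (ignored for planar geometry). Default 1.
#' @return symmetric n x n distance matrix with zero diagonal.
#' @examples
#' position_distance(rbind(c(0, 0), c(3, 4)))
#' @export
position_distance <- function(pos, geometry = c("planar", "torus"), period = 1) {
  geometry <- match.arg(geometry)
  pos <- as_coord_matrix(pos)
  if (any(!is.finite(pos))) {
    stop("non-finite coordinates for agents: ",
         paste(which(rowSums(!is.finite(pos)) > 0), collapse = ", "))
  }
  if (geometry == "planar") {
    D <- as.matrix(stats::dist(pos))
    dimnames(D) <- NULL
    return(D)
  }
  dx <- torus_delta(pos[, 1], period)
  dy <- torus_delta(pos[, 2], period)
  D <- sqrt(dx^2 + dy^2)
  diag(D) <- 0
  D
}

torus_delta <- function(u, period) {
  d <- abs(outer(u, u, "-")) %% period
  pmin(d, period - d)
}

as_coord_matrix <- function(pos) {
  if (is.data.frame(pos)) pos <- cbind(pos$x, pos$y)
  pos <- as.matrix(pos)
  if (ncol(pos) != 2) stop("positions must have two columns")
  storage.mode(pos) <- "double"
  pos
}

# pairwise squared euclidean distances between rows of A and rows of B
cross_sqdist <- function(A, B) {
  ra <- rowSums(A^2)
  rb <- rowSums(B^2)
  M <- outer(ra, rb, "+") - 2 * tcrossprod(A, B)
  M[M < 0] <- 0
  M
}

exp_kernel_weights <- function(w, tau) {
  kappa <- exp(-(seq_len(w) - 1) / tau)
  kappa / sum(kappa)
}

#' Kernel-smoothed velocity-profile distance matrix
#'
#' Distance between two agents' recent velocity histories:
#' \deqn{d^{(2)}(i, j)^2 = \sum_{s=0}^{w-1} \kappa_s \, \|v_i(t-s) - v_j(t-s)\|^2,}
#' with exponentially decaying weights \eqn{\kappa_s \propto e^{-s/\tau}}
#' normalized to sum to one, so agents moving in concert over the recent
#' window are close regardless of where they are in space.
#'
#' @param vel numeric array of dimension `(n, 2, depth)`: slice `s + 1` holds
#'   the agents' velocities at lag `s` frames before the evaluation frame
#'   (slice 1 = current frame). `depth` must be at least `w`.
#' @param w window length in frames (default 10).
#' @param tau kernel decay constant in frames (default 5).
#' @return symmetric n x n distance matrix with zero diagonal.
#' @export
velocity_profile_distance <- function(vel, w = 10L, tau = 5) {
  vel <- check_vel_array(vel)
  w <- as.integer(w)
  if (w < 1L) stop("`w` must be >= 1")
  if (dim(vel)[3] < w) {
    stop("velocity history depth ", dim(vel)[3], " is shorter than window w = ", w)
  }
  if (tau <= 0) stop("`tau` must be positive")
  kappa <- exp_kernel_weights(w, tau)
  n <- dim(vel)[1]
  D2 <- matrix(0, n, n)
  for (s in seq_len(w)) {
    D2 <- D2 + kappa[s] * cross_sqdist(vel[, , s], vel[, , s])
  }
  D <- sqrt((D2 + t(D2)) / 2)
  diag(D) <- 0
  D
}

check_vel_array <- function(vel) {
  if (length(dim(vel)) != 3 || dim(vel)[2] != 2) {
    stop("`vel` must be an (n, 2, depth) array")
  }
  if (any(!is.finite(vel))) stop("`vel` contains non-finite entries")
  vel
}

#' Lag-minimized velocity-profile distance matrix
#'
#' Generalizes [velocity_profile_distance()] to interactions with a time lag
#' (one agent leading another): for each pair the windowed profile distance is
#' minimized over a shift \eqn{\ell \in \{0, \dots, \ell_{max}\}} applied to
#' either agent's history, so an agent whose velocity profile repeats a
#' partner's earlier motion is recognized as close. Minimizing over which of
#' the two agents is shifted makes the result symmetric by construction.
#'
#' @inheritParams velocity_profile_distance
#' @param lag_max maximum lag in frames (default 0, which reduces exactly to
#'   [velocity_profile_distance()]). The history depth must be at least
#'   `w + lag_max`.
#' @return symmetric n x n distance matrix with zero diagonal; entrywise no
#'   larger than the unlagged distance.
#' @export
lagged_velocity_distance <- function(vel, w = 10L, tau = 5, lag_max = 0L) {
  vel <- check_vel_array(vel)
  w <- as.integer(w)
  lag_max <- as.integer(lag_max)
  if (lag_max < 0L) stop("`lag_max` must be >= 0")
  depth <- dim(vel)[3]
  if (depth < w + lag_max) {
    stop("velocity history depth ", depth, " is shorter than required w + lag_max = ",
         w + lag_max)
  }
  kappa <- exp_kernel_weights(w, tau)
  n <- dim(vel)[1]
  best <- NULL
  for (ell in 0:lag_max) {
    D2 <- matrix(0, n, n)
    for (s in seq_len(w)) {
      # agent in rows shifted ell frames earlier, agent in columns unshifted
      D2 <- D2 + kappa[s] * cross_sqdist(vel[, , s + ell], vel[, , s])
    }
    cand <- pmin(D2, t(D2))
    best <- if (is.null(best)) cand else pmin(best, cand)
  }
  D <- sqrt(best)
  diag(D) <- 0
  D
}

#' Extract a trajectory window for one evaluation frame
#'
#' Collects, from a tidy trajectory table, the agents that are present in
#' every frame of the history window ending at `at_frame` (length
#' `w + lag_max`), and packs their positions at `at_frame` and their velocity
#' histories into the array layout consumed by the metric functions. Agents
#' with any gap in the window are dropped and reported.
#'
#' @param traj tidy trajectory: columns `frame`, `agent_id`, `x`, `y`, `vx`,
#'   `vy` (see [read_trajectories()]).
#' @param at_frame evaluation frame.
#' @param w window length in frames.
#' @param lag_max maximum lag in frames.
#' @return list with `agent_ids`, `pos` (n x 2 at `at_frame`), `vel`
#'   ((n, 2, w + lag_max) array, slice 1 = `at_frame`), and `dropped`
#'   (agent ids excluded for incomplete history).
#' @export
trajectory_window <- function(traj, at_frame, w = 10L, lag_max = 0L) {
  depth <- as.integer(w) + as.integer(lag_max)
  need <- seq(at_frame - depth + 1L, at_frame)
  if (need[1] < min(traj$frame)) {
    stop("insufficient history: window for frame ", at_frame, " needs frame ",
         need[1], " but trajectories start at ", min(traj$frame))
  }
  win <- dplyr::filter(traj, .data$frame %in% need)
  counts <- dplyr::count(win, .data$agent_id)
  present <- dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(win, .data$agent_id),
      n_frames = dplyr::n_distinct(.data$frame), .groups = "drop"
    ),
    .data$n_frames == depth
  )$agent_id
  dropped <- setdiff(unique(win$agent_id), present)
  if (length(present) < 2) {
    stop("fewer than 2 agents have complete history at frame ", at_frame)
  }
  win <- dplyr::arrange(
    dplyr::filter(win, .data$agent_id %in% present),
    .data$agent_id, .data$frame
  )
  n <- length(present)
  ids <- sort(unique(win$agent_id))
  # win is sorted by (agent, frame); reshape to (frame, agent) slices
  vx <- matrix(win$vx, nrow = depth, ncol = n)  # rows: frames ascending
  vy <- matrix(win$vy, nrow = depth, ncol = n)
  x <- matrix(win$x, nrow = depth, ncol = n)
  y <- matrix(win$y, nrow = depth, ncol = n)
  vel <- array(0, dim = c(n, 2, depth))
  for (s in seq_len(depth)) {
    # slice s = lag s-1, i.e. frame at_frame - (s-1) = row depth - s + 1
    vel[, 1, s] <- vx[depth - s + 1L, ]
    vel[, 2, s] <- vy[depth - s + 1L, ]
  }
  list(
    agent_ids = ids,
    pos = cbind(x = x[depth, ], y = y[depth, ]),
    vel = vel,
    dropped = dropped
  )
}
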