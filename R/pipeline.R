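#' Read a tidy trajectory CSV
#'
#' The canonical trajectory format is one row per (frame, agent): columns
#' `frame` (integer), `agent_id` (string), `x`, `y` (positions in domain
#' units) and optionally `vx`, `vy` (domain units per frame). When the
#' velocity columns are absent they are synthesized per agent by central
#' finite differences of position (forward/backward differences at the ends
#' of each agent's presence interval), and the synthesis is flagged in the
#' returned object's `velocity_source` attribute.
#'
#' @param path CSV file path, or a data frame already in the format above.
#' @return validated tibble sorted by frame then agent, with attribute
#'   `velocity_source` (`"file"` or `"finite_difference"`).
#' @export
read_trajectories <- function(path) {
  traj <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  req <- c("frame", "agent_id", "x", "y")
  miss <- setdiff(req, names(traj))
  if (length(miss) > 0) stop("missing required columns: ", paste(miss, collapse = ", "))
  traj$frame <- as.integer(traj$frame)
  traj$agent_id <- as.character(traj$agent_id)
  dup <- duplicated(traj[c("frame", "agent_id")])
  if (any(dup)) {
    stop("duplicate (frame, agent_id) pairs at rows: ",
         paste(utils::head(which(dup), 5), collapse = ", "))
  }
  num_cols <- intersect(c("x", "y", "vx", "vy"), names(traj))
  bad <- !stats::complete.cases(traj[num_cols]) |
    rowSums(!is.finite(as.matrix(traj[num_cols]))) > 0
  if (any(bad)) {
    stop("non-finite values at rows: ", paste(utils::head(which(bad), 5), collapse = ", "))
  }
  has_vel <- all(c("vx", "vy") %in% names(traj))
  traj <- dplyr::arrange(traj, .data$frame, .data$agent_id)
  if (!has_vel) {
    traj <- dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(dplyr::arrange(traj, .data$agent_id, .data$frame), .data$agent_id),
      vx = central_diff(.data$x, .data$frame),
      vy = central_diff(.data$y, .data$frame)
    ))
    traj <- dplyr::arrange(traj, .data$frame, .data$agent_id)
  }
  attr(traj, "velocity_source") <- if (has_vel) "file" else "finite_difference"
  traj
}

# central differences within an agent's contiguous presence; one-sided at the
# ends of each contiguous run of frames
central_diff <- function(p, frame) {
  n <- length(p)
  if (n == 1) return(0)
  v <- numeric(n)
  brk <- c(0, which(diff(frame) != 1), n)  # run boundaries
  for (b in seq_len(length(brk) - 1)) {
    ix <- (brk[b] + 1):brk[b + 1]
    m <- length(ix)
    if (m == 1) { v[ix] <- 0; next }
    pp <- p[ix]
    vv <- numeric(m)
    vv[1] <- pp[2] - pp[1]
    vv[m] <- pp[m] - pp[m - 1]
    if (m > 2) vv[2:(m - 1)] <- (pp[3:m] - pp[1:(m - 2)]) / 2
    v[ix] <- vv
  }
  v
}

#' Write a tidy trajectory CSV
#' @param traj trajectory tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  readr::write_csv(traj, path, progress = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow the
#' method's standard settings: subspace size `k = 15` (10 is typical for
#' small simulated flocks), kernel neighbor index `k_nn = 7`, window
#' `w = 10` frames with decay `tau = 5`, no lag search (`lag_max = 60` is the
#' 2-second search at 30 fps used for leader-follower data), incoherence gate
#' `z_threshold = 3`, and 3 macrostate clusters.
#'
#' @param k alignment/covariance subspace size.
#' @param k_nn GkNN kernel neighbor index.
#' @param w velocity-profile window, frames.
#' @param tau velocity kernel decay, frames.
#' @param lag_max maximum lag for the velocity metric, frames.
#' @param t diffusion time.
#' @param z_threshold incoherence gate on Z.
#' @param n_clusters macrostate clusters.
#' @param seed clustering seed.
#' @param geometry `"planar"` or `"torus"`.
#' @param period torus side length.
#' @param stride analyze every `stride`-th frame.
#' @param min_n frames with fewer complete-history agents are skipped.
#' @param frame_rate frames per second, recorded so lags can be stated in
#'   seconds (default 30).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 15L, k_nn = 7L, w = 10L, tau = 5, lag_max = 0L,
                            t = 1, z_threshold = 3, n_clusters = 3L, seed = 1L,
                            geometry = c("planar", "torus"), period = 1,
                            stride = 1L, min_n = 30L, frame_rate = 30) {
  geometry <- match.arg(geometry)
  stopifnot(k >= 1, k_nn >= 1, w >= 1, tau > 0, lag_max >= 0, stride >= 1)
  structure(
    list(k = as.integer(k), k_nn = as.integer(k_nn), w = as.integer(w),
         tau = tau, lag_max = as.integer(lag_max), t = t,
         z_threshold = z_threshold, n_clusters = as.integer(n_clusters),
         seed = as.integer(seed), geometry = geometry, period = period,
         stride = as.integer(stride), min_n = as.integer(min_n),
         frame_rate = frame_rate),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on a trajectory table
#'
#' For every analyzable frame (enough history for the velocity window and lag
#' search, at least `min_n` agents with complete history, stride applied)
#' the pipeline builds the spatial and velocity-profile distance matrices,
#' their diffusion bases, the map alignment statistic in both directions
#' (Z(p, v): spatial eigenvectors projected onto the velocity subspace, and
#' its reverse), the covariance vector, and the order-parameter reference
#' classification. Frames failing a precondition are skipped and recorded,
#' never abort the run. After the per-frame pass, frames are gated on the
#' forward statistic and the coherent frames clustered into macrostates (see
#' [classify_frames()]).
#'
#' @param traj trajectory tibble (see [read_trajectories()]); a path is also
#'   accepted.
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result`: list with `stats` (tibble:
#'   frame, n, o_p, o_r, reference_state, z_forward, z_reverse, label),
#'   `labeling` (the `state_labeling`), `covariance_vectors` (matrix, one row
#'   per analyzed frame), `skipped` (tibble: frame, reason) and `config`.
#' @export
run_pipeline <- function(traj, config = pipeline_config()) {
  traj <- read_trajectories(traj)
  stopifnot(inherits(config, "pipeline_config"))
  depth <- config$w + config$lag_max
  frames <- sort(unique(traj$frame))
  first_ok <- frames[1] + depth - 1L
  cand <- frames[frames >= first_ok]
  if (length(cand) == 0) {
    stop("no analyzable frames: history depth requires frame >= ", first_ok,
         " but trajectories end at ", frames[length(frames)])
  }
  cand <- cand[seq(1, length(cand), by = config$stride)]
  skipped <- list()
  rows <- list()
  xis <- list()
  for (f in cand) {
    res <- tryCatch(
      analyze_frame(traj, f, config),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(frame = f, reason = res)
    } else {
      rows[[length(rows) + 1]] <- res$row
      xis[[length(xis) + 1]] <- res$xi
    }
  }
  if (length(rows) == 0) {
    stop("no analyzable frames; first skip reason: ", skipped[[1]]$reason)
  }
  stats <- dplyr::bind_rows(rows)
  labeling <- classify_frames(
    tibble::tibble(frame = stats$frame, z = stats$z_forward, xi = xis),
    z_threshold = config$z_threshold,
    n_clusters = config$n_clusters,
    seed = config$seed
  )
  stats$label <- labeling$labels$label
  structure(
    list(
      stats = stats,
      labeling = labeling,
      covariance_vectors = do.call(rbind, xis),
      skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped) else
        tibble::tibble(frame = integer(), reason = character()),
      config = config
    ),
    class = "pipeline_result"
  )
}

analyze_frame <- function(traj, f, config) {
  win <- trajectory_window(traj, f, w = config$w, lag_max = config$lag_max)
  n <- length(win$agent_ids)
  if (n < config$min_n) stop("frame ", f, ": only ", n, " agents (< min_n)")
  if (config$k >= n) stop("frame ", f, ": k = ", config$k, " >= n = ", n)
  if (config$k_nn >= n) stop("frame ", f, ": k_nn >= n")
  D1 <- position_distance(win$pos, geometry = config$geometry, period = config$period)
  D2 <- if (config$lag_max > 0) {
    lagged_velocity_distance(win$vel, w = config$w, tau = config$tau,
                             lag_max = config$lag_max)
  } else {
    velocity_profile_distance(win$vel, w = config$w, tau = config$tau)
  }
  B1 <- diffusion_map_frame(D1, k_nn = config$k_nn, t = config$t, dist_floor = TRUE)
  B2 <- diffusion_map_frame(D2, k_nn = config$k_nn, t = config$t, dist_floor = TRUE)
  zf <- map_alignment(B1, B2, config$k)
  zr <- map_alignment(B2, B1, config$k)
  xi <- covariance_vector(covariance_matrix(B1, B2, config$k))
  op <- order_parameters(win$pos, win$vel[, , 1])
  list(
    row = tibble::tibble(
      frame = f, n = n,
      o_p = op$o_p, o_r = op$o_r, reference_state = op$state,
      z_forward = zf$statistic, z_reverse = zr$statistic
    ),
    xi = xi
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$stats), "frames analyzed,",
      nrow(x$skipped), "skipped\n")
  print(x$labeling$cluster_summary)
  invisible(x)
}

#' @export
tidy.pipeline_result <- function(x, ...) x$stats

#' @export
glance.pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$stats),
    n_skipped = nrow(x$skipped),
    mean_z_forward = mean(x$stats$z_forward),
    k = x$config$k,
    z_threshold = x$config$z_threshold,
    n_clusters = x$config$n_clusters
  )
}

#' Alignment timeline colored by macrostate label
#'
#' Z(p, v) against frame, points colored by the assigned macrostate (N =
#' incoherent), with the gate drawn as a dashed line.
#'
#' @param object a `pipeline_result`.
#' @param ... unused.
#' @export
autoplot.pipeline_result <- function(object, ...) {
  ggplot2::ggplot(object$stats,
                  ggplot2::aes(x = .data$frame, y = .data$z_forward,
                               color = .data$label)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$config$z_threshold,
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "frame", y = "map alignment Z(p, v)", color = "state") +
    ggplot2::theme_minimal()
}

#' Write per-frame pipeline outputs
#'
#' Writes the stats table, the cluster centers and the skip log as CSVs with
#' a provenance header comment carrying the resolved configuration.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  hdr <- paste0(
    "# mapalign pipeline: ",
    paste(names(unclass(cfg))[!vapply(cfg, is.function, logical(1))],
          vapply(cfg[!vapply(cfg, is.function, logical(1))], function(v)
            paste(format(v), collapse = "/"), character(1)),
          sep = "=", collapse = " ")
  )
  stats_path <- file.path(dir, "stats.csv")
  writeLines(hdr, stats_path)
  readr::write_csv(result$stats, stats_path, append = TRUE, col_names = TRUE)
  if (!is.null(result$labeling$centers)) {
    centers_df <- as.data.frame(result$labeling$centers)
    centers_df <- cbind(label = rownames(centers_df), centers_df)
    readr::write_csv(tibble::as_tibble(centers_df), file.path(dir, "centers.csv"))
  }
  readr::write_csv(result$skipped, file.path(dir, "skipped.csv"))
  invisible(dir)
}
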