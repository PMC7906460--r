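#' Covariance matrix between two truncated diffusion maps
#'
#' Entry (i, j) is the inner product of the i-th diffusion coordinate of
#' basis 1 with the j-th diffusion coordinate of basis 2,
#' \eqn{\xi_{ij} = \langle \psi^{(1)}_i, \psi^{(2)}_j \rangle
#'      = \lambda^{(1)}_i \lambda^{(2)}_j \langle \phi^{(1)}_i, \phi^{(2)}_j \rangle}
#' (at each basis's diffusion time). The eigenvalue factors damp the trailing,
#' small-scale modes, so the matrix captures the macro-scale relationship
#' between the two geometries.
#'
#' @param B1,B2 `diffusion_basis` objects on the same agents.
#' @param k truncation rank.
#' @return k x k numeric matrix.
#' @export
covariance_matrix <- function(B1, B2, k) {
  stopifnot(inherits(B1, "diffusion_basis"), inherits(B2, "diffusion_basis"))
  if (B1$n != B2$n) stop("bases are on different numbers of agents: ", B1$n, " vs ", B2$n)
  ids1 <- attr(B1, "agent_ids"); ids2 <- attr(B2, "agent_ids")
  if (!is.null(ids1) && !is.null(ids2) && !identical(ids1, ids2)) {
    stop("bases are on different agent sets")
  }
  k <- as.integer(k)
  if (k < 1L || k > length(B1$eigenvalues) || k > length(B2$eigenvalues)) {
    stop("`k` exceeds a basis size")
  }
  idx <- seq_len(k)
  G <- crossprod(B1$vectors[, idx, drop = FALSE], B2$vectors[, idx, drop = FALSE])
  outer(B1$eigenvalues[idx]^B1$t, B2$eigenvalues[idx]^B2$t) * G
}

#' Magnitude-sorted covariance vector
#'
#' Flattens a covariance matrix into the length-k^2 vector of absolute values
#' sorted in decreasing order. Sorting by magnitude removes the ambiguity of
#' eigenvector sign and of mode index swaps under near-degenerate
#' eigenvalues, giving a frame-level fingerprint comparable across time.
#' Ties are broken by row-major position in the original matrix, so the
#' result is deterministic.
#'
#' @param xi k x k numeric matrix as from [covariance_matrix()].
#' @return numeric vector of length `k^2`, non-increasing.
#' @export
covariance_vector <- function(xi) {
  xi <- as.matrix(xi)
  if (any(!is.finite(xi))) stop("`xi` has non-finite entries")
  a <- abs(as.vector(t(xi)))  # row-major flattening
  a[order(-a, seq_along(a))]
}

#' Group polarization and rotation order parameters
#'
#' The classical macro-variables of a fish school:
#' \deqn{O_p = \frac{1}{N}\Big|\sum_i \hat v(x_i)\Big|, \qquad
#'       O_r = \frac{1}{N}\Big|\sum_i \hat q(x_i) \times \hat v(x_i)\Big|,}
#' where \eqn{\hat v} are unit velocity vectors and \eqn{\hat q} unit vectors
#' from the group centroid to each agent; in 2-D the cross product is its
#' scalar z-component. Agents with zero speed contribute a zero unit vector
#' (they are counted in `n_zero_speed`); agents exactly at the centroid
#' contribute zero to the rotation sum.
#'
#' @param pos n x 2 position matrix (or data frame with `x`, `y`).
#' @param vel n x 2 velocity matrix (or data frame with `vx`, `vy`).
#' @return one-row tibble: `n`, `o_p`, `o_r`, `centroid_x`, `centroid_y`,
#'   `n_zero_speed`, `state` (see [reference_state()]).
#' @examples
#' pos <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
#' vel <- rbind(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))  # counterclockwise mill
#' order_parameters(pos, vel)
#' @export
order_parameters <- function(pos, vel) {
  pos <- as_coord_matrix(pos)
  if (is.data.frame(vel)) vel <- cbind(vel$vx, vel$vy)
  vel <- as.matrix(vel)
  if (nrow(pos) != nrow(vel) || ncol(vel) != 2) {
    stop("`pos` and `vel` must be n x 2 with matching n")
  }
  n <- nrow(pos)
  if (n < 2) stop("need at least 2 agents")
  speed <- sqrt(rowSums(vel^2))
  if (all(speed == 0)) stop("all agents have zero speed; order parameters undefined")
  vhat <- vel / ifelse(speed > 0, speed, 1)
  vhat[speed == 0, ] <- 0
  cen <- colMeans(pos)
  q <- sweep(pos, 2, cen)
  qn <- sqrt(rowSums(q^2))
  qhat <- q / ifelse(qn > 0, qn, 1)
  qhat[qn == 0, ] <- 0
  o_p <- sqrt(sum(colSums(vhat)^2)) / n
  cross_z <- qhat[, 1] * vhat[, 2] - qhat[, 2] * vhat[, 1]
  o_r <- abs(sum(cross_z)) / n
  tibble::tibble(
    n = n, o_p = o_p, o_r = o_r,
    centroid_x = cen[1], centroid_y = cen[2],
    n_zero_speed = sum(speed == 0),
    state = reference_state(o_p, o_r)
  )
}

#' Reference behavioral state from order parameters
#'
#' The conventional demarcation of collective states: milling if
#' `o_p <= 0.35` and `o_r >= 0.65`; swarming if both are `<= 0.35`; polarized
#' if `o_p >= 0.65` and `o_r <= 0.35`; every other combination is
#' transitional.
#'
#' @param o_p,o_r polarization and rotation, each in `[0, 1]` (vectorized).
#' @return character vector of `"milling"`, `"swarming"`, `"polarized"` or
#'   `"transitional"`.
#' @export
reference_state <- function(o_p, o_r) {
  if (any(o_p < 0 | o_p > 1 | o_r < 0 | o_r > 1)) {
    stop("`o_p` and `o_r` must lie in [0, 1]")
  }
  dplyr::case_when(
    o_p <= 0.35 & o_r >= 0.65 ~ "milling",
    o_p <= 0.35 & o_r <= 0.35 ~ "swarming",
    o_p >= 0.65 & o_r <= 0.35 ~ "polarized",
    .default = "transitional"
  )
}

#' Gate incoherent frames and cluster coherent frames into macrostates
#'
#' Frames whose map alignment statistic falls below `z_threshold` show no
#' detectable macro-scale relationship between the two metrics and are
#' labeled `"N"` (incoherent) without entering the clustering. The remaining
#' frames are clustered by k-means on their covariance vectors; clusters are
#' renamed `G1, G2, ...` in order of decreasing mean Z within cluster, so the
#' naming is stable across runs and the most organized macrostate is always
#' `G1`.
#'
#' @param frames tibble with one row per frame: columns `frame`, `z`
#'   (alignment statistic) and `xi` (list-column of covariance vectors of a
#'   common length, as from [covariance_vector()]).
#' @param z_threshold gate on Z (default 3: roughly a three-sigma deviation
#'   under the null, since each standardized summand has unit variance).
#' @param n_clusters number of macrostate clusters (default 3).
#' @param seed integer seed controlling the k-means restarts (default 1).
#' @param nstart number of k-means restarts; the best-inertia solution is
#'   kept (default 10).
#' @return object of class `state_labeling`: list with `labels` (tibble:
#'   frame, z, label), `centers` (cluster centers, rows named by label),
#'   `cluster_summary` (tibble: label, n_frames, mean_z), `z_threshold`,
#'   `n_clusters`, `seed`.
#' @export
classify_frames <- function(frames, z_threshold = 3, n_clusters = 3L,
                            seed = 1L, nstart = 10L) {
  stopifnot(all(c("frame", "z", "xi") %in% names(frames)))
  lens <- lengths(frames$xi)
  if (length(unique(lens)) > 1) stop("covariance vectors have differing lengths")
  coherent <- frames$z >= z_threshold
  labels <- rep("N", nrow(frames))
  centers <- NULL
  if (any(coherent)) {
    if (sum(coherent) < n_clusters) {
      stop("only ", sum(coherent), " coherent frames for ", n_clusters, " clusters")
    }
    X <- do.call(rbind, frames$xi[coherent])
    km <- withr::with_seed(
      as.integer(seed),
      stats::kmeans(X, centers = n_clusters, nstart = nstart, iter.max = 100)
    )
    mean_z <- tapply(frames$z[coherent], km$cluster, mean)
    ord <- order(-mean_z)  # rank 1 = highest mean Z
    new_name <- character(n_clusters)
    new_name[ord] <- paste0("G", seq_len(n_clusters))
    labels[coherent] <- new_name[km$cluster]
    centers <- km$centers[ord, , drop = FALSE]
    rownames(centers) <- paste0("G", seq_len(n_clusters))
    colnames(centers) <- paste0("xi", seq_len(ncol(centers)))
  }
  lab_tbl <- tibble::tibble(frame = frames$frame, z = frames$z, label = labels)
  summ <- dplyr::arrange(
    dplyr::summarise(
      dplyr::group_by(lab_tbl, .data$label),
      n_frames = dplyr::n(), mean_z = mean(.data$z), .groups = "drop"
    ),
    dplyr::desc(.data$mean_z)
  )
  structure(
    list(
      labels = lab_tbl,
      centers = centers,
      cluster_summary = summ,
      z_threshold = z_threshold,
      n_clusters = as.integer(n_clusters),
      seed = as.integer(seed)
    ),
    class = "state_labeling"
  )
}

#' @export
print.state_labeling <- function(x, ...) {
  cat("<state_labeling>", nrow(x$labels), "frames, gate Z <", x$z_threshold, "\n")
  print(x$cluster_summary)
  invisible(x)
}

#' @export
tidy.state_labeling <- function(x, ...) x$labels

#' @export
glance.state_labeling <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x$labels),
    n_gated = sum(x$labels$label == "N"),
    n_clusters = x$n_clusters,
    z_threshold = x$z_threshold
  )
}
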