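#' Gaussian k-nearest-neighbor (GkNN) affinity kernel
#'
#' Converts a symmetric pairwise distance matrix into an affinity matrix with
#' the self-tuning gaussian kernel
#' \deqn{K(x, y) = \exp\!\left(-\frac{d(x,y)^2}{d(x, k(x))\, d(y, k(y))}\right),}
#' where \eqn{d(x, k(x))} is the distance from \eqn{x} to its `k_nn`-th nearest
#' neighbor (the point itself excluded). The per-point bandwidths make the
#' kernel scale-free: multiplying every distance by a constant leaves `K`
#' unchanged, so no global bandwidth needs to be chosen.
#'
#' @param D symmetric numeric matrix of pairwise distances with zero diagonal
#'   and nonnegative entries; at least 2 points.
#' @param k_nn positive integer, which nearest neighbor sets each point's local
#'   bandwidth. Must be smaller than the number of points. Default 7.
#' @param dist_floor if `TRUE`, duplicate points (zero nearest-neighbor
#'   distance) are tolerated by flooring bandwidths at
#'   `1e-12 * median(D[D > 0])` instead of raising an error.
#' @return an affinity matrix: symmetric, entries in `(0, 1]`, unit diagonal.
#' @examples
#' D <- as.matrix(dist(c(0, 1, 3)))
#' gknn_kernel(D, k_nn = 1)
#' @export
gknn_kernel <- function(D, k_nn = 7L, dist_floor = FALSE) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  k_nn <- as.integer(k_nn)
  if (k_nn < 1L || k_nn >= n) {
    stop("`k_nn` must satisfy 1 <= k_nn < n (n = ", n, ", got ", k_nn, ")")
  }
  # k_nn-th nearest neighbor distance per point, self excluded
  dk <- vapply(seq_len(n), function(i) sort(D[i, -i])[k_nn], numeric(1))
  if (any(dk == 0)) {
    if (dist_floor) {
      floor_val <- 1e-12 * stats::median(D[D > 0])
      if (!is.finite(floor_val) || floor_val <= 0) {
        stop("all pairwise distances are zero; cannot build a kernel")
      }
      dk <- pmax(dk, floor_val)
    } else {
      bad <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
      pair <- if (nrow(bad) > 0) paste0(bad[1, 1], " and ", bad[1, 2]) else "unknown"
      stop(
        "duplicate points detected (zero ", k_nn, "-th neighbor distance), ",
        "e.g. points ", pair, "; enable `dist_floor` to tolerate duplicates"
      )
    }
  }
  K <- exp(-D^2 / outer(dk, dk))
  diag(K) <- 1
  # exact symmetry despite floating-point order effects
  (K + t(K)) / 2
}

validate_distance_matrix <- function(D) {
  D <- as.matrix(D)
  dimnames(D) <- NULL
  if (nrow(D) != ncol(D) || nrow(D) < 2) stop("`D` must be a square matrix with n >= 2")
  if (any(!is.finite(D))) stop("`D` contains non-finite entries")
  if (any(D < 0)) stop("`D` has negative entries")
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) stop("`D` is not symmetric")
  if (any(diag(D) != 0)) stop("`D` must have a zero diagonal")
  D
}

#' Normalize an affinity matrix to a Markov (heat) operator
#'
#' Applies the two-step density normalization (the alpha = 1 member of the
#' Coifman--Lafon family): first `A' = S^-1 A S^-1` with `S = diag(rowSums(A))`,
#' which removes the sampling-density bias, then row-normalizes `A'` to the
#' row-stochastic operator `Ahat` whose entry `(i, j)` is the probability that a
#' random walk at point `i` steps to point `j`. The symmetric conjugate
#' `Dh^{-1/2} A' Dh^{-1/2}` (with `Dh = diag(rowSums(A'))`) shares the spectrum
#' of `Ahat` and is kept for a numerically safe symmetric eigensolve.
#'
#' @param A affinity matrix as produced by [gknn_kernel()]: symmetric, positive
#'   entries, unit diagonal.
#' @return an object of class `markov_operator`: a list with `markov` (the
#'   row-stochastic matrix), `sym` (its symmetric conjugate),
#'   `stationary_weights` (row sums of `A'`, proportional to the walk's
#'   stationary distribution) and `n`.
#' @export
markov_operator <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n != ncol(A)) stop("`A` must be square")
  if (any(!is.finite(A)) || any(A < 0)) stop("`A` must be finite and nonnegative")
  s <- rowSums(A)
  if (any(s <= 0)) stop("`A` has a zero row sum; not a valid affinity matrix")
  Ap <- A / outer(s, s)
  d <- rowSums(Ap)
  if (any(d <= 0)) stop("density-normalized affinity has a zero row sum")
  structure(
    list(
      markov = Ap / d,
      sym = Ap / sqrt(outer(d, d)),
      stationary_weights = d,
      n = n
    ),
    class = "markov_operator"
  )
}

#' @export
print.markov_operator <- function(x, ...) {
  cat("<markov_operator> on", x$n, "points\n")
  invisible(x)
}

#' Spectral decomposition of a Markov operator (diffusion basis)
#'
#' Eigendecomposes the symmetric conjugate of the Markov operator, which
#' guarantees a real spectrum and Euclidean-orthonormal eigenvectors (the
#' geometry assumed by the beta null of the alignment statistic). Eigenpairs
#' are sorted by descending eigenvalue; by default the trivial pair (eigenvalue
#' 1, the near-constant stationary mode, which carries no geometric
#' information) is removed, so mode 1 of the returned basis is the first
#' nontrivial diffusion coordinate. Each eigenvector's sign is fixed by making
#' its largest-magnitude entry positive.
#'
#' @param M a `markov_operator`.
#' @param drop_trivial drop the trivial eigenvalue-1 pair (default `TRUE`).
#' @param t diffusion time used when forming diffusion coordinates; default 1.
#' @param basis_type `"symmetric"` (default) returns orthonormal eigenvectors
#'   of the symmetric conjugate; `"markov"` returns unit-normalized right
#'   eigenvectors of the row-stochastic operator itself (not orthonormal; for
#'   fidelity experiments only).
#' @return an object of class `diffusion_basis`: list with `eigenvalues`
#'   (non-increasing), `vectors` (unit-norm columns), `t`, `n`, `disconnected`
#'   (flag: more than one eigenvalue within 1e-10 of 1) and `trivial` (the
#'   removed pair, if any).
#' @export
diffusion_basis <- function(M, drop_trivial = TRUE, t = 1,
                            basis_type = c("symmetric", "markov")) {
  stopifnot(inherits(M, "markov_operator"))
  basis_type <- match.arg(basis_type)
  e <- eigen(M$sym, symmetric = TRUE)
  vals <- e$values
  vecs <- e$vectors
  if (basis_type == "markov") {
    vecs <- vecs / sqrt(M$stationary_weights)
    vecs <- sweep(vecs, 2, sqrt(colSums(vecs^2)), "/")
  }
  disconnected <- sum(vals > 1 - 1e-10) > 1L
  if (disconnected) {
    warning(warningCondition(
      paste0(
        "affinity graph appears disconnected: ",
        sum(vals > 1 - 1e-10), " eigenvalues within 1e-10 of 1"
      ),
      class = "mapalign_disconnected"
    ))
  }
  trivial <- NULL
  if (drop_trivial) {
    trivial <- list(eigenvalue = vals[1], vector = vecs[, 1])
    vals <- vals[-1]
    vecs <- vecs[, -1, drop = FALSE]
  }
  vecs <- fix_sign(vecs)
  structure(
    list(
      eigenvalues = vals,
      vectors = vecs,
      t = t,
      n = M$n,
      disconnected = disconnected,
      trivial = trivial
    ),
    class = "diffusion_basis"
  )
}

# deterministic sign convention: largest-magnitude entry of each column positive
fix_sign <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.diffusion_basis <- function(x, ...) {
  cat("<diffusion_basis> n =", x$n, ", modes =", length(x$eigenvalues),
      ", t =", x$t, "\n")
  cat("leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Truncated diffusion-map coordinates
#'
#' Returns the n-by-k matrix whose column `j` is `lambda_j^t * phi_j`, the
#' j-th diffusion coordinate at the basis's diffusion time. Truncation to the
#' leading `k` coordinates is the optimal k-dimensional embedding of the data
#' under the diffusion distance.
#'
#' @param B a `diffusion_basis`.
#' @param k number of coordinates; must not exceed the basis size.
#' @return numeric matrix with `k` columns.
#' @export
diffusion_coords <- function(B, k = length(B$eigenvalues)) {
  stopifnot(inherits(B, "diffusion_basis"))
  k <- as.integer(k)
  if (k < 1L || k > length(B$eigenvalues)) {
    stop("`k` must be between 1 and the basis size (", length(B$eigenvalues), ")")
  }
  sweep(B$vectors[, seq_len(k), drop = FALSE], 2,
        B$eigenvalues[seq_len(k)]^B$t, "*")
}

#' Diffusion distance by direct matrix power
#'
#' The L2 distance between the t-step transition distributions of random walks
#' started at points `i` and `j`:
#' \eqn{D_t(i,j)^2 = \sum_z (\hat A^t_{iz} - \hat A^t_{jz})^2}. Computed by
#' repeated matrix multiplication, so it serves as an independent oracle for
#' embedding-based distances.
#'
#' @param M a `markov_operator`.
#' @param t nonnegative integer diffusion time.
#' @param i,j point indices.
#' @return nonnegative scalar.
#' @export
diffusion_distance <- function(M, t, i, j) {
  stopifnot(inherits(M, "markov_operator"))
  n <- M$n
  i <- as.integer(i); j <- as.integer(j); t <- as.integer(t)
  if (t < 0) stop("`t` must be a nonnegative integer")
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("indices out of range")
  P <- markov_power(M$markov, t)
  sqrt(sum((P[i, ] - P[j, ])^2))
}

markov_power <- function(A, t) {
  P <- diag(nrow(A))
  for (s in seq_len(t)) P <- P %*% A
  P
}

#' Distance matrix to diffusion basis in one call
#'
#' Convenience wrapper chaining [gknn_kernel()], [markov_operator()] and
#' [diffusion_basis()].
#'
#' @inheritParams gknn_kernel
#' @inheritParams diffusion_basis
#' @return a `diffusion_basis`.
#' @export
diffusion_map_frame <- function(D, k_nn = 7L, t = 1, drop_trivial = TRUE,
                                dist_floor = FALSE) {
  diffusion_basis(
    markov_operator(gknn_kernel(D, k_nn = k_nn, dist_floor = dist_floor)),
    drop_trivial = drop_trivial, t = t
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.diffusion_basis <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    fraction = x$eigenvalues / sum(x$eigenvalues)
  )
}

#' Spectrum plot for a diffusion basis
#'
#' Eigenvalues against mode index on log-log axes; the bulk of a noisy
#' spectrum typically follows an approximate power law, and departures at the
#' head indicate macro-scale structure.
#'
#' @param object a `diffusion_basis`.
#' @param ... unused.
#' @export
autoplot.diffusion_basis <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[dat$eigenvalue > 0, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mode, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mode", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
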