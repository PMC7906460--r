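#' Norm of the projection of a unit vector onto a leading diffusion subspace
#'
#' Projects a unit vector onto the span of the leading `k` eigenvectors of a
#' second diffusion basis and returns the norm of the projection,
#' \eqn{\|\Pi_k \phi\| = \sqrt{\sum_{j \le k} \langle \phi, \phi_j \rangle^2}}
#' (the bases produced by [diffusion_basis()] are orthonormal, so this is an
#' orthogonal projection). Values near 1 mean the vector lies almost entirely
#' inside the other metric's macro-scale subspace.
#'
#' @param phi numeric unit vector of length n.
#' @param B2 a `diffusion_basis` on the same n points.
#' @param k subspace dimension.
#' @return projection norm in `[0, 1]`.
#' @export
project_norm <- function(phi, B2, k) {
  sqrt(project_sqnorm(phi, B2, k))
}

project_sqnorm <- function(phi, B2, k) {
  stopifnot(inherits(B2, "diffusion_basis"))
  if (length(phi) != B2$n) stop("`phi` has length ", length(phi), ", basis has n = ", B2$n)
  nrm <- sqrt(sum(phi^2))
  if (abs(nrm - 1) > 1e-8) stop("`phi` must be a unit vector (norm = ", signif(nrm, 6), ")")
  if (k < 1 || k > length(B2$eigenvalues)) {
    stop("`k` must be between 1 and the basis size (", length(B2$eigenvalues), ")")
  }
  sum(crossprod(B2$vectors[, seq_len(k), drop = FALSE], phi)^2)
}

#' Standardize a squared projection against the random-subspace null
#'
#' Under the null that the k-dimensional subspace is oriented uniformly at
#' random, the squared projection of a unit vector in R^n has mean `k/n` and
#' variance `2(n-k)k / (n^3 + 2n^2)`. This centers and scales a squared
#' projection accordingly:
#' \deqn{P = \left(\|\Pi_k\phi\|^2 - \frac{k}{n}\right)
#'       \sqrt{\frac{n^3 + 2n^2}{2(n-k)k}}.}
#'
#' @param sq_norm squared projection in `[0, 1]` (vectorized).
#' @param n ambient dimension (number of agents).
#' @param k subspace dimension, `0 < k < n`.
#' @return standardized value(s); approximately mean 0, variance 1 under the
#'   null.
#' @export
standardize_projection <- function(sq_norm, n, k) {
  if (k <= 0 || k >= n) stop("`k` must satisfy 0 < k < n")
  if (any(sq_norm < -1e-10 | sq_norm > 1 + 1e-10)) {
    stop("`sq_norm` must lie in [0, 1]")
  }
  (sq_norm - k / n) * sqrt((n^3 + 2 * n^2) / (2 * (n - k) * k))
}

#' Null model for squared projections of random unit vectors
#'
#' The squared norm of the projection of a uniformly random unit vector in
#' R^n onto a fixed k-dimensional subspace is beta distributed. The mean and
#' variance used for standardization are `k/n` and `2(n-k)k/(n^3+2n^2)`;
#' these are the moments of a Beta(k/2, (n-k)/2) law, and that shape order is
#' used for sampling and density evaluation. (The reversed order
#' Beta((n-k)/2, k/2), which appears in some accounts, has mean `(n-k)/n`
#' and is inconsistent with the stated moments; the discrepancy is recorded
#' in the `shape_note` field rather than silently dropped.)
#'
#' @param n ambient dimension.
#' @param k subspace dimension, `0 < k < n`.
#' @return object of class `mas_null`: list with `n`, `k`, `mean`, `variance`,
#'   `shape1` (= k/2), `shape2` (= (n-k)/2) and `shape_note`.
#' @export
null_model <- function(n, k) {
  if (k <= 0 || k >= n) stop("`k` must satisfy 0 < k < n")
  structure(
    list(
      n = n, k = k,
      mean = k / n,
      variance = 2 * (n - k) * k / (n^3 + 2 * n^2),
      shape1 = k / 2,
      shape2 = (n - k) / 2,
      shape_note = paste0(
        "shapes (k/2, (n-k)/2) chosen to match the stated moments ",
        "mean = k/n, var = 2(n-k)k/(n^3+2n^2); the reversed order would ",
        "imply mean (n-k)/n"
      )
    ),
    class = "mas_null"
  )
}

#' @export
print.mas_null <- function(x, ...) {
  cat("<mas_null> n =", x$n, ", k =", x$k,
      "; Beta(", x$shape1, ",", x$shape2, ")",
      "; mean =", signif(x$mean, 4), ", var =", signif(x$variance, 4), "\n")
  invisible(x)
}

#' Density of the squared-projection null
#' @param x quantiles in `[0, 1]`.
#' @param null a `mas_null`.
#' @return density values.
#' @export
dnull_projection <- function(x, null) {
  stopifnot(inherits(null, "mas_null"))
  stats::dbeta(x, null$shape1, null$shape2)
}

#' Sample squared projections from the null
#' @param m number of draws.
#' @param null a `mas_null`.
#' @return numeric vector of length `m`.
#' @export
rnull_projection <- function(m, null) {
  stopifnot(inherits(null, "mas_null"))
  stats::rbeta(m, null$shape1, null$shape2)
}

#' Map alignment statistic (MAS) between two diffusion geometries
#'
#' Measures how much of the macro-scale organization seen through metric 1 is
#' reflected in metric 2's diffusion coordinates. Each leading eigenvector of
#' basis 1 is projected onto the span of basis 2's leading `k` eigenvectors;
#' the squared projections are standardized against the random-subspace null
#' (see [standardize_projection()]); and the standardized values are summed
#' with weights \eqn{\hat u = (\lambda_1, \dots, \lambda_k)/\|\cdot\|_2}
#' proportional to the eigenvalues of basis 1 (each mode's share of the
#' macrostructure):
#' \deqn{Z_k = \sum_{j=1}^{k} \hat u_j \, P_k(\phi^{(1)}_j).}
#' The statistic is not symmetric in its arguments; both directions can be
#' computed by swapping `B1` and `B2`. If the leading eigenvalues of `B1` are
#' all numerically zero the weights are undefined; the statistic is then
#' reported as 0 with the `unweightable` flag set.
#'
#' @param B1,B2 `diffusion_basis` objects on the same agents (same n, same
#'   ordering). If both carry `agent_ids` attributes they must match.
#' @param k number of modes used for the projection subspace, the weight
#'   vector, and the summation range alike.
#' @return object of class `mas`: list with `n`, `k`, `sq_projections`,
#'   `standardized` (the per-mode P values), `weights`, `statistic` (Z_k) and
#'   `unweightable`.
#' @export
map_alignment <- function(B1, B2, k) {
  stopifnot(inherits(B1, "diffusion_basis"), inherits(B2, "diffusion_basis"))
  if (B1$n != B2$n) stop("bases are on different numbers of agents: ", B1$n, " vs ", B2$n)
  ids1 <- attr(B1, "agent_ids"); ids2 <- attr(B2, "agent_ids")
  if (!is.null(ids1) && !is.null(ids2) && !identical(ids1, ids2)) {
    stop("bases are on different agent sets; difference: ",
         paste(union(setdiff(ids1, ids2), setdiff(ids2, ids1)), collapse = ", "))
  }
  k <- as.integer(k)
  if (k < 1L || k > length(B1$eigenvalues) || k > length(B2$eigenvalues)) {
    stop("`k` exceeds a basis size")
  }
  if (k >= B1$n) stop("`k` must be smaller than n for the null standardization")
  n <- B1$n
  idx <- seq_len(k)
  # inner products <phi_j^(1), phi_i^(2)>, columns indexed by j
  C <- crossprod(B2$vectors[, idx, drop = FALSE], B1$vectors[, idx, drop = FALSE])
  sq <- colSums(C^2)
  P <- standardize_projection(pmin(sq, 1), n, k)
  lam <- B1$eigenvalues[idx]^B1$t
  lam_norm <- sqrt(sum(lam^2))
  if (lam_norm < 1e-12) {
    u_hat <- rep(NA_real_, k)
    z <- 0
    unweightable <- TRUE
  } else {
    u_hat <- lam / lam_norm
    z <- sum(u_hat * P)
    unweightable <- FALSE
  }
  structure(
    list(
      n = n, k = k,
      sq_projections = sq,
      standardized = P,
      weights = u_hat,
      statistic = z,
      unweightable = unweightable
    ),
    class = "mas"
  )
}

#' @export
print.mas <- function(x, ...) {
  cat("<mas> Z_", x$k, " = ", signif(x$statistic, 5), " (n = ", x$n, ")",
      if (x$unweightable) " [unweightable]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mas <- function(x, ...) {
  tibble::tibble(
    mode = seq_len(x$k),
    sq_projection = x$sq_projections,
    standardized = x$standardized,
    weight = x$weights
  )
}

#' @export
glance.mas <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, statistic = x$statistic, unweightable = x$unweightable
  )
}

#' Suggest the subspace size k from spectral decay
#'
#' The bulk of a diffusion spectrum typically follows an approximate power
#' law \eqn{\lambda_j \approx C j^{-\beta}}; modes rising above that tail
#' carry macro-scale structure. For each candidate cut `c` (from 0, meaning
#' the whole spectrum is tail) the eigenvalues beyond the cut are fit by
#' least squares on log-log axes as a power law in their position within the
#' tail, \eqn{\lambda_{c+m} \approx C m^{-\beta}}, and the smallest cut for
#' which every tail eigenvalue stays within `rel_tol` relative error of the
#' fit is returned (as `max(cut, 1)`, since at least one macro-scale mode is
#' always retained). If no cut satisfies the tolerance the cut minimizing
#' the worst relative error is returned with a warning.
#'
#' When several spectra (frames) are supplied, the fit uses their element-wise
#' mean, and a stability diagnostic reports, per mode, the variability across
#' frames of the variance-explained fraction \eqn{\lambda_j / \sum_i \lambda_i};
#' modes whose fraction is stable across frames behave like tail (noise)
#' modes.
#'
#' @param spectra a numeric vector of eigenvalues, or a list of such vectors
#'   (one per frame), each of length at least 10, non-increasing.
#' @param rel_tol maximum relative deviation from the power-law fit for a
#'   mode to count as tail (default 0.2).
#' @param min_tail minimum number of modes that must remain in the tail fit
#'   (default 5).
#' @param stability_cv coefficient-of-variation threshold below which a
#'   mode's variance-explained fraction is flagged stable (default 0.25).
#' @return integer `k` with attributes `fit` (tibble: candidate cut, max
#'   relative error) and, when multiple spectra are given, `stability`
#'   (tibble: mode, mean fraction, cv, stable flag).
#' @export
suggest_k <- function(spectra, rel_tol = 0.2, min_tail = 5L, stability_cv = 0.25) {
  if (!is.list(spectra)) spectra <- list(spectra)
  if (length(spectra) < 1) stop("need at least one spectrum")
  m <- min(lengths(spectra))
  if (m < 10) stop("each spectrum must have at least 10 eigenvalues")
  mat <- do.call(rbind, lapply(spectra, function(s) s[seq_len(m)]))
  lam <- colMeans(mat)

  cuts <- 0:(m - min_tail - 1L)
  fit_errs <- purrr::map_dbl(cuts, function(cut) {
    j <- seq(cut + 1L, m)
    keep <- lam[j] > 0
    if (sum(keep) < 3) return(NA_real_)
    pos <- (j - cut)[keep]  # position within the tail
    lj <- log(pos); ll <- log(lam[j][keep])
    co <- stats::coef(stats::lm.fit(cbind(1, lj), ll))
    fitted <- exp(co[1] + co[2] * lj)
    max(abs(lam[j][keep] - fitted) / fitted)
  })
  if (all(is.na(fit_errs))) stop("all tail eigenvalues non-positive; cannot fit")
  ok <- which(!is.na(fit_errs) & fit_errs < rel_tol)
  if (length(ok) > 0) {
    k <- cuts[ok[1]]
  } else {
    k <- cuts[which.min(fit_errs)]
    warning("no cut meets rel_tol = ", rel_tol,
            "; returning the cut with the smallest worst-case deviation")
  }
  out <- max(1L, as.integer(k))
  attr(out, "fit") <- tibble::tibble(cut = cuts, max_rel_error = fit_errs)
  if (length(spectra) > 1) {
    tot <- rowSums(mat)
    frac <- mat / tot
    mu <- colMeans(frac)
    cv <- apply(frac, 2, stats::sd) / mu
    attr(out, "stability") <- tibble::tibble(
      mode = seq_len(m),
      mean_fraction = mu,
      cv = cv,
      stable = cv < stability_cv
    )
  }
  out
}
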