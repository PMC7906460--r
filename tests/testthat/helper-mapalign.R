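# shared fixtures built in code

# distance matrix of a random planar point cloud
random_distance_matrix <- function(n, seed = NULL, dim = 2) {
  draw <- function() as.matrix(dist(matrix(rnorm(n * dim), n, dim)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# orthonormal columns via QR of a gaussian matrix
random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

# hand-built diffusion basis for alignment tests (bypasses the eigensolve)
synthetic_basis <- function(vectors, eigenvalues, t = 1) {
  structure(
    list(
      eigenvalues = eigenvalues, vectors = vectors, t = t,
      n = nrow(vectors), disconnected = FALSE, trivial = NULL
    ),
    class = "diffusion_basis"
  )
}

# basis pair from independent random geometries
random_geometry_basis <- function(n, k_nn = 7) {
  suppressWarnings(diffusion_map_frame(as.matrix(dist(matrix(rnorm(2 * n), n, 2))),
                                       k_nn = k_nn))
}

quiet_pipeline <- function(...) suppressWarnings(run_pipeline(...))
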