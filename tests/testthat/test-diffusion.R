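test_that("GkNN kernel matches hand-evaluated values on collinear points", {
  D <- as.matrix(dist(c(0, 1, 3)))
  K <- gknn_kernel(D, k_nn = 1)
  # nearest-neighbor distances are 1, 1, 2
  expect_equal(K[1, 2], exp(-1))
  expect_equal(K[2, 3], exp(-2))
  expect_equal(K[1, 3], exp(-4.5))
  expect_equal(diag(K), rep(1, 3))
  expect_equal(K, t(K))
})

test_that("GkNN kernel is invariant under global distance rescaling", {
  for (seed in 1:3) {
    D <- random_distance_matrix(25, seed = seed)
    K <- gknn_kernel(D, k_nn = 7)
    for (c in c(1e-3, 1, 1e3)) {
      expect_lt(max(abs(gknn_kernel(c * D, k_nn = 7) - K)), 1e-12)
    }
  }
})

test_that("GkNN kernel rejects bad inputs and duplicates", {
  D <- random_distance_matrix(10, seed = 1)
  expect_error(gknn_kernel(D, k_nn = 10), "k_nn")
  expect_error(gknn_kernel(D, k_nn = 0), "k_nn")
  Ddup <- as.matrix(dist(c(0, 0, 1, 3)))
  expect_error(gknn_kernel(Ddup, k_nn = 1), "duplicate")
  # tolerant mode floors the bandwidth instead
  K <- gknn_kernel(Ddup, k_nn = 1, dist_floor = TRUE)
  expect_true(all(is.finite(K)))
  Dneg <- D; Dneg[1, 2] <- Dneg[2, 1] <- -1
  expect_error(gknn_kernel(Dneg, 3), "negative")
})

test_that("Markov normalization matches the 2x2 closed form and uniform case", {
  a <- 0.3
  M <- markov_operator(matrix(c(1, a, a, 1), 2))
  expect_equal(M$markov, matrix(c(1, a, a, 1) / (1 + a), 2))
  # constant affinity gives the uniform operator
  Mu <- markov_operator(matrix(0.7, 5, 5))
  expect_equal(Mu$markov, matrix(1 / 5, 5, 5))
})

test_that("Markov operator rows sum to one on random inputs", {
  for (seed in 1:5) {
    A <- gknn_kernel(random_distance_matrix(30, seed = seed), k_nn = 7)
    M <- markov_operator(A)
    expect_lt(max(abs(rowSums(M$markov) - 1)), 1e-10)
    expect_true(all(M$markov >= 0))
    # similar to the symmetric conjugate: same spectrum
    ev_m <- sort(Re(eigen(M$markov, only.values = TRUE)$values))
    ev_s <- sort(eigen(M$sym, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(ev_m, ev_s, tolerance = 1e-8)
  }
})

test_that("spectral decomposition resolves the 2-state chain by hand", {
  p <- 0.25
  sym <- matrix(c(1 - p, p, p, 1 - p), 2)
  M <- structure(
    list(markov = sym, sym = sym, stationary_weights = c(1, 1), n = 2L),
    class = "markov_operator"
  )
  B <- diffusion_basis(M)
  expect_equal(B$eigenvalues, 1 - 2 * p)
  expect_equal(abs(B$vectors[, 1]), rep(1 / sqrt(2), 2))
  # diffusion coordinate = lambda * phi
  expect_equal(sort(diffusion_coords(B, 1)[, 1]),
               sort(0.5 * c(1, -1) / sqrt(2)))
})

test_that("uniform operator has an all-zero spectrum after trivial removal", {
  B <- diffusion_basis(markov_operator(matrix(1, 6, 6)))
  expect_equal(B$eigenvalues, rep(0, 5), tolerance = 1e-12)
})

test_that("eigendecomposition reconstructs matrix powers of the operator", {
  for (seed in 1:3) {
    D <- random_distance_matrix(40, seed = seed)
    M <- markov_operator(gknn_kernel(D, k_nn = 7))
    B <- diffusion_basis(M, drop_trivial = FALSE)
    d <- M$stationary_weights
    for (t in c(1, 2, 5)) {
      S_t <- B$vectors %*% (B$eigenvalues^t * t(B$vectors))
      A_t <- (1 / sqrt(d)) * S_t %*% diag(sqrt(d))
      expect_lt(max(abs(A_t - mapalign:::markov_power(M$markov, t))), 1e-8)
    }
  }
})

test_that("retained spectrum is real and bounded by one", {
  for (seed in 1:5) {
    B <- diffusion_map_frame(random_distance_matrix(35, seed = seed), k_nn = 5)
    expect_true(is.numeric(B$eigenvalues))
    expect_true(all(abs(B$eigenvalues) <= 1 + 1e-10))
    expect_true(all(diff(B$eigenvalues) <= 1e-12))
    # orthonormal columns
    G <- crossprod(B$vectors)
    expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  }
})

test_that("relabeling agents permutes the diffusion basis equivariantly", {
  D <- random_distance_matrix(20, seed = 4)
  perm <- withr::with_seed(9, sample(20))
  B1 <- diffusion_map_frame(D, k_nn = 5)
  B2 <- diffusion_map_frame(D[perm, perm], k_nn = 5)
  expect_equal(B1$eigenvalues, B2$eigenvalues, tolerance = 1e-10)
  for (j in 1:5) {
    v1 <- B1$vectors[perm, j]
    v2 <- B2$vectors[, j]
    expect_lt(min(max(abs(v1 - v2)), max(abs(v1 + v2))), 1e-7)
  }
})

test_that("disconnected affinity graphs are flagged with a structured warning", {
  # two far-separated blocks with essentially zero cross affinity
  A <- diag(10)
  A[1:5, 1:5] <- 0.9; A[6:10, 6:10] <- 0.9
  diag(A) <- 1
  A[1:5, 6:10] <- A[6:10, 1:5] <- 1e-300
  expect_warning(
    B <- diffusion_basis(markov_operator(A)),
    class = "mapalign_disconnected"
  )
  expect_true(B$disconnected)
})

test_that("diffusion map truncation scales unit eigenvectors by eigenvalues", {
  B <- diffusion_map_frame(random_distance_matrix(15, seed = 2), k_nn = 4)
  k <- length(B$eigenvalues)
  coords <- diffusion_coords(B, k)
  expect_equal(sqrt(colSums(coords^2)), abs(B$eigenvalues), tolerance = 1e-8)
  expect_error(diffusion_coords(B, k + 1), "basis size")
})

test_that("diffusion distance agrees with hand-computed cases", {
  sym <- matrix(c(0.75, 0.25, 0.25, 0.75), 2)
  M <- structure(
    list(markov = sym, sym = sym, stationary_weights = c(1, 1), n = 2L),
    class = "markov_operator"
  )
  expect_equal(diffusion_distance(M, 1, 1, 2)^2, 0.5)
  expect_equal(diffusion_distance(M, 1, 1, 1), 0)
  # uniform operator: all rows identical after one step
  Mu <- markov_operator(matrix(1, 4, 4))
  expect_equal(diffusion_distance(Mu, 1, 1, 3), 0)
  expect_error(diffusion_distance(M, 1, 1, 5), "out of range")
})
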