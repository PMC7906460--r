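test_that("covariance matrix is diagonal for a shared basis and sign-stable", {
  set.seed(20)
  Q <- random_orthonormal(30, 4)
  B <- synthetic_basis(Q[, 1:2], c(0.9, 0.5))
  expect_equal(covariance_matrix(B, B, 2), diag(c(0.81, 0.25)), tolerance = 1e-12)
  # mutually orthogonal leading modes give the zero matrix
  B2 <- synthetic_basis(Q[, 3:4], c(0.9, 0.5))
  expect_equal(covariance_matrix(B, B2, 2), matrix(0, 2, 2), tolerance = 1e-12)
  # flipping an eigenvector's sign flips one row, leaving magnitudes unchanged
  Bf <- synthetic_basis(cbind(-Q[, 1], Q[, 2]), c(0.9, 0.5))
  x1 <- covariance_matrix(B, B2, 2); x2 <- covariance_matrix(Bf, B2, 2)
  expect_equal(abs(x1), abs(x2), tolerance = 1e-12)
  expect_equal(covariance_vector(x1), covariance_vector(x2))
})

test_that("covariance entries respect the Cauchy-Schwarz eigenvalue bound", {
  set.seed(21)
  B1 <- random_geometry_basis(40)
  B2 <- random_geometry_basis(40)
  k <- 6
  xi <- covariance_matrix(B1, B2, k)
  bound <- outer(B1$eigenvalues[1:k], B2$eigenvalues[1:k])
  expect_true(all(abs(xi) <= abs(bound) + 1e-10))
})

test_that("covariance vectors sort magnitudes with deterministic ties", {
  xi <- matrix(c(0.2, -0.5, 0.1, 0.3), 2, byrow = TRUE)
  expect_equal(covariance_vector(xi), c(0.5, 0.3, 0.2, 0.1))
  expect_equal(covariance_vector(matrix(0, 3, 3)), rep(0, 9))
  expect_equal(covariance_vector(xi), covariance_vector(-xi))
  # exact ties keep row-major order (a permutation-stable contract)
  tied <- matrix(c(0.5, 0.5, 0.5, 0.2), 2, byrow = TRUE)
  expect_equal(covariance_vector(tied), c(0.5, 0.5, 0.5, 0.2))
})

test_that("order parameters recover canonical configurations", {
  # rigid translation: full polarization
  pos <- withr::with_seed(22, matrix(runif(20), 10, 2))
  vel <- matrix(rep(c(2, 1), each = 10), 10, 2)
  op <- order_parameters(pos, vel)
  expect_equal(op$o_p, 1)
  expect_equal(op$state, "polarized")
  # perfect counterclockwise mill on the unit circle
  mill_pos <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  mill_vel <- rbind(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
  opm <- order_parameters(mill_pos, mill_vel)
  expect_equal(opm$o_r, 1)
  expect_equal(opm$o_p, 0)
  expect_equal(opm$state, "milling")
  expect_error(order_parameters(mill_pos, 0 * mill_vel), "zero speed")
})

test_that("random headings give polarization shrinking as 1/sqrt(N)", {
  set.seed(23)
  for (N in c(100, 400)) {
    op <- replicate(200, {
      th <- runif(N, 0, 2 * pi)
      order_parameters(matrix(runif(2 * N), N, 2), cbind(cos(th), sin(th)))$o_p
    })
    # E|sum of N random unit vectors| ~ sqrt(pi N)/2
    expect_lt(abs(mean(op) * sqrt(N) - sqrt(pi) / 2), 0.15)
  }
})

test_that("reference states follow the polarization/rotation demarcation", {
  expect_equal(reference_state(0.2, 0.8), "milling")
  expect_equal(reference_state(0.8, 0.1), "polarized")
  expect_equal(reference_state(0.2, 0.2), "swarming")
  expect_equal(reference_state(0.5, 0.5), "transitional")
  expect_equal(reference_state(c(0.1, 0.9), c(0.9, 0.1)),
               c("milling", "polarized"))
  expect_error(reference_state(1.2, 0.5), "\\[0, 1\\]")
})

test_that("classification gates incoherent frames and recovers clean clusters", {
  set.seed(24)
  # all frames below the gate: no clustering at all
  low <- tibble::tibble(
    frame = 1:5, z = rep(1, 5),
    xi = replicate(5, runif(9), simplify = FALSE)
  )
  lab <- classify_frames(low, z_threshold = 3, n_clusters = 2)
  expect_true(all(lab$labels$label == "N"))
  expect_null(lab$centers)

  # three well-separated clusters plus gated frames
  centers <- list(rep(0, 9), rep(10, 9), rep(20, 9))
  zs <- c(5, 8, 12)  # cluster mean Z increasing with index
  frames <- purrr::map_dfr(1:3, function(g) {
    tibble::tibble(
      frame = (g - 1) * 20 + 1:20,
      z = zs[g] + seq(-0.5, 0.5, length.out = 20),
      xi = purrr::map(1:20, ~ centers[[g]] + rnorm(9, 0, 0.1))
    )
  })
  gated <- tibble::tibble(frame = 61:70, z = 0.5,
                          xi = replicate(10, rep(5, 9), simplify = FALSE))
  all_frames <- dplyr::bind_rows(frames, gated)
  res <- classify_frames(all_frames, z_threshold = 3, n_clusters = 3, seed = 7)
  truth <- rep(c(3, 2, 1, NA), times = c(20, 20, 20, 10))  # G1 = highest mean Z
  got <- res$labels$label
  expect_true(all(got[61:70] == "N"))
  expect_equal(got[1:20], rep("G3", 20))
  expect_equal(got[21:40], rep("G2", 20))
  expect_equal(got[41:60], rep("G1", 20))
  # no coherent frame is gated and vice versa
  expect_true(all((all_frames$z < 3) == (got == "N")))
  # determinism
  res2 <- classify_frames(all_frames, z_threshold = 3, n_clusters = 3, seed = 7)
  expect_identical(res$labels, res2$labels)
  # cluster naming tracks mean Z ordering
  expect_equal(res$cluster_summary$label[1], "G1")
  expect_error(classify_frames(gated[1:2, ] |> dplyr::mutate(z = 10),
                               n_clusters = 3), "coherent frames")
})
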