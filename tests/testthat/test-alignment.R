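test_that("projection norms behave at the extremes of the span", {
  set.seed(10)
  n <- 30
  Q <- random_orthonormal(n, 12)
  B2 <- synthetic_basis(Q[, 1:10], seq(0.9, 0.45, length.out = 10))
  expect_equal(project_norm(Q[, 1], B2, 5), 1)
  expect_equal(project_norm(Q[, 12], B2, 10), 0)
  expect_error(project_norm(2 * Q[, 1], B2, 5), "unit vector")
})

test_that("squared projections of random unit vectors match the beta mean", {
  set.seed(11)
  n <- 200; k <- 15; m <- 5000
  U <- random_orthonormal(n, k)
  sq <- replicate(m, {
    v <- rnorm(n); v <- v / sqrt(sum(v^2))
    sum(crossprod(U, v)^2)
  })
  nm <- null_model(n, k)
  se <- sqrt(nm$variance / m)
  expect_lt(abs(mean(sq) - k / n), 3 * se)
})

test_that("standardization matches its printed closed form", {
  expect_equal(standardize_projection(10 / 100, 100, 10), 0)
  expect_equal(standardize_projection(1, 100, 10),
               0.9 * sqrt(1020000 / 1800), tolerance = 1e-10)
  expect_equal(standardize_projection(0, 100, 10),
               -0.1 * sqrt(1020000 / 1800), tolerance = 1e-10)
  expect_error(standardize_projection(0.5, 10, 10), "0 < k < n")
  # affine with positive slope
  s <- standardize_projection(seq(0, 1, by = 0.1), 50, 5)
  expect_true(all(diff(s) > 0))
  expect_equal(diff(diff(s)), rep(0, 9), tolerance = 1e-10)
})

test_that("the null model carries consistent moments and a calibrated law", {
  nm <- null_model(100, 10)
  expect_equal(nm$mean, 0.1)
  expect_equal(nm$variance, 1800 / 1020000)
  # moments of Beta(shape1, shape2) agree with the printed formulas
  a <- nm$shape1; b <- nm$shape2
  expect_equal(a / (a + b), nm$mean)
  expect_equal(a * b / ((a + b)^2 * (a + b + 1)), nm$variance)
  expect_error(null_model(10, 10), "0 < k < n")

  # goodness of fit of true squared projections against the configured law
  set.seed(12)
  n <- 200; k <- 15
  nm2 <- null_model(n, k)
  U <- random_orthonormal(n, k)
  sq <- replicate(5000, {
    v <- rnorm(n); v <- v / sqrt(sum(v^2))
    sum(crossprod(U, v)^2)
  })
  ks <- stats::ks.test(sq, function(q) stats::pbeta(q, nm2$shape1, nm2$shape2))
  expect_gt(ks$p.value, 0.01)
})

test_that("map alignment reproduces its closed forms for nested bases", {
  set.seed(13)
  n <- 100; k <- 10
  Q <- random_orthonormal(n, 20)
  lam <- rep(0.8, 20)
  B <- synthetic_basis(Q, lam)
  z_same <- map_alignment(B, B, k)
  p_max <- standardize_projection(1, n, k)
  expect_equal(z_same$statistic, sqrt(k) * p_max, tolerance = 1e-8)
  expect_equal(z_same$sq_projections, rep(1, k), tolerance = 1e-10)
  # orthogonal bases: negative closed form
  B1 <- synthetic_basis(Q[, 1:10], lam[1:10])
  B2 <- synthetic_basis(Q[, 11:20], lam[1:10])
  z_orth <- map_alignment(B1, B2, k)
  expect_equal(z_orth$statistic, sqrt(k) * standardize_projection(0, n, k),
               tolerance = 1e-8)
})

test_that("map alignment validates inputs and flags degenerate weights", {
  set.seed(14)
  Q <- random_orthonormal(40, 10)
  B1 <- synthetic_basis(Q[, 1:5], rep(0.5, 5))
  B2 <- synthetic_basis(Q[, 6:10], rep(0.5, 5))
  expect_error(map_alignment(B1, synthetic_basis(random_orthonormal(30, 5), rep(0.5, 5)), 3),
               "different numbers")
  attr(B1, "agent_ids") <- letters[1:40]
  B2b <- B2; attr(B2b, "agent_ids") <- c(letters[1:39], "zz")
  expect_error(map_alignment(B1, B2b, 3), "different agent sets")
  # zero eigenvalues: unweightable, Z = 0
  B0 <- synthetic_basis(Q[, 1:5], rep(0, 5))
  z <- map_alignment(B0, B2, 3)
  expect_true(z$unweightable)
  expect_equal(z$statistic, 0)
  # asymmetry: forward and reverse are both computable and differ in general
  B1w <- synthetic_basis(Q[, 1:5], c(0.9, 0.5, 0.3, 0.2, 0.1))
  Vmix <- qr.Q(qr(Q[, 1:5] + 0.3 * Q[, 6:10]))
  B2w <- synthetic_basis(Vmix, c(0.7, 0.6, 0.5, 0.4, 0.3))
  expect_false(isTRUE(all.equal(map_alignment(B1w, B2w, 4)$statistic,
                                map_alignment(B2w, B1w, 4)$statistic)))
})

test_that("standardized summands are null-calibrated and complete at k = n", {
  set.seed(15)
  n <- 120
  # completeness: projections over the full basis sum to 1, P telescopes to max
  Q <- random_orthonormal(n, n)
  B2 <- synthetic_basis(Q, seq(1, 0.01, length.out = n))
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  expect_equal(mapalign:::project_sqnorm(v, B2, n), 1, tolerance = 1e-8)

  # null calibration of P at moderate draws
  k <- 10
  U <- random_orthonormal(n, k)
  P <- standardize_projection(replicate(5000, {
    w <- rnorm(n); w <- w / sqrt(sum(w^2))
    sum(crossprod(U, w)^2)
  }), n, k)
  expect_lt(abs(mean(P)), 0.05)
  expect_lt(abs(stats::var(P) - 1), 0.1)
})

test_that("Z stabilizes once k exceeds the shared structure", {
  # bases share their first 3 modes exactly; later modes are independent
  set.seed(16)
  n <- 150
  Q <- random_orthonormal(n, n)
  shared <- Q[, 1:3]
  rest1 <- Q[, 4:30]
  rest2 <- qr.Q(qr(Q[, 4:n] %*% matrix(rnorm((n - 3) * 27), n - 3, 27)))
  lam <- seq(0.95, 0.4, length.out = 30)
  B1 <- synthetic_basis(cbind(shared, rest1), lam)
  B2 <- synthetic_basis(cbind(shared, rest2), lam)
  z <- vapply(c(3, 8, 13, 18, 23), function(k) map_alignment(B1, B2, k)$statistic,
              numeric(1))
  gaps <- abs(diff(z))
  expect_lt(gaps[4], gaps[1])
  expect_lt(max(gaps[3:4]), 0.5 * gaps[1])
})

test_that("identical inputs give bit-identical alignment results", {
  set.seed(17)
  D1 <- random_distance_matrix(40)
  D2 <- random_distance_matrix(40)
  B1a <- diffusion_map_frame(D1); B2a <- diffusion_map_frame(D2)
  B1b <- diffusion_map_frame(D1); B2b <- diffusion_map_frame(D2)
  expect_identical(map_alignment(B1a, B2a, 8), map_alignment(B1b, B2b, 8))
})

test_that("suggest_k finds the head of constructed spectra", {
  lam <- c(rep(0.9, 4), 0.9 * ((5:30) - 4)^(-2))
  k <- suggest_k(lam)
  expect_true(as.integer(k) %in% c(4L, 5L))
  # exact power law from the first mode
  expect_equal(as.integer(suggest_k(2 * (1:30)^(-1.5))), 1L)
  # stability diagnostic over frames: pure noise spectra with stable
  # variance-explained fractions flag (nearly) all modes as tail
  set.seed(18)
  spectra <- lapply(1:8, function(i) (1:40)^(-1.2) * exp(rnorm(40, 0, 0.02)))
  ks <- suggest_k(spectra)
  stab <- attr(ks, "stability")
  expect_true(mean(stab$stable) > 0.9)
  expect_error(suggest_k(rep(-1, 20)), "non-positive")
})
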