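test_that("perspective projection obeys pinhole geometry", {
  cam <- nas_camera(eye = c(0, 0, 0), look = c(0, 1, 0))
  # a point on the optical axis projects to the screen center
  expect_equal(unname(project_trajectory(rbind(c(0, 100, 0)), cam)[1, ]),
               c(512, 384))
  # mirror-symmetric points project mirror-symmetrically
  pr <- project_trajectory(rbind(c(-50, 100, 0), c(50, 100, 0)), cam)
  expect_equal(pr[1, 1] - 512, -(pr[2, 1] - 512))
  # doubling the depth halves the offset from center
  pr2 <- project_trajectory(rbind(c(50, 100, 0), c(50, 200, 0)), cam)
  expect_equal(pr2[1, 1] - 512, 2 * (pr2[2, 1] - 512), tolerance = 1e-9)
  # near-plane handling
  expect_warning(pr3 <- project_trajectory(rbind(c(0, -5, 0),
                                                 c(0, 100, 0)), cam),
                 "near plane")
  expect_equal(nrow(pr3), 1)
  expect_error(project_trajectory(matrix(0, 0, 3), cam), "empty")
  expect_error(suppressWarnings(
    project_trajectory(rbind(c(0, -5, 0)), cam)), "all points")
  expect_error(nas_camera(fov_h = 3.5), "fov_h")
})

test_that("trajectory averaging resamples, excludes outliers, and means", {
  line <- cbind(seq(0, 10, length.out = 23), 0)
  rs <- resample_path(line, 5)
  expect_equal(rs[, 1], seq(0, 10, length.out = 5))

  same <- replicate(4, cbind(0:10, 0), simplify = FALSE)
  av <- average_trajectory(same, n_points = 11)
  expect_equal(av$mean, cbind(0:10, 0), ignore_attr = TRUE)
  expect_false(any(av$outlier))

  # 9 identical + 1 grossly deviant: the deviant is excluded
  dev <- c(replicate(9, cbind(0:10, 0), simplify = FALSE),
           list(cbind(0:10, 40)))
  av2 <- average_trajectory(dev, n_points = 11)
  expect_equal(which(av2$outlier), 10)
  expect_equal(av2$mean[, 2], rep(0, 11))

  # two straight segments sharing endpoints average to the midline
  a <- rbind(c(0, 0), c(10, 10))
  b <- rbind(c(0, 0), c(10, -10))
  av3 <- average_trajectory(list(a, b), n_points = 5)
  expect_equal(av3$mean[, 2], rep(0, 5))
  expect_error(average_trajectory(list(a)), "at least 2")
})

test_that("discrete Frechet equals the brute-force coupling oracle", {
  expect_equal(discrete_frechet(rbind(c(0, 0), c(1, 1)),
                                rbind(c(0, 0), c(1, 1))), 0)
  expect_equal(discrete_frechet(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_equal(discrete_frechet(rbind(c(0, 0), c(4, 0)),
                                rbind(c(0, 3), c(4, 3))), 3)
  set.seed(77)
  for (i in 1:200) {
    A <- matrix(runif(2 * sample(1:6, 1)), ncol = 2)
    B <- matrix(runif(2 * sample(1:6, 1)), ncol = 2)
    expect_equal(discrete_frechet(A, B), frechet_brute(A, B),
                 tolerance = 1e-12)
  }
})

test_that("discrete Frechet is a metric on sampled paths", {
  set.seed(78)
  paths <- replicate(12, matrix(runif(10), ncol = 2), simplify = FALSE)
  for (i in 1:25) {
    idx <- sample(12, 3)
    a <- paths[[idx[1]]]; b <- paths[[idx[2]]]; c_ <- paths[[idx[3]]]
    dab <- discrete_frechet(a, b)
    expect_equal(dab, discrete_frechet(b, a), tolerance = 1e-12)
    expect_lte(dab, discrete_frechet(a, c_) + discrete_frechet(c_, b) +
                 1e-12)
  }
})

test_that("link correlation ranks matching and inverted geometries", {
  set.seed(9)
  D <- matrix(0, 9, 9)
  D[upper.tri(D)] <- runif(36)
  D <- D + t(D)
  expect_equal(link_correlation(D, D), 1)
  expect_equal(link_correlation(D, max(D) - D + diag(9) * 0), -1)
  expect_warning(r0 <- link_correlation(D, matrix(1, 9, 9) - diag(1, 9)),
                 "constant")
  expect_equal(r0, 0)
})

test_that("alternative distance matrices are well-formed", {
  for (D in list(optimal_frechet_matrix(), target_distance_matrix())) {
    expect_equal(dim(D), c(9L, 9L))
    expect_true(isSymmetric(unclass(D), check.attributes = FALSE))
    expect_equal(max(D), 1)
    expect_equal(unname(diag(D)), rep(0, 9))
  }
})

test_that("planted sessions link sequence geometry to the viewpoint", {
  fx <- planted_fixture()
  rho <- link_correlation(fx$emb$cent$dist, fx$frechet)
  expect_gt(rho, 0.8)
  # stronger than the bird's-eye (world frame) association
  rho_world <- link_correlation(fx$emb$cent$dist,
                                world_frechet_matrix(fx$session))
  expect_gt(rho, rho_world)
  # and clearly outside the label-shuffle null
  null <- shuffle_link(fx$emb$proj, fx$emb$labels, fx$frechet,
                       n_shuffles = 50, seed = 3)
  expect_gt(rho, quantile(null, 0.95))
  expect_identical(null, shuffle_link(fx$emb$proj, fx$emb$labels,
                                      fx$frechet, n_shuffles = 50,
                                      seed = 3))
  expect_error(shuffle_link(fx$emb$proj, fx$emb$labels, fx$frechet,
                            n_shuffles = 0), "n_shuffles")
})

test_that("ablation at fraction zero reproduces the unablated link", {
  fx <- planted_fixture()
  sub <- fx$delay_seqs
  ab <- ablation_curve(sub, fx$frechet, fractions = c(0, 0.5), iters = 2,
                      seed = 21)
  rho0 <- link_correlation(fx$emb$cent$dist, fx$frechet)
  expect_equal(ab$mean_rho[1], rho0, tolerance = 1e-12)
  expect_equal(ab$sd_rho[1], 0)
  expect_lte(ab$mean_rho[2], ab$mean_rho[1])
  expect_error(ablation_curve(sub, fx$frechet, fractions = c(0.5, 1)),
               "fractions")
})
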