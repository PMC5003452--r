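# Projection, fuzzy c-means, validity indices, hotspot/boundary decoding,
# interpolation and the full ATM pipeline.

test_that("projection onto the probe-set axis returns the f2 column", {
  cv <- retention_curve(c(5, 10), c(900L, 800L), c(100L, 90L))
  expect_equal(project_curve(cv), c(100, 90))
  # idempotent projector for a random full-rank basis
  set.seed(4)
  B <- matrix(rnorm(6), nrow = 3)
  P <- projection_spec(B)$projector
  expect_equal(P %*% P, P, tolerance = 1e-10)
  expect_equal(P, t(P), tolerance = 1e-10)
  # orthonormal basis: P = B B'
  qr_b <- qr.Q(qr(B))
  expect_equal(projection_spec(qr_b)$projector, qr_b %*% t(qr_b),
               tolerance = 1e-10)
  expect_error(projection_spec(matrix(c(1, 1, 0, 2, 2, 0), nrow = 3)),
               "independent")
})

test_that("fcm recovers well-separated clusters crisply", {
  part <- fcm(c(0, 0.1, 10, 10.1), c = 2, seed = 1)
  expect_equal(sort(part$centroids), c(0.05, 10.05), tolerance = 1e-3)
  # descending centroid order: cluster 1 is the high side
  expect_gt(part$centroids[1], part$centroids[2])
  expect_true(all(part$memberships[1, 3:4] > 0.99))
  expect_true(all(part$memberships[2, 1:2] > 0.99))
  expect_true(part$converged)
})

test_that("fcm handles degenerate and coincident data", {
  part <- fcm(rep(5, 10), c = 2, seed = 2)
  expect_equal(part$objective, 0)
  expect_equal(part$centroids, c(5, 5), tolerance = 1e-6)
  expect_equal(colSums(part$memberships), rep(1, 10))
  # point coinciding with a centroid gets full membership there
  m <- xspecies:::fcm_memberships(c(0, 5), c(0, 10), q = 2)
  expect_equal(m[, 1], c(1, 0))
  expect_error(fcm(1:3, c = 3), "c < n")
  expect_error(fcm(1:10, c = 2, q = 1), "q must be > 1")
})

test_that("fcm objective is non-increasing and stationary at convergence", {
  set.seed(77)
  for (s in 1:20) {
    data <- c(rnorm(30, 0, 1), rnorm(30, 8, 1))
    part <- fcm(data, c = 2, seed = s, restarts = 2)
    expect_true(all(diff(part$objective_trace) <= 1e-8))
    # one extra alternating update must not move the centroids
    m <- xspecies:::fcm_memberships(data, part$centroids, part$q)
    mq <- m^part$q
    new_cent <- as.vector((mq %*% data) / rowSums(mq))
    expect_equal(new_cent, part$centroids, tolerance = 1e-4)
    expect_equal(colSums(part$memberships), rep(1, length(data)),
                 tolerance = 1e-9)
  }
})

test_that("validity indices score separation and fuzziness as defined", {
  data <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  part <- fcm(data, c = 2, seed = 3)
  expect_lt(fukuyama_sugeno(part, data), -100) # strongly negative

  # degenerate all-equal memberships score worse under FS
  degen <- part
  degen$memberships <- matrix(0.5, 2, length(data))
  degen$centroids <- rep(mean(data), 2)
  expect_lt(fukuyama_sugeno(part, data), fukuyama_sugeno(degen, data))

  # partition entropy: crisp -> 0, uniform -> ln 2, brute force otherwise
  crisp <- part
  crisp$memberships <- rbind(rep(c(0, 1), each = 50),
                             rep(c(1, 0), each = 50))
  expect_equal(partition_entropy(crisp), 0)
  expect_equal(partition_entropy(degen), log(2))
  set.seed(5)
  m <- matrix(runif(30), nrow = 3)
  m <- sweep(m, 2, colSums(m), "/")
  rand <- list(memberships = m, q = 2)
  expect_equal(partition_entropy(rand), -sum(m * log(m)) / ncol(m))
})

test_that("select_c finds planted cluster counts", {
  set.seed(12)
  two <- c(rnorm(60, 0, 0.5), rnorm(60, 10, 0.5))
  expect_equal(select_c(two, index = "fs", seed = 1), 2L)
  expect_equal(select_c(two, index = "pe", seed = 1), 2L)
  expect_equal(select_c(two, c_range = 2, seed = 1), 2L)
  three <- c(rnorm(40, 0, 0.3), rnorm(40, 10, 0.3), rnorm(40, 20, 0.3))
  expect_equal(select_c(three, index = "fs", seed = 1), 3L)
})

test_that("hotspot anchors span from plateau end to drop cluster", {
  # crisp two-cluster partition over a sorted 6-point curve
  cv <- retention_curve(0:5, c(60L, 60L, 60L, 10L, 10L, 10L),
                        c(6L, 6L, 6L, 1L, 1L, 1L))
  part <- list(memberships = rbind(c(1, 1, 1, 0, 0, 0),
                                   c(0, 0, 0, 1, 1, 1)),
               centroids = c(6, 1), c = 2L, q = 2)
  hs <- hotspot_interval(part, cv)
  expect_equal(hs$j_inf, 3L)  # last plateau point
  expect_equal(hs$j_sup, 4L)  # first drop point
  expect_equal(hs$interval, c(2, 3))
  # single-element clusters
  part2 <- list(memberships = rbind(c(1, 0, 0, 0, 0, 0),
                                    c(0, 0, 0, 0, 0, 1)),
               centroids = c(6, 1))
  expect_equal(hotspot_interval(part2, cv)$interval, c(0, 5))
  # non-monotone anchors error
  part3 <- list(memberships = rbind(c(0, 0, 1), c(1, 0, 0)),
                centroids = c(2, 1))
  cv3 <- retention_curve(0:2, c(3L, 2L, 1L), c(3L, 2L, 1L))
  expect_error(hotspot_interval(part3, cv3), "c or ")
})

test_that("fuzzy boundary extracts overlapping members and halves epsilon", {
  part <- list(memberships = rbind(c(.9, .6, .4, .1), c(.1, .4, .6, .9)))
  fb <- fuzzy_boundary(part, epsilon = 0.2)
  expect_equal(fb$boundary, c(2L, 3L))
  expect_equal(fb$l, 2L); expect_equal(fb$k, 3L)
  # crisp partition: empty at eps 0.6, retries downward then errors
  crisp <- list(memberships = rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_error(fuzzy_boundary(crisp, epsilon = 0.6), "empty fuzzy boundary")
  # halving succeeds when overlap exists at a smaller epsilon
  fb2 <- fuzzy_boundary(part, epsilon = 0.45)
  expect_equal(fb2$epsilon, 0.45 / 2)
  expect_equal(fb2$boundary, c(2L, 3L))
})

test_that("interpolation inverts the probe-set curve at the boundary mean", {
  cv <- retention_curve(c(300, 400), c(9000L, 8000L), c(96L, 94L))
  ip <- interpolate_xatm(cv, boundary = 1:2)
  expect_equal(ip$u_bar, 95)
  expect_equal(ip$x_atm, 350)
  # boundary mean at a knot
  cv2 <- retention_curve(c(0, 10, 20), c(90L, 60L, 30L), c(9L, 6L, 3L))
  ip2 <- interpolate_xatm(cv2, boundary = 1:3, values = c(9, 6, 3))
  expect_equal(ip2$x_atm, 10)
  # flat run resolves to its midpoint
  cv3 <- retention_curve(0:4, c(96L, 95L, 95L, 95L, 94L),
                         c(96L, 95L, 95L, 95L, 94L))
  ip3 <- interpolate_xatm(cv3, boundary = c(1L, 5L))
  expect_equal(ip3$u_bar, 95)
  expect_equal(ip3$x_atm, 2)
  # lagrange option agrees with linear on straight segments
  ipl <- interpolate_xatm(cv2, boundary = 1:3, values = c(9, 6, 3),
                          method = "lagrange")
  expect_equal(ipl$x_atm, 10, tolerance = 1e-9)
})

test_that("run_atm recovers a planted knee with nested intervals", {
  cv <- make_knee_curve(30, 100, n_sets = 100, pairs_per_set = 10,
                        thresholds = 0:100)
  res <- run_atm(cv, seed = 1)
  expect_gte(res$x_atm, 25)
  expect_lte(res$x_atm, 50)
  expect_true(res$x_atm >= res$target_interval[1] &&
              res$x_atm <= res$target_interval[2])
  expect_true(res$target_interval[1] >= res$tolerance_interval[1] &&
              res$target_interval[2] <= res$tolerance_interval[2])
  expect_false(res$low_confidence)
  # determinism
  res2 <- run_atm(cv, seed = 1)
  expect_identical(res[names(res) != "partition"],
                   res2[names(res2) != "partition"])
})

test_that("a plateau-free linear curve is flagged low-confidence", {
  lin <- retention_curve(0:100, as.integer(seq(1000, 0, length.out = 101)),
                         as.integer(seq(100, 0, length.out = 101)))
  res <- run_atm(lin, seed = 1)
  expect_true(res$low_confidence)
  expect_gt(res$x_atm, 10)      # somewhere mid-curve, not at an edge
  expect_lt(res$x_atm, 90)
})

test_that("boundary lies inside the hotspot index set", {
  for (s in 1:10) {
    cv <- make_knee_curve(20 + 3 * s, 90, n_sets = 100, thresholds = 0:100,
                          noise_sd = 1, seed = s)
    res <- run_atm(cv, seed = s)
    expect_true(all(seq(res$boundary_indices["l"],
                        res$boundary_indices["k"]) %in% res$hotspot_j))
  }
})

test_that("relative cut-off difference is the percentage formula", {
  expect_equal(cutoff_relative_difference(400, 391.34), 2.165)
  expect_equal(cutoff_relative_difference(100, 100), 0)
  expect_error(cutoff_relative_difference(0, 1), "positive")
})
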