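# Fold-changes, MA/D/FCD, DFC screen, POST tests, robust statistics,
# BH adjustment, filters, Euler partition and candidate strategy.

test_that("symmetric fold-change maps ratios onto the signed scale", {
  expect_equal(round(symmetric_fc(564 / 288), 2), 1.96)
  expect_equal(symmetric_fc(0.5), -2)
  expect_equal(symmetric_fc(1), 1)
  expect_error(symmetric_fc(0), "positive")
  expect_error(symmetric_fc(-2), "positive")
  q <- c(4, 0.25, 1.5)
  expect_equal(symmetric_fc(q), c(4, -4, 1.5))
  expect_true(all(abs(symmetric_fc(runif(100, 0.1, 10))) >= 1))
})

test_that("MA and D values respect the trait pairing", {
  expect_equal(ma_value(7, 7, 3, 3), 0)
  expect_equal(ma_value(4, 1, 4, 1), 2)
  # simultaneous swap negates
  expect_equal(ma_value(1, 4, 1, 4), -2)
  expect_error(ma_value(0, 1, 1, 1), "positive")

  expect_equal(d_value(5, 5, 9, 9), 0)
  expect_equal(d_value(100, 36, 100, 36), 64)
  expect_equal(d_value(36, 100, 36, 100), -64)

  expect_equal(fcd(64), 8)
  expect_equal(fcd(0), 0)
  expect_equal(fcd(-64), -8)
})

test_that("dfc_screen applies threshold, dual cut-offs and sign consistency", {
  pm <- probe_matrix(rbind(c(564, 288, 450, 290),   # fc1 = 1.96 < 2
                           c(600, 100, 450, 150),   # fc1 = 6, fc2 = 3
                           c(600, 100, 150, 450),   # sign conflict
                           c(600, 100, 90, 30)),    # b4 below th
                     sprintf("p%d", 1:4), c("B1", "B2", "B3", "B4"),
                     rep("s1", 4))
  flags <- dfc_screen(quad_design(pm), th = 93.04, eps1 = 2, eps2 = 1.5)
  expect_equal(unname(flags), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("trimmed mean and Winsorized variance match brute force", {
  expect_equal(trimmed_mean(1:10, 0.1), 5.5)
  expect_equal(trimmed_mean(sample(1:10), 0.1), 5.5)  # permutation invariant
  expect_equal(trimmed_mean(c(3, 1, 2), 0.05), 2)     # h = 0 -> plain mean
  expect_equal(winsorized_variance(rep(7, 8), 0.1), 0)
  expect_equal(winsorized_variance(1:10, 0.1),
               stats::var(c(2, 2:9, 9)))
  expect_error(trimmed_mean(1:4, 0.5), "gamma")

  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    g <- runif(1, 0.01, 0.45)
    x <- rnorm(n, sd = 10)
    h <- floor(g * n)
    if (2 * h >= n) next
    s <- sort(x)
    expect_equal(trimmed_mean(x, g), mean(s[(h + 1):(n - h)]))
    expect_equal(trimmed_mean(x, g), mean(x, trim = g))  # base-R oracle
    w <- c(rep(s[h + 1], h), s[(h + 1):(n - h)], rep(s[n - h], h))
    expect_equal(winsorized_variance(x, g), stats::var(w))
  }
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_equal(bh_adjust(c(0.5, NA, 0.01)),
               stats::p.adjust(c(0.5, NA, 0.01), "BH"))
})

test_that("Patel small-sample factor evaluates the printed formula", {
  expect_equal(patel_scale(11, 1), 1 + 16 * exp(-9))
  expect_equal(patel_scale(10, 0), 1)   # no trimming -> no scaling
})

test_that("post_between ranks an outlying MA probe lowest in its set", {
  # five probes; engineer MAs {0,0,0,0,~3}: b1 = b2 except the outlier
  b2 <- rep(100, 5); b3 <- rep(80, 5); b4 <- rep(80, 5)
  b1 <- c(100, 100, 100, 100, 800)
  pm <- probe_matrix(cbind(b1, b2, b3, b4), sprintf("p%d", 1:5),
                     c("B1", "B2", "B3", "B4"), rep("s1", 5))
  res <- post_between(quad_design(pm))
  expect_equal(which.min(res$p), 5L)
  # probe 5's leave-one-out sample has zero spread and a different MA:
  # degenerate case flagged with the smallest representable p
  expect_equal(res$p[5], .Machine$double.xmin)

  # all MAs equal -> all p = 1
  pm2 <- probe_matrix(cbind(rep(200, 4), rep(100, 4), rep(160, 4),
                            rep(80, 4)),
                      sprintf("p%d", 1:4), c("B1", "B2", "B3", "B4"),
                      rep("s1", 4))
  expect_equal(post_between(quad_design(pm2))$p, rep(1, 4))

  # sets smaller than 3 are skipped
  pm3 <- probe_matrix(matrix(runif(8, 50, 100), nrow = 2),
                      c("p1", "p2"), c("B1", "B2", "B3", "B4"),
                      rep("s1", 2))
  expect_true(all(is.na(post_between(quad_design(pm3))$p)))
})

test_that("post_between matches a brute-force leave-one-out computation", {
  set.seed(23)
  qd <- make_quad(n_sets = 20, pairs = 8, seed = 23)$design
  res <- post_between(qd)
  b <- unclass(qd)
  rho <- (log2(b[, 1] / b[, 2]) + log2(b[, 3] / b[, 4])) / 2
  sid <- set_ids(qd)
  for (i in sample(nrow(qd), 25)) {
    rest <- rho[setdiff(which(sid == sid[i]), i)]
    n_i <- length(rest)
    tt <- unname((rho[i] - mean(rest)) / (sd(rest) * sqrt(1 + 1 / n_i)))
    expect_equal(res$t[i], tt)
    expect_equal(res$df[i], n_i - 1)
    expect_equal(res$p[i], 2 * pt(-abs(tt), n_i - 1))
  }
})

test_that("post_within reduces to ordinary t at h = 0 and applies Patel scaling", {
  set.seed(29)
  qd <- make_quad(n_sets = 10, pairs = 11, seed = 29)$design
  b <- unclass(qd)
  delta <- b[, 1] - b[, 2]
  sid <- set_ids(qd)

  # gamma small enough that h = floor(gamma * 10) = 0
  res0 <- post_within(qd, "G1", gamma = 0.01, small_sample_scale = FALSE)
  i <- 7L
  rest <- delta[setdiff(which(sid == sid[i]), i)]
  tt <- unname((delta[i] - mean(rest)) / (sd(rest) / sqrt(length(rest))))
  expect_equal(res0$t[i], tt)
  expect_equal(res0$df[i], length(rest) - 1)

  # Patel scaling multiplies t by a(n, h), df unchanged
  r_on <- post_within(qd, "G1", gamma = 0.1, small_sample_scale = TRUE)
  r_off <- post_within(qd, "G1", gamma = 0.1, small_sample_scale = FALSE)
  expect_equal(r_on$t, r_off$t * patel_scale(10, 1))
  expect_equal(r_on$df, r_off$df)
  expect_equal(r_on$df[i], 10 - 2 * 1 - 1)

  # G2 uses the bulk columns
  res_g2 <- post_within(qd, "G2", gamma = 0.1)
  d2 <- b[, 3] - b[, 4]
  rest2 <- d2[setdiff(which(sid == sid[i]), i)]
  tm <- trimmed_mean(rest2, 0.1)
  sw <- sqrt(winsorized_variance(rest2, 0.1))
  tt2 <- unname(patel_scale(10, 1) * (d2[i] - tm) /
                  (sw / ((1 - 0.2) * sqrt(10))))
  expect_equal(res_g2$t[i], tt2)
})

test_that("a planted outlier D-value gets the set minimum p", {
  set.seed(41)
  base <- rnorm(11, 0, 5)
  b1 <- 500 + base; b1[4] <- b1[4] + 400     # outlier in G1 difference
  pm <- probe_matrix(cbind(b1, rep(500, 11), rep(400, 11), rep(400, 11)),
                     sprintf("p%d", 1:11), c("B1", "B2", "B3", "B4"),
                     rep("s1", 11))
  res <- post_within(quad_design(pm), "G1", gamma = 0.1)
  expect_equal(which.min(res$p), 4L)
})

test_that("volcano and twin-volcano filters honour every cut-off", {
  rec <- data.frame(
    padj_between = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01),
    ma = c(2, 0.5, 2, -2, 2, 2),
    fc1 = c(3, 3, 3, 3, 3, 3),
    fc2 = c(2, 2, 2, 2, 1.2, 2),
    b1 = c(500, 500, 500, 500, 500, 50), b2 = rep(500, 6),
    b3 = rep(500, 6), b4 = rep(500, 6),
    padj_g1 = c(0.01, 0.2, 0.2, 0.01, 0.2, 0.2),
    padj_g2 = c(0.2, 0.01, 0.2, 0.2, 0.2, 0.2),
    fcd_g1 = c(9, 1, 9, -9, 9, 9),
    fcd_g2 = c(1, 9, 9, 1, 9, 9))
  # hand evaluation: p, |ma| >= .75, |fc2| >= 1.5, th = 93.04
  expect_equal(volcano_filter(rec, 0.05, 0.75, fcf2_cut = 1.5, th = 93.04),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  # without th, record 6 passes; without fcf2, record 5 passes too
  expect_equal(volcano_filter(rec, 0.05, 0.75, fcf2_cut = 1.5),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(sum(volcano_filter(rec, 0.05, 0.75)), 4L)

  tv <- twin_volcano_filter(rec, 0.05, fcd_cut = 8)
  expect_equal(tv$flag, c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(tv$group[1:2], c("G1", "G2"))
  # anti-monotone: tightening cuts never adds flags
  tv2 <- twin_volcano_filter(rec, 0.05, fcd_cut = 8, fcp_cut = 4)
  expect_true(all(tv$flag[tv2$flag]))
  vp2 <- volcano_filter(rec, 0.01, 0.75, fcf2_cut = 1.5, th = 93.04)
  expect_true(all(volcano_filter(rec, 0.05, 0.75, fcf2_cut = 1.5,
                                 th = 93.04)[vp2]))
})

test_that("euler_partition matches the frozen 16-combination truth table", {
  combos <- expand.grid(vp4 = c(FALSE, TRUE), dfc2 = c(FALSE, TRUE),
                        tvp2 = c(FALSE, TRUE), tvp4 = c(FALSE, TRUE))
  valid <- !(combos$tvp4 & !combos$tvp2)
  expected <- with(combos[valid, ], ifelse(
    dfc2 & tvp4, "e", ifelse(
    dfc2, "d", ifelse(
    tvp4, "f", ifelse(
    vp4 & tvp2, "b", ifelse(
    vp4, "a", ifelse(tvp2, "c", "none")))))))
  got <- with(combos[valid, ], euler_partition(vp4, dfc2, tvp2, tvp4))
  expect_equal(got, expected)
  # spot checks: all four sets -> e; VP4 only -> a
  expect_equal(euler_partition(TRUE, TRUE, TRUE, TRUE), "e")
  expect_equal(euler_partition(TRUE, FALSE, FALSE, FALSE), "a")
  expect_error(euler_partition(FALSE, FALSE, FALSE, TRUE), "subset")
})

test_that("candidate strategy follows the region rules", {
  rec <- data.frame(
    fc1 = c(3, 1.96, 3, 3, 1.96, 1.2, 3),
    fcd = c(9, 9, 9, 8.2, 9, 9, 9),
    b1 = c(500, 564, 500, 500, 500, 500, 42),
    b2 = c(500, 288, 500, 500, 500, 500, 500),
    b3 = c(500, 450, 500, 500, 500, 500, 500),
    b4 = c(500, 290, 80, 500, 500, 500, 500))
  labels <- c("e", "b", "f", "e", "a", "c", "f")
  got <- candidate_strategy(rec, labels, th = 93.04, fcp_cut = 2,
                            fcd_cut = 8, fcp_near = 0.1)
  # 1: e with fcd well above cut -> candidate
  # 2: b with fc1 = 1.96 ~ cut 2 and strong hybridisation -> candidate
  # 3: f with b4 = 80, just under th -> candidate
  # 4: e with fcd barely above cut (8.2 < 8.5) -> dropped
  # 5: a with strong hybridisation and near-cut ratio -> candidate
  # 6: c -> never
  # 7: f with very poor hybridisation (42 vs 93.04) -> dropped
  expect_equal(got, c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("sfp_screen builds a coherent record table", {
  qd <- make_quad(n_sets = 40, pairs = 11, n_sfp = 4, seed = 13,
                  preprocess_it = TRUE)
  rec <- sfp_screen(qd$design, th = 40)
  expect_equal(nrow(rec), nrow(qd$design))
  # record invariants
  expect_true(all(abs(rec$fc1) >= 1))
  expect_equal(rec$fcd, sign(rec$d) * sqrt(abs(rec$d)))
  ok <- !is.na(rec$p_between)
  expect_true(all(rec$padj_between[ok] >= rec$p_between[ok] - 1e-12))
  # TVP4 subset of TVP2; DFC with th subset of DFC without
  expect_true(all(rec$tvp[rec$tvp4]))
  no_th <- dfc_screen(qd$design, th = -Inf)
  expect_true(all(no_th[rec$dfc]))
  # labelled probes are exactly the flagged ones
  flagged <- rec$vp4 | rec$dfc | rec$tvp | rec$tvp4
  expect_equal(rec$euler != "none", flagged)
  # planted SFPs dominate the DFC flags
  expect_true(all(qd$truth$probe_id %in% rec$probe_id[rec$dfc]))
})
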