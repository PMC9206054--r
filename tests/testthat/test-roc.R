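test_that("ROC points accumulate from the strictest bin with an origin anchor", {
  curve <- roc_points(bin_confidence(vo_counts("young", "control")))
  expect_equal(curve$fid_rate[1], 0)
  expect_equal(curve$cid_rate[1], 0)
  # strictest observed point: 5/1500 and 80/250
  expect_equal(curve$fid_rate[2], 5 / 1500)
  expect_equal(curve$cid_rate[2], 0.32)
  # rightmost point equals the overall rates
  n <- nrow(curve)
  expect_equal(curve$fid_rate[n], 0.056)
  expect_equal(curve$cid_rate[n], 0.604)
  expect_true(all(diff(curve$fid_rate) >= 0))
  expect_true(all(diff(curve$cid_rate) >= 0))
})

test_that("ROC coordinates are monotone and bounded on random tables", {
  set.seed(404)
  for (i in 1:20) {
    tp <- matrix(rpois(21, 6), 3, 7,
                 dimnames = list(c("suspect_id", "filler_id", "no_id"), 1:7))
    ta <- matrix(rpois(14, 6), 2, 7,
                 dimnames = list(c("filler_id", "no_id"), 1:7))
    tab <- lineup_table(tp, ta, k = 6)
    curve <- roc_points(bin_confidence(tab))
    expect_true(all(diff(curve$fid_rate) >= -1e-12))
    expect_true(all(diff(curve$cid_rate) >= -1e-12))
    expect_true(all(curve$fid_rate >= 0 & curve$fid_rate <= 1))
    expect_true(all(curve$cid_rate >= 0 & curve$cid_rate <= 1))
    expect_equal(sum(curve$weight), if (nrow(curve) > 1) 1 else 0)
  }

  # zero TA filler IDs pin every x at 0
  tab <- toy_table()
  ta0 <- tab$ta; ta0["filler_id", ] <- 0
  curve <- roc_points(bin_confidence(lineup_table(tab$tp, ta0, k = 6)))
  expect_true(all(curve$fid_rate == 0))

  # no IDs at all collapses to a flagged single-point curve
  tp0 <- tab$tp; tp0["suspect_id", ] <- 0; tp0["filler_id", ] <- 0
  tp0["no_id", ] <- 30
  deg <- roc_points(bin_confidence(lineup_table(tp0, ta0, k = 6)))
  expect_true(attr(deg, "degenerate"))
  expect_equal(nrow(deg), 1)
})

test_that("conservative cutoff takes the smaller rightmost false ID rate", {
  yc <- roc_points(bin_confidence(vo_counts("young", "control")))
  oc <- roc_points(bin_confidence(vo_counts("older", "control")))
  expect_equal(as.numeric(conservative_cutoff(yc, oc)), 0.056)
  expect_equal(max(oc$fid_rate), 91 / 1500)  # 0.060667
  expect_equal(as.numeric(conservative_cutoff(yc, yc)), 0.056)
})

test_that("pAUC integrates trapezoids with interpolation and extrapolation", {
  tri <- structure(data.frame(fid_rate = c(0, 0.1), cid_rate = c(0, 1),
                              weight = c(0, 1)),
                   class = c("roc_curve", "data.frame"))
  expect_equal(as.numeric(pauc(tri, 0.1)), 0.05)

  three <- structure(data.frame(fid_rate = c(0, 0.02, 0.06),
                                cid_rate = c(0, 0.5, 0.7),
                                weight = c(0, 0.5, 0.5)),
                     class = c("roc_curve", "data.frame"))
  # hand trapezoid with interpolation at the cutoff: y(0.04) = 0.6, so
  # 0.02 * (0 + 0.5)/2 + 0.02 * (0.5 + 0.6)/2
  expect_equal(as.numeric(pauc(three, 0.04)), 0.016)
  expect_equal(as.numeric(pauc(three, 0.04)),
               trapezoid_pauc(three$fid_rate, three$cid_rate, 0.04))

  # additivity of integration: area to 0.04 = area to 0.02 + oracle strip
  full <- as.numeric(pauc(three, 0.06))
  strip <- trapezoid_pauc(three$fid_rate, three$cid_rate, 0.04) -
    trapezoid_pauc(three$fid_rate, three$cid_rate, 0.02)
  expect_equal(as.numeric(pauc(three, 0.04)),
               as.numeric(pauc(three, 0.02)) + strip)

  # pAUC is monotone nondecreasing in the cutoff
  cuts <- seq(0.005, 0.08, by = 0.005)
  vals <- vapply(cuts, function(ct) as.numeric(pauc(three, ct)), numeric(1))
  expect_true(all(diff(vals) >= 0))

  # beyond the rightmost point the final segment is extended, flagged
  ext <- pauc(three, 0.08)
  expect_true(attr(ext, "extrapolated"))
  expect_equal(as.numeric(ext),
               full + 0.02 * (0.7 + 0.8) / 2)  # slope 5 continues to y=0.8
  expect_false(attr(pauc(three, 0.04), "extrapolated"))
  expect_error(pauc(three, 0), "positive")
})

test_that("pAUC matches the independent trapezoid oracle on the fixture", {
  for (g in c("young", "older")) {
    curve <- roc_points(bin_confidence(vo_counts(g, "control")))
    for (ct in c(0.02, 0.056, 0.06)) {
      expect_equal(as.numeric(pauc(curve, ct)),
                   trapezoid_pauc(curve$fid_rate, curve$cid_rate, ct),
                   tolerance = 1e-12)
    }
  }
})

test_that("pAUC is invariant to splitting a bin one side of which holds no IDs", {
  tab <- toy_table()
  tp <- tab$tp; ta <- tab$ta
  tp["suspect_id", 1] <- 0; ta["filler_id", 1] <- 0
  tab <- lineup_table(tp, ta, k = 6)
  base <- roc_points(bin_confidence(tab, list(1:3, 4L, 5L, 6:7)))
  # splitting {1,2,3} into {1},{2,3} adds only a repeated ROC point because
  # level 1 contributes no identifications
  split <- roc_points(bin_confidence(tab, list(1L, 2:3, 4L, 5L, 6:7)))
  ct <- max(base$fid_rate)
  expect_equal(as.numeric(pauc(split, ct)), as.numeric(pauc(base, ct)))
})

test_that("bootstrap pAUC is reproducible, degenerate-safe, and tightens with n", {
  tab <- vo_counts("young", "control")
  a <- bootstrap_pauc(tab, cutoff = 0.056, n_boot = 400, seed = 7)
  b <- bootstrap_pauc(tab, cutoff = 0.056, n_boot = 400, seed = 7)
  expect_identical(a, b)
  expect_equal(length(a), 400)

  # all mass in one category: identical replicates, SE 0, warning
  tp <- matrix(0, 3, 7, dimnames = list(c("suspect_id", "filler_id", "no_id"), 1:7))
  ta <- matrix(0, 2, 7, dimnames = list(c("filler_id", "no_id"), 1:7))
  tp["suspect_id", 7] <- 50; ta["filler_id", 7] <- 50
  deg <- lineup_table(tp, ta, k = 6)
  expect_warning(d <- bootstrap_pauc(deg, cutoff = 0.05, n_boot = 50, seed = 1),
                 "degenerate")
  expect_equal(sd(d), 0)

  # SE shrinks roughly as 1/sqrt(n) when all counts are scaled x4
  se1 <- sd(bootstrap_pauc(tab, cutoff = 0.056, n_boot = 2000, seed = 11))
  se4 <- sd(bootstrap_pauc(scale_table(tab, 4), cutoff = 0.056,
                           n_boot = 2000, seed = 12))
  expect_gt(se4 / se1, 0.35)
  expect_lt(se4 / se1, 0.65)

  # bootstrap mean approaches the point estimate as counts grow
  point <- as.numeric(pauc(roc_points(bin_confidence(tab)), 0.056))
  big <- bootstrap_pauc(scale_table(tab, 40), cutoff = 0.056,
                        n_boot = 2000, seed = 13)
  expect_lt(abs(mean(big) - point), 0.001)
})

test_that("pAUC Z-test of a table against itself is null", {
  tab <- vo_counts("young", "control")
  cmp <- pauc_z_test(tab, tab, n_boot = 300, seed = 5)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$pauc_1, cmp$pauc_2)
})
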