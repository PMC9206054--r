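test_that("CAC applies CID/(CID + FID/k) per confidence bin", {
  curve <- cac(vo_counts("young", "control"))
  # high-confidence bin: CID = 80, FID = 5
  expect_equal(curve$accuracy[curve$bin == "6-7"], 80 / (80 + 5 / 6))
  expect_equal(curve$n_cid[curve$bin == "6-7"], 80)
  # every bin matches the hand formula
  expect_equal(curve$accuracy,
               curve$n_cid / (curve$n_cid + curve$n_fid / 6))

  tab <- toy_table()
  ta0 <- tab$ta; ta0["filler_id", ] <- 0
  pure <- cac(lineup_table(tab$tp, ta0, k = 6))
  expect_true(all(pure$accuracy == 1))

  tp0 <- tab$tp; tp0["suspect_id", ] <- 0
  none <- cac(lineup_table(tp0, tab$ta, k = 6))
  expect_true(all(none$accuracy == 0))

  # a bin with no ID responses is undefined, not zero
  tpe <- tab$tp; tae <- tab$ta
  tpe["suspect_id", 1:3] <- 0; tae["filler_id", 1:3] <- 0
  expect_warning(und <- cac(lineup_table(tpe, tae, k = 6)), "undefined")
  expect_true(is.na(und$accuracy[1]))
})

test_that("CAC bins agree with the positive predictive value of ROC increments", {
  tab <- vo_counts("older", "control")
  scheme <- default_bins()
  curve <- cac(tab, scheme)
  roc <- roc_points(bin_confidence(tab, scheme))
  # ROC increments walk from the strictest bin; CAC rows run low -> high
  d_cid <- diff(roc$cid_rate) * 250          # CID counts, high conf first
  d_fid <- diff(roc$fid_rate) * 250 * 6      # FID counts
  ppv <- rev(d_cid / (d_cid + d_fid / 6))
  expect_equal(curve$accuracy, ppv)
})

test_that("RAC bins identifications by response speed", {
  # all TP suspect IDs fast, all TA filler IDs slow
  rec <- data.frame(
    participant_id = sprintf("p%d", 1:8),
    group = "young", condition = "control",
    lineup_type = rep(c("target_present", "target_absent"), each = 4),
    response = rep(c("suspect_id", "filler_id"), each = 4),
    confidence = 5L,
    rt = c(2, 3, 4, 5, 20, 25, 30, 40)
  )
  curve <- suppressWarnings(rac(rec))
  expect_equal(curve$accuracy[curve$bin == "<6s"], 1)
  expect_equal(curve$accuracy[curve$bin == ">18s"], 0)

  single <- rec[1, ]
  c1 <- suppressWarnings(rac(single))
  expect_equal(c1$accuracy[c1$bin == "<6s"], 1)
  expect_true(all(is.na(c1$accuracy[c1$bin != "<6s"])))

  # boundary values fall in the upper bin
  rec$rt <- c(6, 6, 6, 6, 12, 12, 18, 18)
  curve <- suppressWarnings(rac(rec))
  expect_equal(curve$n_cid[curve$bin == "6-12s"], 4)
  expect_equal(curve$n_fid[curve$bin == "12-18s"], 2)
  expect_equal(curve$n_fid[curve$bin == ">18s"], 2)

  # records without rt are excluded and counted
  rec$rt[1] <- NA
  curve <- suppressWarnings(rac(rec))
  expect_equal(attr(curve, "n_excluded"), 1)
})

test_that("simulated records with positive RT slope give a falling RAC", {
  rec <- simulate_trials(n_tp = 20000, n_ta = 20000, seed = 31)
  curve <- rac(rec)
  # nonincreasing across bins within sampling error
  expect_true(all(diff(curve$accuracy) <= 0.03))
  expect_gt(curve$accuracy[1], curve$accuracy[nrow(curve)])
})

test_that("bootstrap accuracy intervals are reproducible and scale with n", {
  tab <- vo_counts("young", "control")
  a <- bootstrap_cac(tab, n_boot = 500, seed = 9)
  b <- bootstrap_cac(tab, n_boot = 500, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$ci_low <= a$accuracy + 1e-12))
  expect_true(all(a$ci_high >= a$accuracy - 1e-12))

  # degenerate data -> zero-width interval
  tp <- matrix(0, 3, 7, dimnames = list(c("suspect_id", "filler_id", "no_id"), 1:7))
  ta <- matrix(0, 2, 7, dimnames = list(c("filler_id", "no_id"), 1:7))
  tp["suspect_id", 7] <- 40; ta["no_id", 7] <- 40
  deg <- lineup_table(tp, ta, k = 6)
  dc <- suppressWarnings(bootstrap_cac(deg, confidence_bins(list(1:7)),
                                       n_boot = 100, seed = 2))
  expect_equal(dc$ci_low, dc$ci_high)

  # interval width shrinks when counts scale x4
  w1 <- a$ci_high - a$ci_low
  a4 <- bootstrap_cac(scale_table(tab, 4), n_boot = 500, seed = 9)
  w4 <- a4$ci_high - a4$ci_low
  expect_true(all(w4 < w1))

  # RAC bootstrap: deterministic given seed, CIs bracket the point estimate
  rec <- simulate_trials(n_tp = 800, n_ta = 800, seed = 17)
  r1 <- bootstrap_rac(rec, n_boot = 300, seed = 4)
  r2 <- bootstrap_rac(rec, n_boot = 300, seed = 4)
  expect_identical(r1, r2)
  ok <- !is.na(r1$accuracy)
  expect_true(all(r1$ci_low[ok] <= r1$accuracy[ok] + 1e-12))
  expect_true(all(r1$ci_high[ok] >= r1$accuracy[ok] - 1e-12))
})

test_that("sparse bins merge with their neighbours until stable", {
  counts <- c(50, 40, 3, 2)
  res <- rebin_on_sparsity(counts, min_count = 10)
  # the two sparse rightmost bins end up pooled, and every merged bin
  # reaches the threshold
  joint <- vapply(res$groups, function(g) all(c(3, 4) %in% g), logical(1))
  expect_true(any(joint))
  expect_true(all(vapply(res$groups, function(g) sum(counts[g]),
                         numeric(1)) >= 10))

  same <- rebin_on_sparsity(c(50, 40, 30, 20), min_count = 10)
  expect_equal(same$groups, as.list(1:4))
  expect_equal(length(same$log), 0)

  expect_warning(one <- rebin_on_sparsity(c(1, 1, 1, 1), min_count = 10),
                 "single bin")
  expect_equal(one$groups, list(1:4))

  # merged bins always reach the threshold when the total allows it
  res2 <- rebin_on_sparsity(c(4, 3, 9, 40, 2), min_count = 10)
  totals <- vapply(res2$groups, function(g) sum(c(4, 3, 9, 40, 2)[g]),
                   numeric(1))
  expect_true(all(totals >= 10))
})

test_that("error-bar overlap predicate reads intervals off the curves", {
  tab <- vo_counts("young", "control")
  curve <- bootstrap_cac(tab, n_boot = 2000, seed = 12)
  # the published pattern: high-confidence accuracy reliably above low
  expect_false(bars_overlap(curve, "1-3", curve, "6-7"))
  expect_true(bars_overlap(curve, "1-3", curve, "1-3"))
  expect_error(bars_overlap(cac(tab), "1-3", cac(tab), "6-7"), "bootstrap")
})
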