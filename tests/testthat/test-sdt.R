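test_that("category probabilities obey closed forms and symmetry", {
  # TA any-ID above a single criterion: 1 - Phi(c)^k
  p <- predict_probs(sdt_params(0, 0, k = 6))
  expect_equal(unname(p$ta["filler_1"]), 1 - 0.5^6, tolerance = 1e-7)
  expect_equal(unname(p$ta["no_id"]), 0.5^6, tolerance = 1e-7)

  # with mu_t = 0 the target is exchangeable with the lures:
  # TP suspect-ID = (1/k) * TP any-ID
  any_id <- unname(p$tp["suspect_1"] + p$tp["filler_1"])
  expect_equal(unname(p$tp["suspect_1"]), any_id / 6, tolerance = 1e-7)

  # probabilities conserve within each lineup type across a parameter grid
  for (mu in c(0, 1, 2)) for (k in c(2, 6)) {
    pr <- predict_probs(sdt_params(mu, c(-1, 0, 1, 2), k = k))
    expect_equal(sum(pr$tp), 1, tolerance = 1e-7)
    expect_equal(sum(pr$ta), 1, tolerance = 1e-7)
    expect_true(all(pr$tp >= 0) && all(pr$ta >= 0))
  }

  expect_error(sdt_params(1, c(1, 1, 2)), "strictly increasing")
})

test_that("quadrature matches the Monte-Carlo oracle at a hard point", {
  p <- predict_probs(sdt_params(2, 1, k = 6))
  mc <- mc_category_probs(2, 1, 6, n = 2e5, seed = 55)
  expect_lt(abs(p$tp[["suspect_1"]] - mc$tp_suspect), 3 * mc$se["tp_suspect"])
  expect_lt(abs(p$tp[["filler_1"]] - mc$tp_filler), 3 * mc$se["tp_filler"])
  expect_lt(abs(sum(p$ta) - p$ta[["no_id"]] - mc$ta_id), 3 * mc$se["ta_id"])
})

test_that("the multinomial likelihood peaks at probability-proportional counts", {
  params <- sdt_params(1.5, c(1, 1.6, 2.2, 2.8), k = 6)
  pr <- predict_probs(params)
  n <- 5000
  tp <- rbind(suspect_id = c(pr$tp[paste0("suspect_", 1:4)]),
              filler_id = c(pr$tp[paste0("filler_", 1:4)]),
              no_id = c(pr$tp[["no_id"]], 0, 0, 0)) * n
  ta <- rbind(filler_id = c(pr$ta[paste0("filler_", 1:4)]),
              no_id = c(pr$ta[["no_id"]], 0, 0, 0)) * n
  tab <- lineup_table(tp, ta, k = 6, bins = list(1:3, 4L, 5L, 6:7))
  ll0 <- sdt_loglik(params, tab)
  for (d_mu in c(-0.3, -0.05, 0.05, 0.3)) {
    perturbed <- sdt_params(1.5 + d_mu, params$criteria, k = 6)
    expect_lt(sdt_loglik(perturbed, tab), ll0)
  }
  for (d_c in c(-0.1, 0.1)) {
    perturbed <- sdt_params(1.5, params$criteria + d_c, k = 6)
    expect_lt(sdt_loglik(perturbed, tab), ll0)
  }

  # empty table: zero log-likelihood
  empty <- lineup_table(tp * 0, ta * 0, k = 6, bins = list(1:3, 4L, 5L, 6:7))
  expect_equal(sdt_loglik(params, empty), 0)

  # zero predicted probability with observed counts guards to -Inf
  narrow <- sdt_params(1.5, c(1, 1.6, 2.2, 50), k = 6)
  tab2 <- tab
  expect_equal(as.numeric(sdt_loglik(narrow, tab2)), -Inf)
})

test_that("the likelihood falls as mu_t leaves the generating value", {
  rec <- simulate_trials(default_sim_params(mu_t = 1.5), n_tp = 8000,
                         n_ta = 8000, seed = 61)
  tab <- bin_confidence(tabulate_trials(rec))
  crit <- default_sim_params(mu_t = 1.5)$criteria[c(1, 4, 5, 6)]
  ll_at <- function(mu) sdt_loglik(sdt_params(mu, crit, k = 6), tab)
  expect_gt(ll_at(1.5), ll_at(1.0))
  expect_gt(ll_at(1.5), ll_at(2.0))
})

test_that("fit-then-predict reproduces the observed correct ID rate", {
  tab <- bin_confidence(vo_counts("young", "control"))
  fit <- fit_sdt(tab)
  expect_true(fit$converged)
  expect_equal(fit$params$sigma_t, 1)  # equal variance pins sigma_t
  pr <- predict_probs(fit$params)
  pred_cid <- sum(pr$tp[paste0("suspect_", 1:4)])
  expect_lt(abs(pred_cid - 0.604), 2 * sqrt(0.604 * 0.396 / 250))
})

test_that("predict -> fit -> predict is idempotent on noiseless counts", {
  gen <- sdt_params(1.3, c(0.9, 1.5, 2.0, 2.6), k = 6)
  pr <- predict_probs(gen)
  n <- 100000
  tp <- rbind(suspect_id = c(pr$tp[paste0("suspect_", 1:4)]),
              filler_id = c(pr$tp[paste0("filler_", 1:4)]),
              no_id = c(pr$tp[["no_id"]], 0, 0, 0)) * n
  ta <- rbind(filler_id = c(pr$ta[paste0("filler_", 1:4)]),
              no_id = c(pr$ta[["no_id"]], 0, 0, 0)) * n
  tab <- lineup_table(tp, ta, k = 6, bins = list(1:3, 4L, 5L, 6:7))
  fit <- fit_sdt(tab)
  expect_lt(abs(fit$params$mu_t - 1.3), 0.02)
  expect_lt(max(abs(fit$params$criteria - gen$criteria)), 0.02)
})

test_that("d-prime follows the equal-variance definition and the age ordering", {
  expect_equal(dprime(sdt_params(0, 0)), 0)
  expect_equal(dprime(sdt_params(2, c(0, 1))), 2)
  expect_error(dprime(sdt_params(2, 0, sigma_t = 1.4, equal_variance = FALSE)),
               "d_a")

  young <- fit_sdt(bin_confidence(vo_counts("young", "control")))
  older <- fit_sdt(bin_confidence(vo_counts("older", "control")))
  expect_gt(dprime(young$params), dprime(older$params))
})

test_that("the model ROC respects chance and discriminability orderings", {
  chance <- predicted_roc(sdt_params(0, 0, k = 6), n_grid = 41)
  # exchangeability: TP suspect-ID rate equals the TA per-member ID rate
  expect_equal(chance$cid_rate, chance$fid_rate, tolerance = 1e-6)

  lo <- predicted_roc(sdt_params(0.8, 0, k = 6), n_grid = 41)
  hi <- predicted_roc(sdt_params(1.8, 0, k = 6), n_grid = 41)
  # compare at matched false-ID rates via interpolation
  grid <- seq(0.01, 0.12, by = 0.01)
  y_lo <- approx(lo$fid_rate, lo$cid_rate, grid)$y
  y_hi <- approx(hi$fid_rate, hi$cid_rate, grid)$y
  expect_true(all(y_hi >= y_lo - 1e-9))

  # fitted model curve tracks the empirical control-cell points
  tab <- bin_confidence(vo_counts("young", "control"))
  fit <- fit_sdt(tab)
  emp <- roc_points(tab)
  mod <- predicted_roc(fit$params, n_grid = 201)
  y_mod <- approx(mod$fid_rate, mod$cid_rate, emp$fid_rate[-1])$y
  expect_lt(max(abs(y_mod - emp$cid_rate[-1])), 0.1)
})
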