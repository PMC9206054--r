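#' Default generative parameters emulating the study conditions
#'
#' A seven-criterion equal-variance model whose overall identification rates
#' sit in the range the fixture shows for untreated (control) witnesses:
#' roughly 60\% correct IDs on target-present lineups and a third of
#' target-absent lineups producing a filler ID, with confidence spread over
#' the full 7-point scale.
#'
#' @param mu_t target mean memory strength.
#' @param c1 lowest (identification) criterion.
#' @param step spacing between successive confidence criteria.
#' @param k lineup size.
#' @return an \code{\link{sdt_params}} with 7 criteria.
#' @export
default_sim_params <- function(mu_t = 2, c1 = 1.5, step = 0.3, k = 6) {
  sdt_params(mu_t, c1 + step * (0:6), k = k)
}

#' Simulate trial-level lineup records from the SDT model
#'
#' For each target-present lineup, one target strength and k-1 lure strengths
#' are drawn; for each target-absent lineup, k lure strengths. The
#' independent-observations max rule is applied: the strongest member is
#' identified iff its strength exceeds the lowest criterion, with confidence
#' given by the highest criterion exceeded (mapped onto the 1..7 scale when 7
#' criteria are supplied). No-ID confidence comes from rejection criteria
#' below c_1: the further the maximum falls below c_1, the more confident
#' the rejection. Response times follow a lognormal model in which stronger
#' evidence margins produce faster decisions:
#' \code{rt = exp(log(base) - slope * |max - c_1| + noise)}.
#'
#' @param params an \code{\link{sdt_params}} (at most 7 criteria).
#' @param n_tp,n_ta numbers of target-present / target-absent lineups
#'   (250 each per cell in the study design).
#' @param seed RNG seed.
#' @param rt_base median RT in seconds at zero evidence margin.
#' @param rt_slope seconds-per-unit-margin decay rate (log scale); positive
#'   values make stronger evidence faster.
#' @param rt_noise_sd lognormal noise SD.
#' @param rejection_criteria increasing thresholds below c_1 mapping no-ID
#'   maxima to rejection confidence (deeper below c_1 = higher confidence).
#'   Defaults to 6 equally spaced thresholds 0.4 apart below c_1.
#' @param group,condition labels attached to the records.
#' @return data frame of trial records (see \code{\link{load_trials}}).
#' @export
simulate_trials <- function(params = default_sim_params(), n_tp = 250,
                            n_ta = 250, seed = NULL,
                            rt_base = 10, rt_slope = 0.7, rt_noise_sd = 0.4,
                            rejection_criteria = NULL,
                            group = "young", condition = "control") {
  stopifnot(inherits(params, "sdt_params"), n_tp >= 0, n_ta >= 0,
            rt_base > 0, rt_noise_sd >= 0)
  m <- length(params$criteria)
  if (m > 7) stop("at most 7 criteria map onto the 1..7 confidence scale")
  c1 <- params$criteria[1]
  if (is.null(rejection_criteria))
    rejection_criteria <- c1 - rev(seq_len(7 - 1)) * 0.4
  stopifnot(all(diff(rejection_criteria) > 0),
            all(rejection_criteria < c1))
  local_seed(seed)
  k <- params$k
  empty <- data.frame(participant_id = character(), group = character(),
                      condition = character(), lineup_type = character(),
                      response = character(), confidence = integer(),
                      rt = numeric(), stringsAsFactors = FALSE)
  if (n_tp + n_ta == 0) return(empty)

  one_type <- function(n, target_present) {
    if (n == 0) return(NULL)
    lure_cols <- if (target_present) k - 1 else k
    lures <- matrix(stats::rnorm(n * lure_cols), n, lure_cols)
    lure_max <- do.call(pmax, lapply(seq_len(lure_cols), function(j) lures[, j]))
    if (target_present) {
      target <- stats::rnorm(n, params$mu_t, params$sigma_t)
      strength <- pmax(target, lure_max)
      target_won <- target >= lure_max
    } else {
      strength <- lure_max
      target_won <- rep(FALSE, n)
    }
    identified <- strength > c1
    response <- ifelse(!identified, "no_id",
                       ifelse(target_won & target_present,
                              "suspect_id", "filler_id"))
    conf <- integer(n)
    conf[identified] <- findInterval(strength[identified], params$criteria)
    mr <- length(rejection_criteria)
    conf[!identified] <- mr + 1L -
      findInterval(strength[!identified], rejection_criteria)
    margin <- abs(strength - c1)
    rt <- exp(log(rt_base) - rt_slope * margin +
                stats::rnorm(n, 0, rt_noise_sd))
    data.frame(
      participant_id = NA_character_, group = group, condition = condition,
      lineup_type = if (target_present) "target_present" else "target_absent",
      response = response, confidence = as.integer(conf), rt = rt,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one_type(n_tp, TRUE), one_type(n_ta, FALSE))
  out$participant_id <- sprintf("s%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  validate_trials(out)
}

#' Simulation-based power analysis for the pAUC Z-test
#'
#' Emulates the planning analysis: for each per-cell sample size, repeatedly
#' simulate the two conditions from their generating SDT parameters, run the
#' full empirical pipeline (tabulation, confidence binning, conservative
#' cutoff, pAUC, paired bootstrap SE, Z, two-sided p), and report the
#' rejection rate at the stated alpha. With identical generating parameters
#' this measures type-I calibration; with separated parameters, power.
#'
#' @param params_a,params_b generating \code{\link{sdt_params}} for the two
#'   conditions.
#' @param n_grid per-cell lineup counts (each used for both TP and TA).
#' @param scheme confidence binning scheme applied before the ROC.
#' @param n_boot bootstrap replicates per test (2000 in the planning
#'   analysis).
#' @param n_sim simulation replicates per sample size.
#' @param alpha significance level.
#' @param seed RNG seed; every replicate derives an independent child seed.
#' @return data frame of class \code{power_result}: per n, the rejection
#'   rate, number of usable replicates, skipped (degenerate) replicates, and
#'   mean |Z|.
#' @export
power_analysis <- function(params_a, params_b, n_grid, scheme = default_bins(),
                           n_boot = 2000, n_sim = 200, alpha = 0.05,
                           seed = 1) {
  stopifnot(length(n_grid) >= 1, n_sim >= 1)
  scheme <- confidence_bins(scheme)
  rows <- lapply(seq_along(n_grid), function(gi) {
    n <- n_grid[gi]
    reject <- logical(0); zs <- numeric(0); skipped <- 0L
    for (s in seq_len(n_sim)) {
      sd0 <- child_seed(seed, (gi - 1L) * n_sim + s - 1L)
      rec_a <- simulate_trials(params_a, n, n, seed = sd0)
      rec_b <- simulate_trials(params_b, n, n, seed = child_seed(sd0, 0))
      tab_a <- tabulate_trials(rec_a, k = params_a$k)
      tab_b <- tabulate_trials(rec_b, k = params_b$k)
      if (sum(ta_filler_counts(tab_a)) == 0 ||
          sum(ta_filler_counts(tab_b)) == 0 ||
          (sum(tp_suspect_counts(tab_a)) == 0 &&
           sum(tp_suspect_counts(tab_b)) == 0)) {
        skipped <- skipped + 1L
        next
      }
      cmp <- pauc_z_test(tab_a, tab_b, scheme, n_boot = n_boot,
                         seed = child_seed(sd0, 1))
      reject <- c(reject, is.finite(cmp$z) && cmp$p < alpha)
      zs <- c(zs, abs(cmp$z))
    }
    data.frame(n = n, rejection_rate = mean(reject),
               n_used = length(reject), n_skipped = skipped,
               mean_abs_z = mean(zs[is.finite(zs)]))
  })
  structure(do.call(rbind, rows), class = c("power_result", "data.frame"),
            alpha = alpha, n_boot = n_boot, seed = seed)
}
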