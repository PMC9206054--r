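#' Signal-detection parameters for a simultaneous lineup
#'
#' Equal-variance independent-observations model: each of the k lineup
#' members contributes an independent memory-strength draw — the target from
#' N(mu_t, sigma_t), each lure/filler from N(mu_l, sigma_l) with mu_l = 0 and
#' sigma_l = 1 fixed as the measurement scale. The witness identifies the
#' member with the maximum strength iff that maximum exceeds the lowest
#' criterion c_1; the confidence band is set by the highest criterion
#' exceeded.
#'
#' @param mu_t target mean memory strength.
#' @param criteria strictly increasing decision criteria c_1 < ... < c_m.
#' @param sigma_t target standard deviation (1 under equal variance).
#' @param k lineup size.
#' @param equal_variance if \code{TRUE}, enforce \code{sigma_t = 1}.
#' @return list of class \code{sdt_params}.
#' @export
sdt_params <- function(mu_t, criteria, sigma_t = 1, k = 6,
                       equal_variance = TRUE) {
  criteria <- as.numeric(criteria)
  if (length(criteria) < 1 || is.unsorted(criteria, strictly = TRUE))
    stop("criteria must be strictly increasing")
  stopifnot(sigma_t > 0, k >= 2)
  if (equal_variance && sigma_t != 1)
    stop("equal-variance model requires sigma_t = 1")
  structure(list(mu_t = mu_t, sigma_t = sigma_t, mu_l = 0, sigma_l = 1,
                 criteria = criteria, k = k,
                 equal_variance = equal_variance),
            class = "sdt_params")
}

#' @export
print.sdt_params <- function(x, ...) {
  cat(sprintf("SDT lineup model (k = %d): mu_t = %.4f, sigma_t = %.4f\n",
              x$k, x$mu_t, x$sigma_t))
  cat("criteria:", paste(sprintf("%.4f", x$criteria), collapse = ", "), "\n")
  invisible(x)
}

# Integration control: integrands are effectively zero beyond ~10 SD.
sdt_upper <- function(params) max(10, params$mu_t + 10 * params$sigma_t)
SDT_TOL <- 1e-8

# P(target is the maximum and exceeds c) on a target-present lineup.
p_tp_suspect_exceed <- function(params, c) {
  if (c >= sdt_upper(params)) return(0)
  f <- function(x) stats::dnorm(x, params$mu_t, params$sigma_t) *
    stats::pnorm(x)^(params$k - 1)
  stats::integrate(f, lower = c, upper = sdt_upper(params),
                   abs.tol = SDT_TOL, rel.tol = SDT_TOL)$value
}

# P(some filler is the maximum and exceeds c) on a target-present lineup.
p_tp_filler_exceed <- function(params, c) {
  if (params$k == 2) {
    f <- function(x) stats::dnorm(x) *
      stats::pnorm(x, params$mu_t, params$sigma_t)
  } else {
    f <- function(x) stats::dnorm(x) * stats::pnorm(x)^(params$k - 2) *
      stats::pnorm(x, params$mu_t, params$sigma_t)
  }
  if (c >= sdt_upper(params)) return(0)
  (params$k - 1) * stats::integrate(f, lower = c, upper = sdt_upper(params),
                                    abs.tol = SDT_TOL, rel.tol = SDT_TOL)$value
}

# P(any member exceeds c) on a target-absent lineup (closed form).
p_ta_id_exceed <- function(params, c) 1 - stats::pnorm(c)^params$k

#' Model-implied response-category probabilities
#'
#' For each lineup type, the probability of a suspect ID, filler ID (TP) or
#' filler ID (TA) in each confidence band, plus the no-ID probability. Band j
#' collects maxima falling between criteria c_j and c_{j+1} (the last band is
#' open above). Probabilities within each lineup type sum to 1.
#'
#' @param params an \code{\link{sdt_params}}.
#' @return list of class \code{sdt_probs} with elements \code{tp} (named
#'   vector: \code{suspect_b}, \code{filler_b} per band b, \code{no_id}) and
#'   \code{ta} (\code{filler_b} per band, \code{no_id}).
#' @export
predict_probs <- function(params) {
  stopifnot(inherits(params, "sdt_params"))
  cr <- params$criteria
  m <- length(cr)
  sus_ex <- vapply(cr, function(c) p_tp_suspect_exceed(params, c), numeric(1))
  fil_ex <- vapply(cr, function(c) p_tp_filler_exceed(params, c), numeric(1))
  ta_ex <- vapply(cr, function(c) p_ta_id_exceed(params, c), numeric(1))
  band <- function(ex) c(ex[-length(ex)] - ex[-1], ex[length(ex)]) |>
    pmax(0)  # guard tiny negative quadrature noise
  tp <- c(band(sus_ex), band(fil_ex))
  names(tp) <- c(paste0("suspect_", seq_len(m)), paste0("filler_", seq_len(m)))
  tp <- c(tp, no_id = max(0, 1 - sus_ex[1] - fil_ex[1]))
  ta <- band(ta_ex)
  names(ta) <- paste0("filler_", seq_len(m))
  ta <- c(ta, no_id = max(0, 1 - ta_ex[1]))
  structure(list(tp = tp, ta = ta), class = "sdt_probs")
}

#' Multinomial log-likelihood of a binned table under the SDT model
#'
#' TP and TA blocks are independent multinomials over the model's category
#' probabilities. The number of criteria must equal the number of confidence
#' bins. No-ID responses are collapsed across confidence (rejection
#' confidence is not modelled: the ROC analyses the model supports use only
#' identification responses).
#'
#' @param params an \code{\link{sdt_params}} with as many criteria as the
#'   table has bins.
#' @param table a binned \code{\link{lineup_table}}.
#' @return the log-likelihood (scalar); \code{-Inf} (with a message
#'   attribute) when a category with observed counts has zero predicted
#'   probability.
#' @export
sdt_loglik <- function(params, table) {
  stopifnot(inherits(params, "sdt_params"), inherits(table, "lineup_table"))
  m <- length(params$criteria)
  if (ncol(table$tp) != m)
    stop("number of criteria must match the number of confidence bins")
  pr <- predict_probs(params)
  obs_tp <- c(table$tp["suspect_id", ], table$tp["filler_id", ],
              no_id = sum(table$tp["no_id", ]))
  obs_ta <- c(table$ta["filler_id", ], no_id = sum(table$ta["no_id", ]))
  ll_block <- function(obs, p) {
    use <- obs > 0
    if (any(use & p <= 0)) {
      out <- -Inf
      attr(out, "message") <- "zero predicted probability with nonzero count"
      return(out)
    }
    sum(obs[use] * log(p[use]))
  }
  a <- ll_block(obs_tp, unname(pr$tp))
  b <- ll_block(obs_ta, unname(pr$ta))
  out <- a + b
  msg <- attr(a, "message") %||% attr(b, "message")
  if (!is.null(msg)) attr(out, "message") <- msg
  out
}

# Initial criteria from the empirical cumulative TA ID rates via the
# inverse-normal transform of the max rule: P(any TA ID > c) = 1 - Phi(c)^k.
init_criteria <- function(table) {
  fid <- rev(cumsum(rev(ta_filler_counts(table)))) / table$n_ta
  fid <- pmin(pmax(fid, 1 / (2 * table$n_ta)), 1 - 1 / (2 * table$n_ta))
  cr <- stats::qnorm((1 - fid)^(1 / table$k))
  # enforce strict ordering against ties in sparse bins
  for (j in seq_along(cr)[-1])
    if (cr[j] <= cr[j - 1]) cr[j] <- cr[j - 1] + 1e-3
  cr
}

#' Fit the independent-observations SDT model by maximum likelihood
#'
#' Maximises the multinomial likelihood over mu_t and the criteria
#' (sigma_t free only when \code{equal_variance = FALSE}). Criteria are
#' optimised on an unconstrained scale (first criterion plus log-increments)
#' to preserve strict ordering. The optimiser restarts from jittered
#' initialisations to guard against local optima.
#'
#' @param table a binned \code{\link{lineup_table}}.
#' @param equal_variance fix \code{sigma_t = 1} (the default model).
#' @param objective \code{"ml"} (multinomial maximum likelihood) or
#'   \code{"chisq"} (minimum Pearson chi-square, for sensitivity checks).
#' @param n_restarts jittered restarts after the data-driven initialisation.
#' @param seed RNG seed for the jitter.
#' @return list of class \code{sdt_fit}: \code{params}, \code{loglik},
#'   \code{converged}, \code{gof} (Pearson chi-square against fitted
#'   expected counts, with df), \code{objective}.
#' @export
fit_sdt <- function(table, equal_variance = TRUE,
                    objective = c("ml", "chisq"), n_restarts = 3, seed = 10) {
  stopifnot(inherits(table, "lineup_table"))
  objective <- match.arg(objective)
  m <- ncol(table$tp)
  obs_tp <- c(table$tp["suspect_id", ], table$tp["filler_id", ],
              sum(table$tp["no_id", ]))
  obs_ta <- c(table$ta["filler_id", ], sum(table$ta["no_id", ]))
  if (sum(c(obs_tp, obs_ta) > 0) < m + 1)
    stop("too few informative cells to fit ", m + 1, " parameters")

  unpack <- function(theta) {
    mu <- theta[1]
    sig <- if (equal_variance) 1 else exp(theta[2])
    off <- if (equal_variance) 1 else 2
    cr <- cumsum(c(theta[off + 1], exp(theta[off + 1 + seq_len(m - 1)])))
    sdt_params(mu, cr, sigma_t = sig, k = table$k,
               equal_variance = equal_variance)
  }
  neg_obj <- function(theta) {
    p <- try(unpack(theta), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    pr <- predict_probs(p)
    if (objective == "ml") {
      ll <- sdt_loglik(p, table)
      if (!is.finite(ll)) return(1e10)
      -ll
    } else {
      exp_tp <- table$n_tp * unname(pr$tp)
      exp_ta <- table$n_ta * unname(pr$ta)
      keep <- c(exp_tp, exp_ta) > 1e-10
      sum(((c(obs_tp, obs_ta) - c(exp_tp, exp_ta))^2 /
             pmax(c(exp_tp, exp_ta), 1e-10))[keep])
    }
  }

  cr0 <- init_criteria(table)
  cid_rate <- sum(tp_suspect_counts(table)) / max(table$n_tp, 1)
  # crude but serviceable start: the target must beat c_1 and the lure max
  mu0 <- cr0[1] + stats::qnorm(min(max(cid_rate, 0.02), 0.98)) + 0.5
  theta0 <- c(mu0,
              if (!equal_variance) 0,
              cr0[1], log(pmax(diff(cr0), 1e-3)))
  local_seed(seed)
  starts <- c(list(theta0), lapply(seq_len(n_restarts), function(i)
    theta0 + stats::rnorm(length(theta0), 0, 0.25)))
  best <- NULL
  for (th in starts) {
    res <- try(stats::optim(th, neg_obj, method = "Nelder-Mead",
                            control = list(maxit = 5000, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimisation failed from every start")
  params <- unpack(best$par)
  pr <- predict_probs(params)
  exp_all <- c(table$n_tp * unname(pr$tp), table$n_ta * unname(pr$ta))
  obs_all <- c(obs_tp, obs_ta)
  keep <- exp_all > 1e-10
  gof_stat <- sum((obs_all[keep] - exp_all[keep])^2 / exp_all[keep])
  n_par <- length(best$par)
  gof_df <- sum(keep) - n_par - 2  # two multinomial constraints
  structure(list(
    params = params,
    loglik = if (objective == "ml") -best$value else sdt_loglik(params, table),
    converged = best$convergence == 0,
    objective = objective,
    gof = list(statistic = gof_stat, df = gof_df,
               p = if (gof_df > 0)
                 stats::pchisq(gof_stat, gof_df, lower.tail = FALSE)
               else NA_real_)
  ), class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("loglik = %.3f (%s fit), converged: %s\n",
              x$loglik, x$objective, x$converged))
  cat(sprintf("goodness of fit: chi-square = %.3f, df = %d\n",
              x$gof$statistic, x$gof$df))
  invisible(x)
}

#' d-prime from equal-variance SDT parameters
#'
#' \code{d' = (mu_t - mu_l) / sigma_l}. Defined only for the equal-variance
#' model; unequal-variance fits require the d_a family instead (not
#' implemented here).
#'
#' @param params an \code{\link{sdt_params}}.
#' @return d-prime (scalar).
#' @export
dprime <- function(params) {
  stopifnot(inherits(params, "sdt_params"))
  if (!params$equal_variance || params$sigma_t != 1)
    stop("d-prime requires the equal-variance model; use d_a for ",
         "unequal-variance parameters (not implemented)")
  (params$mu_t - params$mu_l) / params$sigma_l
}

#' Model-implied ROC curve
#'
#' Sweeps a fine grid of decision criteria, returning the model's
#' (estimated false ID rate, correct ID rate) locus: x is the TA any-ID rate
#' divided by k, y is the TP suspect-ID rate.
#'
#' @param params an \code{\link{sdt_params}}.
#' @param n_grid number of criterion values.
#' @param c_range criterion range swept (default spans the response scale).
#' @return a \code{roc_curve} data frame (origin-anchored, strictest first).
#' @export
predicted_roc <- function(params, n_grid = 101,
                          c_range = c(params$mu_t + 4, -2)) {
  stopifnot(inherits(params, "sdt_params"))
  cs <- seq(c_range[1], c_range[2], length.out = n_grid)
  y <- vapply(cs, function(c) p_tp_suspect_exceed(params, c), numeric(1))
  x <- vapply(cs, function(c) p_ta_id_exceed(params, c) / params$k, numeric(1))
  structure(data.frame(fid_rate = c(0, x), cid_rate = c(0, y),
                       weight = 0),
            class = c("roc_curve", "data.frame"),
            k = params$k, n_tp = NA_integer_, n_ta = NA_integer_,
            degenerate = FALSE)
}
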