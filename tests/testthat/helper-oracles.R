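# Shared oracles and small fixtures built in code.

# Monte-Carlo oracle for the independent-observations model: simulates raw
# strength draws and applies the max rule directly, independent of the
# package's quadrature path. Returns category probabilities and their
# binomial MC standard errors.
mc_category_probs <- function(mu_t, crit, k, n = 1e6, seed = 99) {
  set.seed(seed)
  tgt <- rnorm(n, mu_t)
  lure_max <- rep(-Inf, n)
  for (j in seq_len(k - 1)) lure_max <- pmax(lure_max, rnorm(n))
  s <- pmax(tgt, lure_max)
  sus <- mean(tgt >= lure_max & s > crit)
  fil <- mean(lure_max > tgt & s > crit)
  ta_max <- rep(-Inf, n)
  for (j in seq_len(k)) ta_max <- pmax(ta_max, rnorm(n))
  ta <- mean(ta_max > crit)
  se <- function(p) sqrt(p * (1 - p) / n)
  list(tp_suspect = sus, tp_filler = fil, ta_id = ta,
       se = c(tp_suspect = se(sus), tp_filler = se(fil), ta_id = se(ta)))
}

# Hand-built trapezoid pAUC, written independently of pauc()/pauc_mat().
trapezoid_pauc <- function(x, y, cutoff) {
  stopifnot(length(x) == length(y), cutoff > 0)
  n <- length(x)
  if (cutoff > x[n]) {
    dx <- x[n] - x[n - 1]
    slope <- if (dx > 0) (y[n] - y[n - 1]) / dx else 0
    x <- c(x, cutoff); y <- c(y, y[n] + slope * (cutoff - x[n]))
    n <- n + 1
  }
  area <- 0
  for (j in 2:n) {
    if (x[j - 1] >= cutoff) break
    hi <- min(x[j], cutoff)
    y_hi <- if (x[j] > x[j - 1])
      y[j - 1] + (y[j] - y[j - 1]) * (hi - x[j - 1]) / (x[j] - x[j - 1])
    else y[j]
    area <- area + (hi - x[j - 1]) * (y[j - 1] + y_hi) / 2
  }
  area
}

# A small synthetic outcome table with every response category populated.
toy_table <- function() {
  tp <- rbind(suspect_id = c(1, 2, 4, 8, 12, 16, 20),
              filler_id  = c(2, 2, 3, 3, 2, 1, 1),
              no_id      = c(5, 6, 8, 9, 7, 5, 3))
  ta <- rbind(filler_id  = c(3, 4, 6, 7, 6, 3, 1),
              no_id      = c(10, 12, 14, 16, 14, 12, 12))
  lineup_table(tp, ta, k = 6)
}

# Scale every count of a table by an integer factor.
scale_table <- function(table, factor) {
  lineup_table(table$tp * factor, table$ta * factor, k = table$k,
               bins = table$bins)
}

# Four-row toy trial CSV written to a temp file.
write_toy_trials <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    participant_id = c("a", "b", "c", "d"),
    group = "young", condition = "control",
    lineup_type = c("target_present", "target_present",
                    "target_absent", "target_absent"),
    response = c("suspect_id", "no_id", "filler_id", "no_id"),
    confidence = c(6L, 2L, 4L, 5L),
    rt = c(3.2, 20.1, 9.5, NA)
  )
  utils::write.csv(df, path, row.names = FALSE)
  path
}
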