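#' Confidence-accuracy characteristic (CAC)
#'
#' Suspect identification accuracy computed separately per confidence bin.
#' For a k-member lineup with no designated innocent suspect,
#' \code{accuracy = CID / (CID + FID / k)} where CID is the number of TP
#' suspect IDs and FID the number of TA filler IDs in the bin; FID/k
#' estimates how often an innocent suspect would have been picked.
#'
#' @param table a raw \code{\link{lineup_table}}.
#' @param scheme confidence binning scheme.
#' @return data frame of class \code{accuracy_curve} with columns \code{bin},
#'   \code{n_cid}, \code{n_fid}, \code{accuracy}, \code{weight}. Bins with no
#'   ID responses carry \code{accuracy = NA} (undefined, with a warning).
#' @export
cac <- function(table, scheme = default_bins()) {
  stopifnot(inherits(table, "lineup_table"))
  scheme <- confidence_bins(scheme)
  binned <- bin_confidence(table, scheme)
  accuracy_curve(colnames(binned$tp),
                 tp_suspect_counts(binned), ta_filler_counts(binned),
                 k = binned$k)
}

# Shared constructor for CAC/RAC curves from per-bin CID/FID counts.
accuracy_curve <- function(labels, n_cid, n_fid, k) {
  ids <- n_cid + n_fid
  acc <- ifelse(ids > 0, n_cid / (n_cid + n_fid / k), NA_real_)
  if (any(ids == 0))
    warning("bin(s) with no ID responses: accuracy undefined; ",
            "consider rebin_on_sparsity()")
  structure(
    data.frame(bin = as.character(labels), n_cid = as.numeric(n_cid),
               n_fid = as.numeric(n_fid), accuracy = acc,
               weight = if (sum(ids) > 0) ids / sum(ids) else rep(0, length(ids)),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("accuracy_curve", "data.frame"), k = k
  )
}

#' Response-time-accuracy characteristic (RAC)
#'
#' Suspect identification accuracy per response-time bin,
#' \code{accuracy = CID / (CID + FID / k)}, with identification responses
#' binned by how fast they were made. Default bins: < 6 s, 6-12 s, 12-18 s,
#' > 18 s (half-open; boundary values fall in the upper bin). Records
#' without a response time are excluded, with the exclusion count attached
#' as attribute \code{n_excluded}.
#'
#' @param records trial-level records (see \code{\link{load_trials}}).
#' @param edges interior RT bin edges in seconds (strictly increasing).
#' @param k lineup size.
#' @return an \code{accuracy_curve} over RT bins.
#' @export
rac <- function(records, edges = default_rt_edges(), k = 6) {
  records <- validate_trials(as.data.frame(records))
  ids <- records[records$response %in% c("suspect_id", "filler_id"), ]
  n_missing <- sum(is.na(ids$rt))
  ids <- ids[!is.na(ids$rt), ]
  nb <- length(edges) + 1L
  idx <- rt_bin_index(ids$rt, edges)
  is_cid <- ids$lineup_type == "target_present" & ids$response == "suspect_id"
  is_fid <- ids$lineup_type == "target_absent" & ids$response == "filler_id"
  n_cid <- vapply(seq_len(nb), function(j) sum(is_cid & idx == j), numeric(1))
  n_fid <- vapply(seq_len(nb), function(j) sum(is_fid & idx == j), numeric(1))
  out <- accuracy_curve(rt_bin_labels(edges), n_cid, n_fid, k = k)
  attr(out, "n_excluded") <- n_missing
  out
}

# Percentile interval bounds for a two-sided level (0.68 -> 16th/84th).
ci_probs <- function(level) c((1 - level) / 2, 1 - (1 - level) / 2)

#' Bootstrap confidence intervals for a CAC curve
#'
#' TP and TA lineups are resampled with replacement independently
#' (multinomial over outcome-by-confidence categories); accuracy is
#' recomputed per bin per replicate and a percentile interval at the stated
#' level is attached. 68\% intervals correspond to +/- 1 standard error.
#'
#' @param table a raw \code{\link{lineup_table}}.
#' @param scheme confidence binning scheme.
#' @param n_boot bootstrap replicates.
#' @param level two-sided interval level (default 0.68).
#' @param seed RNG seed.
#' @return the \code{accuracy_curve} with columns \code{ci_low},
#'   \code{ci_high} and logical \code{unstable} (bin empty in more than half
#'   of the replicates).
#' @export
bootstrap_cac <- function(table, scheme = default_bins(), n_boot = 10000,
                          level = 0.68, seed = NULL) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  scheme <- confidence_bins(scheme)
  curve <- suppressWarnings(cac(table, scheme))
  local_seed(seed)
  cum <- resample_cumulative(table, scheme, n_boot)
  nb <- length(scheme)
  # undo cumulation: per-bin counts, strictest first -> reorder low..high
  decum <- function(m) {
    m <- rbind(m[1, , drop = FALSE], diff(m))
    m[nb:1, , drop = FALSE]
  }
  cid <- decum(matrix(cum$cid, nrow = nb))
  fid <- decum(matrix(cum$fid, nrow = nb))
  attach_ci(curve, cid, fid, table$k, level)
}

#' Bootstrap confidence intervals for a RAC curve
#'
#' TP and TA trial records are resampled with replacement independently;
#' otherwise as \code{\link{bootstrap_cac}}.
#'
#' @inheritParams rac
#' @inheritParams bootstrap_cac
#' @return the \code{accuracy_curve} with \code{ci_low}/\code{ci_high}/
#'   \code{unstable}.
#' @export
bootstrap_rac <- function(records, edges = default_rt_edges(), k = 6,
                          n_boot = 10000, level = 0.68, seed = NULL) {
  stopifnot(n_boot >= 1)
  records <- validate_trials(as.data.frame(records))
  curve <- suppressWarnings(rac(records, edges, k = k))
  local_seed(seed)
  tp <- records[records$lineup_type == "target_present", ]
  ta <- records[records$lineup_type == "target_absent", ]
  nb <- length(edges) + 1L
  per_bin <- function(df, resp) {
    keep <- df$response == resp & !is.na(df$rt)
    idx <- integer(0)
    if (any(keep)) idx <- rt_bin_index(df$rt[keep], edges)
    # category index per trial: bin for qualifying IDs, 0 otherwise
    cat_idx <- integer(nrow(df))
    cat_idx[keep] <- idx
    cat_idx
  }
  cid_cat <- per_bin(tp, "suspect_id")
  fid_cat <- per_bin(ta, "filler_id")
  draw_counts <- function(cat_idx, n) {
    if (n == 0) return(matrix(0, nb, n_boot))
    picks <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    apply(picks, 2, function(p) tabulate(cat_idx[p], nbins = nb))
  }
  cid <- draw_counts(cid_cat, nrow(tp))
  fid <- draw_counts(fid_cat, nrow(ta))
  attach_ci(curve, cid, fid, k, level)
}

# Percentile CIs from per-bin bootstrap CID/FID count matrices.
attach_ci <- function(curve, cid, fid, k, level) {
  nb <- nrow(curve)
  probs <- ci_probs(level)
  lo <- hi <- unstable <- rep(NA_real_, nb)
  for (j in seq_len(nb)) {
    ids <- cid[j, ] + fid[j, ]
    acc <- ifelse(ids > 0, cid[j, ] / (cid[j, ] + fid[j, ] / k), NA_real_)
    frac_empty <- mean(ids == 0)
    unstable[j] <- frac_empty > 0.5
    ok <- acc[!is.na(acc)]
    if (length(ok) > 0) {
      q <- stats::quantile(ok, probs, names = FALSE, type = 7)
      lo[j] <- q[1]; hi[j] <- q[2]
    }
  }
  curve$ci_low <- lo
  curve$ci_high <- hi
  curve$unstable <- as.logical(unstable)
  attr(curve, "level") <- level
  curve
}

#' Do two accuracy-curve error bars overlap?
#'
#' The graphical inference rule for CAC/RAC comparisons: a difference between
#' two bins (possibly from different curves) is treated as reliable when
#' their bootstrap error bars do not overlap. Exposed as a predicate, never
#' as a p-value.
#'
#' @param curve_a,curve_b \code{accuracy_curve}s carrying CIs.
#' @param bin_a,bin_b bin indices or labels to compare.
#' @return \code{TRUE} if the intervals overlap (no reliable difference).
#' @export
bars_overlap <- function(curve_a, bin_a, curve_b = curve_a, bin_b) {
  pick <- function(curve, bin) {
    if (!all(c("ci_low", "ci_high") %in% names(curve)))
      stop("curve carries no intervals: bootstrap the curve first")
    i <- if (is.character(bin)) match(bin, curve$bin) else bin
    if (is.na(i) || i < 1 || i > nrow(curve)) stop("bin not found")
    c(curve$ci_low[i], curve$ci_high[i])
  }
  a <- pick(curve_a, bin_a); b <- pick(curve_b, bin_b)
  if (anyNA(c(a, b))) stop("missing interval: bootstrap the curve first")
  a[1] <= b[2] && b[1] <= a[2]
}
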