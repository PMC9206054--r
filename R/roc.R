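#' Confidence-based ROC curve for lineup data
#'
#' Accumulates identification rates from the strictest (highest) confidence
#' bin to the most lenient. Point j plots the cumulative estimated false ID
#' rate (TA filler IDs at bins >= j, divided by the number of TA lineups and
#' by the lineup size k) against the cumulative correct ID rate (TP suspect
#' IDs at bins >= j over TP lineups). An origin anchor (0, 0) is prepended.
#' The rightmost point equals the overall (estimated false ID rate,
#' correct ID rate).
#'
#' @param binned a binned \code{\link{lineup_table}} (see
#'   \code{\link{bin_confidence}}).
#' @return data frame of class \code{roc_curve} with columns
#'   \code{fid_rate}, \code{cid_rate}, \code{weight} (relative frequency of
#'   ID responses contributing to each point; 0 at the anchor). A table with
#'   no ID responses at all yields the degenerate single-point curve, with
#'   attribute \code{degenerate = TRUE}.
#' @export
roc_points <- function(binned) {
  stopifnot(inherits(binned, "lineup_table"))
  if (binned$n_tp == 0 || binned$n_ta == 0)
    stop("both lineup types are required for an ROC curve")
  cid <- rev(tp_suspect_counts(binned))  # strictest bin first
  fid <- rev(ta_filler_counts(binned))
  total_ids <- sum(cid) + sum(fid)
  degenerate <- total_ids == 0
  out <- data.frame(
    fid_rate = c(0, cumsum(fid) / binned$n_ta / binned$k),
    cid_rate = c(0, cumsum(cid) / binned$n_tp),
    weight = c(0, if (degenerate) rep(0, length(cid)) else (cid + fid) / total_ids)
  )
  if (degenerate) out <- out[1, , drop = FALSE]
  structure(out, class = c("roc_curve", "data.frame"),
            k = binned$k, n_tp = binned$n_tp, n_ta = binned$n_ta,
            degenerate = degenerate)
}

#' Shared false-ID-rate cutoff from the more conservative condition
#'
#' The pAUC comparison integrates both curves over a common false ID range
#' ending at the rightmost point of the condition that produced fewer
#' identifications overall (more conservative responding), i.e. the smaller
#' of the two rightmost false ID rates.
#'
#' @param curve_a,curve_b \code{roc_curve} objects.
#' @return the cutoff (scalar); attribute \code{degenerate = TRUE} if either
#'   curve collapses to the origin (cutoff 0).
#' @export
conservative_cutoff <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "roc_curve"), inherits(curve_b, "roc_curve"))
  ca <- max(curve_a$fid_rate); cb <- max(curve_b$fid_rate)
  out <- min(ca, cb)
  attr(out, "degenerate") <- out == 0
  out
}

# Vectorised trapezoidal pAUC over columns of x/y point matrices (points in
# rows, replicates in columns), integrating from 0 to cutoff with linear
# interpolation inside a segment and linear extrapolation of the final
# segment beyond the rightmost point.
pauc_mat <- function(x, y, cutoff) {
  stopifnot(cutoff > 0, nrow(x) == nrow(y), ncol(x) == ncol(y))
  p <- nrow(x); B <- ncol(x)
  # extrapolated final point at the cutoff where needed
  dx <- x[p, ] - x[p - 1, ]
  slope <- ifelse(dx > 0, (y[p, ] - y[p - 1, ]) / dx, 0)
  need_ext <- x[p, ] < cutoff
  x_ext <- ifelse(need_ext, cutoff, x[p, ])
  y_ext <- ifelse(need_ext, y[p, ] + slope * (cutoff - x[p, ]), y[p, ])
  x <- rbind(x, x_ext); y <- rbind(y, y_ext)
  area <- numeric(B)
  for (j in 2:(p + 1)) {
    lo <- x[j - 1, ]; hi <- x[j, ]
    hic <- pmin(hi, cutoff)
    w <- pmax(hic - pmin(lo, cutoff), 0)
    frac <- ifelse(hi > lo, (hic - lo) / (hi - lo), 1)
    y_hic <- y[j - 1, ] + (y[j, ] - y[j - 1, ]) * pmin(pmax(frac, 0), 1)
    area <- area + w * (y[j - 1, ] + y_hic) / 2
  }
  list(pauc = area, extrapolated = need_ext)
}

#' Partial area under a lineup ROC curve
#'
#' Trapezoidal area between false ID rate 0 (the origin anchor) and the
#' cutoff. A cutoff falling inside a segment is handled by linear
#' interpolation; a cutoff beyond the curve's rightmost point is handled by
#' linearly extrapolating the final segment, flagged via the
#' \code{extrapolated} attribute.
#'
#' @param curve a \code{roc_curve}.
#' @param cutoff false-ID-rate upper integration limit (> 0).
#' @return the pAUC (scalar) with attribute \code{extrapolated}.
#' @export
pauc <- function(curve, cutoff) {
  stopifnot(inherits(curve, "roc_curve"))
  if (cutoff <= 0) stop("cutoff must be positive")
  if (nrow(curve) < 2) {  # degenerate single-point curve
    out <- 0; attr(out, "extrapolated") <- FALSE
    return(out)
  }
  res <- pauc_mat(matrix(curve$fid_rate, ncol = 1),
                  matrix(curve$cid_rate, ncol = 1), cutoff)
  out <- res$pauc
  attr(out, "extrapolated") <- res$extrapolated
  out
}

# Resample a raw (7-level) table at the trial level: independent multinomial
# draws over the TP and TA outcome categories. Returns cumulative binned
# suspect-ID and filler-ID count matrices (strictest bin first), one column
# per replicate.
resample_cumulative <- function(table, scheme, n_boot) {
  stopifnot(inherits(table, "lineup_table"))
  tp_counts <- as.vector(table$tp)        # 21 categories
  ta_counts <- as.vector(table$ta)        # 14 categories
  tp_draw <- stats::rmultinom(n_boot, table$n_tp, tp_counts / table$n_tp)
  ta_draw <- stats::rmultinom(n_boot, table$n_ta, ta_counts / table$n_ta)
  # suspect_id is row 1 of tp (3 rows x 7 levels); filler_id row 1 of ta
  sus <- tp_draw[seq(1, by = 3, length.out = 7), , drop = FALSE]
  fil <- ta_draw[seq(1, by = 2, length.out = 7), , drop = FALSE]
  bin_rows <- function(m) {
    t(vapply(scheme, function(b) colSums(m[b, , drop = FALSE]),
             numeric(ncol(m))))
  }
  sus_b <- bin_rows(sus); fil_b <- bin_rows(fil)
  nb <- length(scheme)
  list(
    cid = apply(sus_b[nb:1, , drop = FALSE], 2, cumsum),
    fid = apply(fil_b[nb:1, , drop = FALSE], 2, cumsum)
  )
}

#' Bootstrap distribution of the pAUC
#'
#' Resamples TP and TA lineups independently with replacement at the trial
#' level (multinomial over the outcome-by-confidence categories), rebins each
#' replicate, rebuilds the ROC and recomputes the pAUC at a fixed cutoff.
#'
#' @param table a raw (7-level) \code{\link{lineup_table}}.
#' @param scheme confidence binning scheme.
#' @param cutoff false-ID-rate integration limit.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed (required for reproducibility).
#' @return numeric vector of \code{n_boot} pAUC values.
#' @export
bootstrap_pauc <- function(table, scheme = default_bins(), cutoff,
                           n_boot = 10000, seed = NULL) {
  stopifnot(n_boot >= 1, cutoff > 0)
  scheme <- confidence_bins(scheme)
  local_seed(seed)
  cum <- resample_cumulative(table, scheme, n_boot)
  x <- rbind(0, cum$fid / table$n_ta / table$k)
  y <- rbind(0, cum$cid / table$n_tp)
  out <- pauc_mat(x, y, cutoff)$pauc
  if (stats::sd(out) == 0)
    warning("degenerate bootstrap: all replicates identical (SE 0)")
  out
}

#' Bootstrap Z-test comparing two pAUCs
#'
#' Builds both ROC curves under a common binning scheme, sets the cutoff from
#' the more conservative condition, and tests the pAUC difference with
#' \code{Z = (pAUC_1 - pAUC_2) / sd(pAUC_1* - pAUC_2*)}, the denominator
#' being the standard deviation of the difference across paired bootstrap
#' replicates (independent trial-level resampling within each condition).
#' Two-sided p from the standard normal.
#'
#' @param table_a,table_b raw (7-level) \code{\link{lineup_table}}s.
#' @param scheme confidence binning scheme.
#' @param n_boot bootstrap replicates (10000 by default).
#' @param seed RNG seed.
#' @return list of class \code{pauc_comparison}: \code{pauc_1},
#'   \code{pauc_2}, \code{cutoff}, \code{se_diff}, \code{z}, \code{p},
#'   \code{n_boot}, \code{seed}, plus extrapolation flags.
#' @export
pauc_z_test <- function(table_a, table_b, scheme = default_bins(),
                        n_boot = 10000, seed = 1) {
  scheme <- confidence_bins(scheme)
  curve_a <- roc_points(bin_confidence(table_a, scheme))
  curve_b <- roc_points(bin_confidence(table_b, scheme))
  cutoff <- conservative_cutoff(curve_a, curve_b)
  if (isTRUE(attr(cutoff, "degenerate")))
    stop("a curve is degenerate at the origin: pAUC comparison undefined")
  p1 <- pauc(curve_a, cutoff)
  p2 <- pauc(curve_b, cutoff)
  b1 <- bootstrap_pauc(table_a, scheme, cutoff, n_boot,
                       seed = child_seed(seed, 0))
  b2 <- bootstrap_pauc(table_b, scheme, cutoff, n_boot,
                       seed = child_seed(seed, 1))
  se <- stats::sd(b1 - b2)
  z <- if (se == 0) {
    if (p1 == p2) 0 else sign(p1 - p2) * Inf
  } else (as.numeric(p1) - as.numeric(p2)) / se
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  structure(list(
    pauc_1 = as.numeric(p1), pauc_2 = as.numeric(p2),
    cutoff = as.numeric(cutoff), se_diff = se, z = z, p = p,
    n_boot = n_boot, seed = seed,
    extrapolated_1 = isTRUE(attr(p1, "extrapolated")),
    extrapolated_2 = isTRUE(attr(p2, "extrapolated"))
  ), class = "pauc_comparison")
}

#' @export
print.pauc_comparison <- function(x, ...) {
  cat(sprintf("pAUC comparison (cutoff %.6f, %d bootstrap replicates)\n",
              x$cutoff, x$n_boot))
  cat(sprintf("  pAUC_1 = %.6f, pAUC_2 = %.6f\n", x$pauc_1, x$pauc_2))
  cat(sprintf("  Z = %.4f, p = %.4f (two-sided)\n", x$z, x$p))
  invisible(x)
}
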