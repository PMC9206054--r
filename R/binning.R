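#' Confidence binning schemes
#'
#' A binning scheme is an ordered partition of the 7-point confidence scale
#' from lowest to highest confidence. The default scheme pools the sparse
#' scale endpoints the way the reliability and ROC analyses require when
#' extreme ratings are too rare to bootstrap: low (1-3), medium-low (4),
#' medium-high (5), high (6-7).
#'
#' @param bins list of integer vectors jointly partitioning \code{1:7}.
#' @return the validated scheme (a list of integer vectors).
#' @export
confidence_bins <- function(bins) {
  stopifnot(is.list(bins), length(bins) >= 1)
  bins <- lapply(bins, function(b) sort(as.integer(b)))
  flat <- unlist(bins)
  if (!identical(sort(flat), 1:7))
    stop("bins must partition the confidence scale 1..7 exactly")
  # ordered lowest to highest
  highs <- vapply(bins, max, integer(1))
  if (is.unsorted(highs, strictly = TRUE))
    stop("bins must be ordered from lowest to highest confidence")
  bins
}

#' @rdname confidence_bins
#' @export
default_bins <- function() confidence_bins(list(1:3, 4L, 5L, 6:7))

#' Pool a lineup table's confidence levels into bins
#'
#' Counts are summed within each bin of the scheme; lineup totals are
#' conserved.
#'
#' @param table a \code{\link{lineup_table}} with singleton levels 1..7.
#' @param scheme a scheme from \code{\link{confidence_bins}}.
#' @return a binned \code{\link{lineup_table}} with one column per bin.
#' @export
bin_confidence <- function(table, scheme = default_bins()) {
  stopifnot(inherits(table, "lineup_table"))
  scheme <- confidence_bins(scheme)
  if (!all(lengths(table$bins) == 1))
    stop("table is already binned; bin from the raw 7-level table")
  levels <- unlist(table$bins)
  pool <- function(m) {
    out <- vapply(scheme, function(b) rowSums(m[, match(b, levels), drop = FALSE]),
                  numeric(nrow(m)))
    matrix(out, nrow = nrow(m), dimnames = list(rownames(m), NULL))
  }
  lineup_table(pool(table$tp), pool(table$ta), k = table$k, bins = scheme)
}

#' Default response-time bins
#'
#' Half-open RT bins in seconds: < 6, [6, 12), [12, 18), >= 18. Boundary
#' values fall in the upper bin.
#'
#' @return numeric vector of interior bin edges \code{c(6, 12, 18)}.
#' @export
default_rt_edges <- function() c(6, 12, 18)

# Assign RTs (seconds) to half-open bins defined by interior edges.
rt_bin_index <- function(rt, edges = default_rt_edges()) {
  stopifnot(all(diff(edges) > 0))
  findInterval(rt, edges) + 1L
}

rt_bin_labels <- function(edges = default_rt_edges()) {
  n <- length(edges)
  c(sprintf("<%gs", edges[1]),
    if (n > 1) sprintf("%g-%gs", edges[-n], edges[-1]),
    sprintf(">%gs", edges[n]))
}

#' Merge sparse bins until each holds enough identifications
#'
#' Mirrors the re-binning rule used when a bin holds too few identification
#' responses for bootstrap error bars: adjacent bins are merged (each sparse
#' bin with its smaller neighbour) until every bin holds at least
#' \code{min_count} responses.
#'
#' @param counts identification responses per ordered bin.
#' @param min_count minimum responses per bin (default 10).
#' @return list with \code{groups} (list of original-bin index vectors) and
#'   \code{log} (character vector describing each merge).
#' @export
rebin_on_sparsity <- function(counts, min_count = 10) {
  stopifnot(all(counts >= 0), min_count >= 1)
  groups <- as.list(seq_along(counts))
  totals <- as.numeric(counts)
  log <- character(0)
  if (sum(totals) < min_count) {
    warning("total responses below min_count; collapsing to a single bin")
    return(list(groups = list(seq_along(counts)),
                log = "collapsed all bins (insufficient total)"))
  }
  while (length(totals) > 1 && any(totals < min_count)) {
    i <- which(totals < min_count)[1]
    # merge with the smaller adjacent neighbour (right on ties/edges)
    j <- if (i == 1) 2
         else if (i == length(totals)) i - 1
         else if (totals[i - 1] < totals[i + 1]) i - 1 else i + 1
    a <- min(i, j); b <- max(i, j)
    log <- c(log, sprintf("merged bins %s and %s (counts %g + %g)",
                          paste(groups[[a]], collapse = ","),
                          paste(groups[[b]], collapse = ","),
                          totals[a], totals[b]))
    groups[[a]] <- c(groups[[a]], groups[[b]])
    totals[a] <- totals[a] + totals[b]
    groups[[b]] <- NULL
    totals <- totals[-b]
  }
  list(groups = groups, log = log)
}
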