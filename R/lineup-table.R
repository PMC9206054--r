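#' Lineup outcome frequency table
#'
#' The unit of analysis for simultaneous lineup experiments: counts of each
#' response category at each confidence level, separately for target-present
#' (TP) and target-absent (TA) lineups. TP lineups admit three responses
#' (suspect ID, filler ID, no ID); TA lineups without a designated innocent
#' suspect admit two (filler ID, no ID).
#'
#' @param tp numeric matrix of TP counts with rows
#'   \code{c("suspect_id", "filler_id", "no_id")} and one column per
#'   confidence level or bin.
#' @param ta numeric matrix of TA counts with rows
#'   \code{c("filler_id", "no_id")} and the same columns as \code{tp}.
#' @param k lineup size (members per lineup); the study design here uses 6.
#' @param bins list of integer vectors giving the raw confidence levels
#'   pooled in each column; defaults to singleton levels \code{1..ncol}.
#'
#' @return An object of class \code{lineup_table} with elements \code{tp},
#'   \code{ta}, \code{k}, \code{bins}, \code{n_tp}, \code{n_ta}.
#' @export
lineup_table <- function(tp, ta, k = 6, bins = NULL) {
  tp <- as.matrix(tp); ta <- as.matrix(ta)
  if (is.null(rownames(tp))) rownames(tp) <- c("suspect_id", "filler_id", "no_id")
  if (is.null(rownames(ta))) rownames(ta) <- c("filler_id", "no_id")
  stopifnot(
    nrow(tp) == 3, nrow(ta) == 2, ncol(tp) == ncol(ta),
    all(tp >= 0), all(ta >= 0), k >= 2,
    identical(rownames(tp), c("suspect_id", "filler_id", "no_id")),
    identical(rownames(ta), c("filler_id", "no_id"))
  )
  if (is.null(bins)) bins <- as.list(seq_len(ncol(tp)))
  stopifnot(length(bins) == ncol(tp))
  labels <- vapply(bins, function(b) {
    if (length(b) == 1) as.character(b) else paste0(min(b), "-", max(b))
  }, character(1))
  colnames(tp) <- labels; colnames(ta) <- labels
  structure(
    list(tp = tp, ta = ta, k = k, bins = bins,
         n_tp = sum(tp), n_ta = sum(ta)),
    class = "lineup_table"
  )
}

#' @export
print.lineup_table <- function(x, ...) {
  cat(sprintf("Lineup outcome table: %d TP / %d TA lineups, k = %d\n",
              x$n_tp, x$n_ta, x$k))
  cat("Target-present counts (by confidence bin):\n")
  print(x$tp)
  cat("Target-absent counts:\n")
  print(x$ta)
  invisible(x)
}

# Column totals used throughout: TP suspect IDs and TA filler IDs per bin.
tp_suspect_counts <- function(table) table$tp["suspect_id", ]
ta_filler_counts  <- function(table) table$ta["filler_id", ]

#' Read trial-level lineup records from CSV
#'
#' Expects a comma-separated, UTF-8 file with columns \code{participant_id},
#' \code{group}, \code{condition}, \code{lineup_type}, \code{response},
#' \code{confidence} and \code{rt} (seconds; may be empty). Each row is one
#' witness's lineup decision.
#'
#' @param path path to the CSV file.
#' @return data frame of validated trial records.
#' @export
load_trials <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "group", "condition", "lineup_type",
                "response", "confidence", "rt")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("trial CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$rt <- suppressWarnings(as.numeric(df$rt))
  if (nrow(df) == 0) return(validate_trials(df))
  validate_trials(df)
}

# Shared validation for trial-level records; reports offending rows.
validate_trials <- function(df) {
  if (nrow(df) == 0) return(df)
  bad <- which(!(df$confidence %in% 1:7))
  if (length(bad) > 0)
    stop("confidence outside 1-7 in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!df$lineup_type %in% c("target_present", "target_absent"))
  if (length(bad) > 0)
    stop("invalid lineup_type in row(s): ", paste(bad, collapse = ", "))
  bad <- which(!df$response %in% c("suspect_id", "filler_id", "no_id"))
  if (length(bad) > 0)
    stop("invalid response in row(s): ", paste(bad, collapse = ", "))
  # No designated innocent suspect: a TA lineup cannot yield a suspect ID.
  bad <- which(df$lineup_type == "target_absent" & df$response == "suspect_id")
  if (length(bad) > 0)
    stop("suspect_id recorded for target-absent lineup in row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(!is.na(df$rt) & df$rt <= 0)
  if (length(bad) > 0)
    stop("non-positive response time in row(s): ", paste(bad, collapse = ", "))
  df
}

#' Tabulate trial records into a lineup outcome table
#'
#' @param records data frame of trial records (see \code{\link{load_trials}}).
#'   All records must belong to a single (group, condition) cell; group by
#'   those variables first otherwise.
#' @param k lineup size.
#' @return a \code{\link{lineup_table}} with singleton confidence bins 1..7.
#' @export
tabulate_trials <- function(records, k = 6) {
  records <- validate_trials(as.data.frame(records))
  if (nrow(records) > 0) {
    cells <- unique(records[, c("group", "condition")])
    if (nrow(cells) > 1)
      stop("records span multiple (group, condition) cells; group them first")
  }
  tp <- matrix(0L, 3, 7,
               dimnames = list(c("suspect_id", "filler_id", "no_id"), 1:7))
  ta <- matrix(0L, 2, 7, dimnames = list(c("filler_id", "no_id"), 1:7))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$lineup_type == "target_present")
      tp[r$response, r$confidence] <- tp[r$response, r$confidence] + 1L
    else
      ta[r$response, r$confidence] <- ta[r$response, r$confidence] + 1L
  }
  lineup_table(tp, ta, k = k, bins = as.list(1:7))
}

#' Expand a frequency table into trial-level records
#'
#' Emits one trial record per tabulated count (response times absent), so
#' trial-level APIs can run on aggregated frequency data.
#' \code{tabulate_trials(expand_table(x))} recovers \code{x}.
#'
#' @param table a \code{\link{lineup_table}} with singleton confidence bins.
#' @param group,condition labels attached to the emitted records.
#' @return data frame of trial records with \code{rt = NA}.
#' @export
expand_table <- function(table, group = "young", condition = "control") {
  stopifnot(inherits(table, "lineup_table"))
  if (!all(lengths(table$bins) == 1))
    stop("expand_table() requires unbinned (singleton-level) tables")
  rows <- list()
  emit <- function(lineup_type, response, conf, n) {
    if (n == 0) return(NULL)
    data.frame(
      participant_id = NA_character_, group = group, condition = condition,
      lineup_type = lineup_type, response = response,
      confidence = as.integer(conf), rt = NA_real_,
      stringsAsFactors = FALSE
    )[rep(1L, n), ]
  }
  for (j in seq_along(table$bins)) {
    conf <- table$bins[[j]]
    for (resp in rownames(table$tp))
      rows[[length(rows) + 1L]] <- emit("target_present", resp, conf, table$tp[resp, j])
    for (resp in rownames(table$ta))
      rows[[length(rows) + 1L]] <- emit("target_absent", resp, conf, table$ta[resp, j])
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(participant_id = character(), group = character(),
                      condition = character(), lineup_type = character(),
                      response = character(), confidence = integer(),
                      rt = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$participant_id <- sprintf("p%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Read/write aggregated frequency tables
#'
#' The aggregated CSV format has one row per
#' (lineup_type, response, confidence) with a \code{count} column, plus
#' optional \code{group}/\code{condition} columns.
#'
#' @param path CSV path.
#' @param k lineup size recorded in the resulting table.
#' @return \code{read_lineup_counts}: a \code{\link{lineup_table}}.
#' @export
read_lineup_counts <- function(path, k = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts_to_table(df, k = k)
}

#' @rdname read_lineup_counts
#' @param table a \code{\link{lineup_table}} to serialise.
#' @export
write_lineup_counts <- function(table, path) {
  stopifnot(inherits(table, "lineup_table"))
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.lineup_table <- function(x, ...) {
  grab <- function(m, lt) {
    do.call(rbind, lapply(rownames(m), function(r) {
      data.frame(lineup_type = lt, response = r,
                 confidence = colnames(m), count = as.integer(m[r, ]),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(grab(x$tp, "target_present"), grab(x$ta, "target_absent"))
}

# Build a lineup_table from a long count data frame (single cell).
counts_to_table <- function(df, k = 6) {
  stopifnot(all(c("lineup_type", "response", "confidence", "count") %in% names(df)))
  conf <- sort(unique(as.integer(df$confidence)))
  stopifnot(all(conf %in% 1:7))
  levels <- 1:7
  tp <- matrix(0L, 3, 7,
               dimnames = list(c("suspect_id", "filler_id", "no_id"), levels))
  ta <- matrix(0L, 2, 7, dimnames = list(c("filler_id", "no_id"), levels))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cj <- as.integer(r$confidence)
    if (r$lineup_type == "target_present")
      tp[r$response, cj] <- tp[r$response, cj] + as.integer(r$count)
    else
      ta[r$response, cj] <- ta[r$response, cj] + as.integer(r$count)
  }
  lineup_table(tp, ta, k = k, bins = as.list(1:7))
}

#' Packaged frequency table from the verbal-overshadowing lineup study
#'
#' Outcome frequencies from a large pre-registered study of verbal
#' overshadowing in eyewitness identification: 1000 young (18-30) and 1000
#' older (60+) adults each viewed a mock-crime video and, after a filled
#' 20-minute delay, either described the perpetrator (experimental) or
#' performed a control task, then attempted an identification from a
#' six-member simultaneous lineup (250 target-present and 250 target-absent
#' lineups per group and condition) with confidence rated 1-7. These counts
#' anchor the package's regression tests.
#'
#' @param group \code{"young"} or \code{"older"}.
#' @param condition \code{"control"} or \code{"experimental"}.
#' @return a \code{\link{lineup_table}} with \code{n_tp = n_ta = 250},
#'   \code{k = 6}.
#' @export
vo_counts <- function(group = c("young", "older"),
                      condition = c("control", "experimental")) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  path <- system.file("extdata", "vo_lineup_counts.csv", package = "lineupROC")
  if (path == "") path <- file.path("inst", "extdata", "vo_lineup_counts.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$group == group & df$condition == condition, ]
  counts_to_table(df, k = 6)
}
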