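#' Reproduce the full Results-section analysis from the packaged fixture
#'
#' Runs, on the four packaged (group x condition) cells: correct and
#' estimated false ID rates; the four 2x2 chi-square comparisons (correct IDs
#' and TA false alarms, within each age group); the three pAUC bootstrap
#' Z-tests (young vs older within the control condition, and control vs
#' experimental within each age group); CAC curves with bootstrap intervals;
#' and equal-variance SDT model fits with d-prime per cell. RAC is omitted
#' here because the packaged fixture is aggregated and carries no response
#' times; see \code{\link{rac}} for trial-level data.
#'
#' @param seed RNG seed; all resampling derives child seeds from it.
#' @param n_boot bootstrap replicates for pAUC tests and CAC intervals.
#' @param scheme confidence binning scheme.
#' @return list of class \code{lineup_report} with elements \code{rates},
#'   \code{chisq}, \code{pauc_tests}, \code{cac}, \code{sdt_fits},
#'   \code{provenance}.
#' @export
reproduce_analysis <- function(seed = 1, n_boot = 10000,
                               scheme = default_bins()) {
  scheme <- confidence_bins(scheme)
  cells <- expand.grid(group = c("young", "older"),
                       condition = c("control", "experimental"),
                       stringsAsFactors = FALSE)
  tabs <- Map(vo_counts, cells$group, cells$condition)
  names(tabs) <- paste(cells$group, cells$condition, sep = "_")

  rates <- do.call(rbind, lapply(names(tabs), function(nm) {
    data.frame(cell = nm,
               correct_id_rate = correct_id_rate(tabs[[nm]])$rate,
               est_false_id_rate = estimated_false_id_rate(tabs[[nm]])$rate)
  }))

  chisq <- list(
    correct_ids_young = compare_conditions(tabs$young_control,
                                           tabs$young_experimental,
                                           "correct_ids"),
    correct_ids_older = compare_conditions(tabs$older_control,
                                           tabs$older_experimental,
                                           "correct_ids"),
    ta_false_alarms_young = compare_conditions(tabs$young_control,
                                               tabs$young_experimental,
                                               "ta_false_alarms"),
    ta_false_alarms_older = compare_conditions(tabs$older_control,
                                               tabs$older_experimental,
                                               "ta_false_alarms")
  )

  pauc_tests <- list(
    age_control = pauc_z_test(tabs$young_control, tabs$older_control,
                              scheme, n_boot, seed = child_seed(seed, 0)),
    condition_young = pauc_z_test(tabs$young_control, tabs$young_experimental,
                                  scheme, n_boot, seed = child_seed(seed, 1)),
    condition_older = pauc_z_test(tabs$older_control, tabs$older_experimental,
                                  scheme, n_boot, seed = child_seed(seed, 2))
  )

  cac_curves <- lapply(seq_along(tabs), function(i)
    bootstrap_cac(tabs[[i]], scheme, n_boot = n_boot,
                  seed = child_seed(seed, 10 + i)))
  names(cac_curves) <- names(tabs)

  sdt_fits <- lapply(tabs, function(tab)
    fit_sdt(bin_confidence(tab, scheme), seed = child_seed(seed, 20)))

  structure(list(
    rates = rates, chisq = chisq, pauc_tests = pauc_tests,
    cac = cac_curves, sdt_fits = sdt_fits,
    provenance = list(seed = seed, n_boot = n_boot, scheme = scheme)
  ), class = "lineup_report")
}

#' @export
print.lineup_report <- function(x, ...) {
  cat("== Identification rates ==\n")
  print(x$rates, row.names = FALSE)
  cat("\n== Condition comparisons (Pearson chi-square, df = 1) ==\n")
  for (nm in names(x$chisq))
    cat(sprintf("  %-24s chi-square = %8.4f, p = %.6f\n", nm,
                x$chisq[[nm]]$statistic, x$chisq[[nm]]$p))
  cat("\n== pAUC bootstrap Z-tests ==\n")
  for (nm in names(x$pauc_tests)) {
    t <- x$pauc_tests[[nm]]
    cat(sprintf("  %-18s pAUC %.5f vs %.5f (cutoff %.5f): Z = %.3f, p = %.4f\n",
                nm, t$pauc_1, t$pauc_2, t$cutoff, t$z, t$p))
  }
  cat("\n== Fitted equal-variance SDT model (d-prime per cell) ==\n")
  for (nm in names(x$sdt_fits))
    cat(sprintf("  %-20s d' = %.3f\n", nm, dprime(x$sdt_fits[[nm]]$params)))
  cat(sprintf("\nseed %d, %d bootstrap replicates\n",
              x$provenance$seed, x$provenance$n_boot))
  invisible(x)
}
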