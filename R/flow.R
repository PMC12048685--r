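#' Quality-control exclusion of clog-affected events
#'
#' Excludes low-quality events recorded after instrument anomalies such as a
#' flow-cell clog. Two detectors are available: `"flag"` trusts the per-event
#' anomaly flag carried by the table; `"rate"` bins events by acquisition
#' time and excludes whole bins whose event rate deviates from the run
#' median by more than `rate_factor` in either direction.
#'
#' @param events Event tibble with `acq_index`, `time_s`, and (for the flag
#'   method) `anomaly` columns.
#' @param method `"flag"` or `"rate"`.
#' @param rate_factor Maximum tolerated fold deviation of a bin's rate from
#'   the median bin rate.
#' @param bin_s Bin width in seconds for the rate method. The terminal
#'   (possibly incomplete) bin is exempt from the low-rate test.
#' @return A logical vector, `TRUE` for events passing QC.
#' @export
qc_exclude <- function(events, method = c("flag", "rate"),
                       rate_factor = 3, bin_s = 0.1) {
  method <- match.arg(method)
  if (nrow(events) == 0) return(logical(0))
  if (is.unsorted(events$acq_index, strictly = TRUE)) {
    abort("`acq_index` must be strictly increasing.")
  }
  if (method == "flag") {
    return(!events$anomaly)
  }
  bins <- floor(events$time_s / bin_s)
  rate <- table(bins)
  med <- median(as.numeric(rate))
  last_bin <- names(rate)[length(rate)]
  high <- as.numeric(rate) > med * rate_factor
  low <- as.numeric(rate) < med / rate_factor & names(rate) != last_bin
  bad <- names(rate)[high | low]
  !(as.character(bins) %in% bad)
}

#' Gate viable cells and singlets from scatter channels
#'
#' Viable cells are events inside a robust ellipse on
#' `log10(FSC-A)` / `log10(SSC-A)`: center at the channel medians, half-axes
#' `k` scaled MADs, which excludes the low-scatter debris floor. Singlets
#' are viable events whose FSC-H/FSC-A ratio lies within a relative band
#' around the viable-population median ratio, excluding doublets (whose
#' area is about twice their height). Gates are nested within `qc_pass`.
#'
#' @param events Event tibble with `fsc_a`, `fsc_h`, `ssc_a`.
#' @param qc_pass Optional logical QC mask (default: all pass).
#' @param k Ellipse half-axis in scaled-MAD units.
#' @param ratio_band Half-width of the relative FSC-H/FSC-A band.
#' @param min_events Minimum events required to estimate the gates.
#' @return An object of class `gate_chain`: a list of nested logical masks
#'   `qc_pass`, `viable`, `singlet` (and later `mruby_pos`) plus a `counts`
#'   tibble.
#' @export
gate_viable_singlets <- function(events, qc_pass = NULL, k = 4,
                                 ratio_band = 0.15, min_events = 100) {
  qc_pass <- qc_pass %||% rep(TRUE, nrow(events))
  stopifnot(length(qc_pass) == nrow(events))
  if (sum(qc_pass) < min_events) {
    abort(sprintf("Fewer than %d events pass QC; cannot estimate gates.",
                  min_events))
  }
  lf <- log10(events$fsc_a)
  ls <- log10(events$ssc_a)
  cf <- median(lf[qc_pass]); cs <- median(ls[qc_pass])
  mf <- mad(lf[qc_pass]); ms <- mad(ls[qc_pass])
  viable <- qc_pass &
    ((lf - cf) / (k * mf))^2 + ((ls - cs) / (k * ms))^2 <= 1
  ratio <- events$fsc_h / events$fsc_a
  med_ratio <- median(ratio[viable])
  singlet <- viable & abs(ratio / med_ratio - 1) <= ratio_band
  new_gate_chain(qc_pass = qc_pass, viable = viable, singlet = singlet)
}

new_gate_chain <- function(qc_pass, viable, singlet, mruby_pos = NULL) {
  masks <- purrr::compact(list(qc_pass = qc_pass, viable = viable,
                               singlet = singlet, mruby_pos = mruby_pos))
  counts <- tibble::tibble(gate = names(masks),
                           n = purrr::map_int(masks, sum))
  structure(c(masks, list(counts = counts)), class = "gate_chain")
}

#' @export
print.gate_chain <- function(x, ...) {
  cat("<gate_chain>\n")
  print(x$counts)
  invisible(x)
}

#' Gate transfected (mRuby-positive) cells against a control population
#'
#' The mRuby threshold is the `q`-th percentile of the control population's
#' mRuby signal among its viable singlets (the control being untransfected
#' or empty-vector cells); sample events above the threshold, within the
#' singlet gate, are mRuby-positive.
#'
#' @param events Sample event tibble.
#' @param gates `gate_chain` for `events` from [gate_viable_singlets()].
#' @param control_events Control event tibble (required).
#' @param control_gates Optional `gate_chain` for the control (estimated
#'   with default parameters when missing).
#' @param q Percentile of the control distribution used as threshold.
#' @return The `gate_chain` extended with an `mruby_pos` mask.
#' @export
gate_mruby <- function(events, gates, control_events, control_gates = NULL,
                       q = 99.9) {
  if (missing(control_events) || is.null(control_events)) {
    abort("A control event table is required to set the mRuby threshold.")
  }
  control_gates <- control_gates %||% gate_viable_singlets(control_events)
  thr <- quantile(control_events$mruby[control_gates$singlet], q / 100,
                  names = FALSE, type = 7)
  mruby_pos <- gates$singlet & events$mruby > thr
  out <- new_gate_chain(gates$qc_pass, gates$viable, gates$singlet,
                        mruby_pos)
  attr(out, "mruby_threshold") <- thr
  out
}

#' Median fluorescence intensity of a gated subpopulation
#'
#' @param events Event tibble with an `egfp` column.
#' @param mask Logical mask selecting the subpopulation (e.g. the
#'   `mruby_pos` gate).
#' @param channel Column to summarize (default `"egfp"`).
#' @return The median intensity; `NA` with a warning and attribute
#'   `undefined = TRUE` when the mask selects no event.
#' @export
egfp_mfi <- function(events, mask, channel = "egfp") {
  stopifnot(length(mask) == nrow(events))
  if (!any(mask)) {
    warn("Empty gate: MFI undefined.")
    return(structure(NA_real_, undefined = TRUE))
  }
  median(events[[channel]][mask])
}

#' Empty-vector-normalized fold activity with replicate statistics
#'
#' Converts per-replicate MFIs into fold activity relative to a reference
#' construct (the empty vector): each replicate's fold is its MFI divided by
#' the mean reference MFI of the same batch (or the global reference mean
#' when no `batch` column is present), so the reference's mean fold is 1 by
#' construction. Per construct the mean fold, SEM, and a two-tailed Welch
#' t-test of its folds against the reference folds are reported, with
#' significance tiers ns/*/**/***/**** at 0.05/0.01/0.001/0.0001.
#'
#' @param mfis Tibble with columns `construct`, `mfi`, optionally `batch`
#'   and `timepoint`.
#' @param reference Name of the reference construct (present with >= 1
#'   replicate, all MFIs > 0).
#' @return A tibble per construct: `construct`, `n`, `mean_fold`, `sem_fold`,
#'   `p_value`, `tier`, plus a `folds` list-column of the per-replicate
#'   folds.
#' @examples
#' mfis <- tibble::tibble(
#'   construct = rep(c("empty_vector", "CVB3"), each = 3),
#'   mfi = c(100, 110, 95, 1300, 1250, 1400))
#' fold_activity(mfis, reference = "empty_vector")
#' @export
fold_activity <- function(mfis, reference = "empty_vector") {
  if (!reference %in% mfis$construct) {
    abort(sprintf("Reference construct '%s' not found.", reference))
  }
  if (!"batch" %in% names(mfis)) mfis$batch <- "all"
  ref_means <- mfis |>
    dplyr::filter(.data$construct == reference) |>
    dplyr::group_by(.data$batch) |>
    dplyr::summarise(ref_mean = mean(.data$mfi), .groups = "drop")
  if (any(ref_means$ref_mean <= 0)) {
    abort("Reference MFIs must be positive.")
  }
  folds <- mfis |>
    dplyr::inner_join(ref_means, by = "batch") |>
    dplyr::mutate(fold = .data$mfi / .data$ref_mean)
  ref_folds <- folds$fold[folds$construct == reference]
  folds |>
    dplyr::group_by(.data$construct) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fold = mean(.data$fold),
      sem_fold = sd(.data$fold) / sqrt(dplyr::n()),
      p_value = welch_p(.data$fold, ref_folds),
      folds = list(.data$fold),
      .groups = "drop"
    ) |>
    dplyr::mutate(tier = p_to_tier(.data$p_value)) |>
    dplyr::relocate("tier", .after = "p_value")
}

# Two-tailed Welch t-test p-value; NA when either side lacks replication
# or has zero variance on both sides (identical samples give p = 1).
welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (isTRUE(all.equal(x, y))) return(1)
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  t.test(x, y, var.equal = FALSE)$p.value
}
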