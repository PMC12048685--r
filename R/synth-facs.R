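#' Simulate cytometry events for the circRNA reporter assay
#'
#' Draws a mixed population of events mimicking what a cytometer records from
#' a transiently transfected well: intact single cells, low-scatter debris,
#' doublets (conserved total signal, so FSC-A is about twice FSC-H), and —
#' among the viable singlets — a transfected subpopulation with high mRuby
#' (transfection control) whose EGFP readout is scaled by `activity_fold`
#' relative to the empty-vector baseline. The median of the transfected EGFP
#' distribution equals `egfp_baseline * activity_fold` by construction, so
#' the generator has a closed-form planted MFI.
#'
#' Events are emitted in acquisition order with a time stamp; events inside
#' `clog_window` (an index interval) are flagged anomalous and their
#' acquisition rate is multiplied by `clog_rate_factor` to emulate a
#' flow-cell clog.
#'
#' @param n_events Number of events to draw (>= 1).
#' @param debris_fraction,doublet_fraction Proportions of debris among all
#'   events and of doublets among non-debris events, each in `[0, 1]`.
#' @param transfected_fraction Proportion of viable singlets that are
#'   transfected (mRuby-high), in `[0, 1]`.
#' @param activity_fold EGFP multiplier of the construct relative to the
#'   empty vector (> 0); the empty vector itself is `activity_fold = 1`.
#' @param egfp_baseline Median EGFP of transfected empty-vector cells.
#' @param egfp_sdlog Log-normal spread of EGFP; `0` gives noiseless EGFP at
#'   the planted median.
#' @param clog_window Optional `c(first, last)` event-index interval flagged
#'   anomalous.
#' @param clog_rate_factor Event-rate multiplier inside the clog window.
#' @param mean_rate Nominal acquisition rate (events/s).
#' @param seed Integer seed; identical seeds give identical tables.
#'
#' @return A list with `events` — a tibble of `acq_index`, `time_s`, `fsc_a`,
#'   `fsc_h`, `ssc_a`, `mruby`, `egfp`, `anomaly` — and `truth`, the
#'   parameters plus the per-event `category` factor
#'   (debris/doublet/untransfected/transfected).
#' @examples
#' sim <- simulate_facs_events(2000, activity_fold = 4, seed = 1)
#' table(sim$truth$category)
#' @export
simulate_facs_events <- function(n_events = 20000,
                                 debris_fraction = 0.05,
                                 doublet_fraction = 0.05,
                                 transfected_fraction = 0.3,
                                 activity_fold = 1,
                                 egfp_baseline = 500,
                                 egfp_sdlog = 0.4,
                                 clog_window = NULL,
                                 clog_rate_factor = 10,
                                 mean_rate = 1000,
                                 seed = NULL) {
  if (n_events < 1) abort("`n_events` must be >= 1.")
  fr <- c(debris_fraction, doublet_fraction, transfected_fraction)
  if (any(fr < 0 | fr > 1)) abort("All fractions must lie in [0, 1].")
  if (activity_fold <= 0) abort("`activity_fold` must be positive.")

  with_seed(seed, {
    n <- as.integer(n_events)
    is_debris <- runif(n) < debris_fraction
    is_doublet <- !is_debris & runif(n) < doublet_fraction
    is_single <- !is_debris & !is_doublet
    is_transf <- is_single & runif(n) < transfected_fraction
    category <- factor(
      dplyr::case_when(
        is_debris ~ "debris",
        is_doublet ~ "doublet",
        is_transf ~ "transfected",
        TRUE ~ "untransfected"
      ),
      levels = c("debris", "doublet", "untransfected", "transfected")
    )

    # Scatter model: cells log-normal around 5e4 FSC with FSC-H ~ FSC-A;
    # doublets carry twice the area at single-cell height; debris sits an
    # order of magnitude lower on both scatter axes.
    fsc_h <- rlnorm(n, log(5e4), 0.2)
    ratio_noise <- rnorm(n, 0, 0.02)
    fsc_a <- fsc_h * (1 + ratio_noise)
    fsc_a[is_doublet] <- 2 * fsc_h[is_doublet] * (1 + ratio_noise[is_doublet])
    ssc_a <- rlnorm(n, log(3e4), 0.3)
    fsc_a[is_debris] <- rlnorm(sum(is_debris), log(3e3), 0.4)
    fsc_h[is_debris] <- fsc_a[is_debris] * (1 + rnorm(sum(is_debris), 0, 0.05))
    ssc_a[is_debris] <- rlnorm(sum(is_debris), log(2e3), 0.4)

    mruby <- rlnorm(n, log(100), 0.3)
    mruby[is_transf] <- rlnorm(sum(is_transf), log(1e4), 0.4)
    egfp <- rlnorm(n, log(50), 0.3)
    egfp[is_transf] <- egfp_baseline * activity_fold *
      rlnorm(sum(is_transf), 0, egfp_sdlog)

    dt <- rep(1 / mean_rate, n)
    anomaly <- rep(FALSE, n)
    if (!is.null(clog_window)) {
      stopifnot(length(clog_window) == 2, clog_window[1] >= 1,
                clog_window[2] <= n, clog_window[1] <= clog_window[2])
      idx <- clog_window[1]:clog_window[2]
      anomaly[idx] <- TRUE
      dt[idx] <- dt[idx] / clog_rate_factor
    }

    events <- tibble::tibble(
      acq_index = seq_len(n),
      time_s = cumsum(dt),
      fsc_a = fsc_a, fsc_h = fsc_h, ssc_a = ssc_a,
      mruby = mruby, egfp = egfp,
      anomaly = anomaly
    )
    truth <- list(
      n_events = n, debris_fraction = debris_fraction,
      doublet_fraction = doublet_fraction,
      transfected_fraction = transfected_fraction,
      activity_fold = activity_fold, egfp_baseline = egfp_baseline,
      egfp_sdlog = egfp_sdlog, clog_window = clog_window, seed = seed,
      category = category
    )
    list(events = events, truth = truth)
  })
}
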