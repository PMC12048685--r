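#' Describe the ground truth behind a simulated qPCR experiment
#'
#' Collects the template abundances and the amplification/degradation model
#' from which [simulate_ct_table()] emits quantification cycles. The Ct model
#' is `Ct = 20 - log(quantity) / log(efficiency)` with quantity in picograms,
#' i.e. the baseline is anchored so that 1 pg yields Ct 20 at efficiency 2;
#' Gaussian cycle noise of SD `ct_noise_sd` is added on top. RNase R
#' treatment divides linear templates (including the reference and the
#' spike-in) by `rnaser_linear_decay` and circular templates by
#' `rnaser_circ_decay` — circles resist the exonuclease, so their decay is
#' typically 1. No-RT controls retain a `no_rt_leak` fraction of the template
#' (residual DNA signal).
#'
#' @param true_quantities Named numeric vector of template quantities (pg)
#'   per amplicon; all positive.
#' @param amplicon_class Named character vector classifying each amplicon as
#'   `"linear"`, `"circular"`, or `"spike"`.
#' @param efficiency Per-cycle amplification factor in `(1, 2]`.
#' @param ct_noise_sd Cycle noise SD; `0` gives exact closed-form Cts.
#' @param rnaser_linear_decay,rnaser_circ_decay Fold depletion (>= 1) under
#'   RNase R for linear and circular templates.
#' @param gradient_weights Named list: per amplicon, a nonnegative,
#'   not-all-zero vector of relative abundances over gradient fractions.
#' @param spike_quantity Quantity (pg) of the spike-in added to every
#'   fraction.
#' @param no_rt_leak Fraction of template surviving in no-RT controls.
#' @return A list of class `qpcr_truth`.
#' @export
qpcr_truth <- function(true_quantities,
                       amplicon_class = NULL,
                       efficiency = 2,
                       ct_noise_sd = 0,
                       rnaser_linear_decay = 16,
                       rnaser_circ_decay = 1,
                       gradient_weights = NULL,
                       spike_quantity = 0.1,
                       no_rt_leak = 1e-3) {
  stopifnot(is.numeric(true_quantities), !is.null(names(true_quantities)))
  if (any(true_quantities <= 0)) abort("All `true_quantities` must be > 0.")
  if (efficiency <= 1 || efficiency > 2) {
    abort("`efficiency` must lie in (1, 2].")
  }
  if (rnaser_linear_decay < 1 || rnaser_circ_decay < 1) {
    abort("RNase R decays must be >= 1.")
  }
  if (is.null(amplicon_class)) {
    amplicon_class <- setNames(rep("linear", length(true_quantities)),
                               names(true_quantities))
  }
  if (!is.null(gradient_weights)) {
    ok <- vapply(gradient_weights,
                 function(w) all(w >= 0) && any(w > 0), logical(1))
    if (!all(ok)) abort("Gradient weights must be nonnegative, not all zero.")
  }
  structure(list(true_quantities = true_quantities,
                 amplicon_class = amplicon_class,
                 efficiency = efficiency, ct_noise_sd = ct_noise_sd,
                 rnaser_linear_decay = rnaser_linear_decay,
                 rnaser_circ_decay = rnaser_circ_decay,
                 gradient_weights = gradient_weights,
                 spike_quantity = spike_quantity,
                 no_rt_leak = no_rt_leak),
            class = "qpcr_truth")
}

# Closed-form quantification cycle for a template quantity in pg.
ct_from_quantity <- function(quantity, efficiency) {
  ifelse(is.na(quantity) | quantity <= 0, NA_real_,
         20 - log(quantity) / log(efficiency))
}

#' Emit a long-format Ct table from planted template quantities
#'
#' Evaluates the Ct model of a [qpcr_truth()] over an assay design: one row
#' per well. The design names the sample, amplicon, treatment (`"none"`,
#' `"rnaser"`, or `"no_rt"`), gradient fraction (or `NA`), and replicate; an
#' optional `quantity` column (used by dilution-series designs) overrides the
#' truth's per-amplicon quantity. Gradient rows of non-spike amplicons get the
#' amplicon total multiplied by its normalized fraction weight; spike-in rows
#' get `spike_quantity` in every fraction. Zero or negative quantities emit a
#' missing Ct ("undetermined").
#'
#' @param truth A [qpcr_truth()].
#' @param design Tibble with columns `sample`, `amplicon`, `treatment`,
#'   `fraction`, `replicate` and optionally `quantity`.
#' @param seed Integer seed for cycle noise.
#' @return A list with `ct` — the design plus a `ct` column — and `truth`.
#' @examples
#' tr <- qpcr_truth(c(circ = 0.2, lin = 1, Nupl1 = 4),
#'                  amplicon_class = c(circ = "circular", lin = "linear",
#'                                     Nupl1 = "linear"))
#' des <- ct_design("s1", c("circ", "lin", "Nupl1"),
#'                  treatments = c("none", "rnaser"), replicates = 2)
#' sim <- simulate_ct_table(tr, des, seed = 1)
#' head(sim$ct)
#' @export
simulate_ct_table <- function(truth, design, seed = NULL) {
  stopifnot(inherits(truth, "qpcr_truth"))
  req <- c("sample", "amplicon", "treatment", "fraction", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    abort(paste("Design lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!all(design$treatment %in% c("none", "rnaser", "no_rt"))) {
    abort("Treatments must be one of 'none', 'rnaser', 'no_rt'.")
  }

  q <- if ("quantity" %in% names(design)) design$quantity else rep(NA_real_, nrow(design))
  base_q <- unname(truth$true_quantities[design$amplicon])
  q <- ifelse(is.na(q), base_q, q)
  cls <- unname(truth$amplicon_class[design$amplicon])

  # Gradient rows: split the amplicon total over fractions by its
  # normalized weights; the spike-in is constant per fraction.
  gi <- !is.na(design$fraction)
  if (any(gi)) {
    wts <- function(a, f) {
      w <- truth$gradient_weights[[a]]
      if (is.null(w)) return(NA_real_)
      w[f] / sum(w)
    }
    q[gi] <- ifelse(
      cls[gi] == "spike",
      truth$spike_quantity,
      q[gi] * mapply(wts, design$amplicon[gi], design$fraction[gi])
    )
  }

  decay <- dplyr::case_when(
    design$treatment != "rnaser" ~ 1,
    cls == "circular" ~ truth$rnaser_circ_decay,
    TRUE ~ truth$rnaser_linear_decay
  )
  q <- q / decay
  q <- ifelse(design$treatment == "no_rt", q * truth$no_rt_leak, q)

  ct <- with_seed(seed, {
    ct_from_quantity(q, truth$efficiency) +
      if (truth$ct_noise_sd > 0) rnorm(length(q), 0, truth$ct_noise_sd) else 0
  })
  out <- tibble::as_tibble(design)
  out$ct <- ct
  list(ct = out, truth = truth)
}

#' Build a factorial qPCR assay design
#'
#' @param samples,amplicons,treatments,replicates Levels crossed into one row
#'   per well; `fractions` is `NA` for non-gradient assays or an integer
#'   vector of gradient fraction indices.
#' @param fractions Gradient fractions (default none).
#' @return A design tibble for [simulate_ct_table()].
#' @export
ct_design <- function(samples, amplicons, treatments = "none",
                      replicates = 3, fractions = NA_integer_) {
  tidyr::expand_grid(sample = samples, amplicon = amplicons,
                     treatment = treatments, fraction = fractions,
                     replicate = seq_len(replicates))
}

#' Build a tenfold serial-dilution design for a standard curve
#'
#' Defaults to the five-point range from 1 pg down to 0.1 fg (1e-4 pg) in
#' tenfold steps.
#'
#' @param amplicon Amplicon name.
#' @param quantities Template quantities in pg, one per dilution.
#' @param replicates Wells per dilution.
#' @return A design tibble with a `quantity` column.
#' @export
ct_design_dilution <- function(amplicon, quantities = 10^seq(0, -4),
                               replicates = 1) {
  tidyr::expand_grid(quantity = quantities,
                     replicate = seq_len(replicates)) |>
    dplyr::mutate(sample = sprintf("dilution_%g_pg", .data$quantity),
                  amplicon = amplicon, treatment = "none",
                  fraction = NA_integer_) |>
    dplyr::select("sample", "amplicon", "treatment", "fraction",
                  "replicate", "quantity")
}
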