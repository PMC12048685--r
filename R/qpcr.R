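#' Relative quantity from a delta-Ct
#'
#' The standard exponential transform: `2^-(ct - ref_ct)`, the relative
#' template level of an amplicon against a reference (e.g. the housekeeping
#' mRNA Nupl1) at efficiency 2. Vectorized; a missing Ct ("undetermined")
#' propagates to a missing result.
#'
#' @param ct,ref_ct Quantification cycles.
#' @return Relative level(s), `2^-(ct - ref_ct)`.
#' @examples
#' rel_quantity(21, 20) # half the reference
#' @export
rel_quantity <- function(ct, ref_ct) 2^(-(ct - ref_ct))

# Replicate aggregation convention: arithmetic mean of Cts, i.e. the
# geometric mean of linear levels.
mean_ct <- function(ct) mean(ct, na.rm = TRUE)

#' RNase R circular/linear enrichment per construct
#'
#' For each sample (construct), amplicon levels are first normalized to the
#' reference amplicon within each treatment arm via [rel_quantity()]
#' (replicate Cts are arithmetically averaged, i.e. linear levels are
#' geometrically averaged). Each amplicon's enrichment is its normalized
#' level after RNase R digestion over its level in the undigested control;
#' because linear RNA is depleted by the exonuclease while circles resist
#' it, circular amplicons enrich. The circ/linear ratio — circRNA enrichment
#' over linear enrichment — is the per-construct readout and equals, in the
#' noiseless generative model, the linear decay over the circular decay
#' (the reference's own decay cancels).
#'
#' @param ct_table Long-format Ct tibble (`sample`, `amplicon`, `treatment`
#'   in `"none"`/`"rnaser"`, `replicate`, `ct`).
#' @param circ_amplicons,linear_amplicons Character vectors of amplicon
#'   names per class.
#' @param ref_amplicon Reference amplicon name (a linear housekeeping
#'   transcript).
#' @return A tibble per sample: `circ_enrichment`, `linear_enrichment`,
#'   `circ_linear_ratio`. Samples missing a +/- RNase R pair are skipped
#'   with a warning.
#' @export
rnaser_enrichment <- function(ct_table, circ_amplicons, linear_amplicons,
                              ref_amplicon) {
  cls <- function(a) dplyr::case_when(
    a %in% circ_amplicons ~ "circular",
    a %in% linear_amplicons ~ "linear",
    a == ref_amplicon ~ "reference",
    TRUE ~ NA_character_
  )
  tbl <- ct_table |>
    dplyr::filter(.data$treatment %in% c("none", "rnaser")) |>
    dplyr::mutate(class = cls(.data$amplicon)) |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::group_by(.data$sample, .data$treatment, .data$amplicon,
                    .data$class) |>
    dplyr::summarise(ct = mean_ct(.data$ct), .groups = "drop")

  ref <- tbl |>
    dplyr::filter(.data$class == "reference") |>
    dplyr::select("sample", "treatment", ref_ct = "ct")
  lev <- tbl |>
    dplyr::filter(.data$class != "reference") |>
    dplyr::inner_join(ref, by = c("sample", "treatment")) |>
    dplyr::mutate(level = rel_quantity(.data$ct, .data$ref_ct)) |>
    dplyr::select("sample", "amplicon", "class", "treatment", "level") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "level")

  if (!all(c("none", "rnaser") %in% names(lev))) {
    abort("Both untreated and RNase R-treated measurements are required.")
  }
  complete <- !is.na(lev$none) & !is.na(lev$rnaser)
  if (any(!complete)) {
    warn("Constructs lacking a +/- RNase R pair were skipped.")
    lev <- lev[complete, , drop = FALSE]
  }
  out <- lev |>
    dplyr::mutate(enrichment = .data$rnaser / .data$none) |>
    dplyr::group_by(.data$sample, .data$class) |>
    dplyr::summarise(enrichment = exp(mean(log(.data$enrichment))),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "class", values_from = "enrichment")
  for (cls_col in c("circular", "linear")) {
    if (!cls_col %in% names(out)) out[[cls_col]] <- NA_real_
  }
  out |>
    dplyr::rename(circ_enrichment = "circular",
                  linear_enrichment = "linear") |>
    dplyr::mutate(circ_linear_ratio =
                    .data$circ_enrichment / .data$linear_enrichment)
}

#' Delta-Ct of samples against their no-RT controls
#'
#' Reports, per sample and amplicon, `Ct(no-RT) - Ct(sample)` averaged over
#' paired replicates, with SD — the number of cycles by which genuine cDNA
#' signal precedes the residual-DNA background. An undetermined no-RT Ct is
#' replaced by the `max_cycle` ceiling and the row flagged.
#'
#' @param ct_table Long-format Ct tibble containing `treatment` values
#'   `"none"` (the samples) and `"no_rt"`.
#' @param max_cycle Ceiling substituted for undetermined no-RT Cts.
#' @return A tibble per sample and amplicon: `mean_delta_ct`, `sd_delta_ct`,
#'   `n`, `ceiling_used`.
#' @export
no_rt_delta <- function(ct_table, max_cycle = 40) {
  wide <- ct_table |>
    dplyr::filter(.data$treatment %in% c("none", "no_rt")) |>
    dplyr::select("sample", "amplicon", "treatment", "replicate", "ct") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "ct")
  if (!"no_rt" %in% names(wide)) abort("No matched no-RT rows found.")
  wide |>
    dplyr::mutate(ceiling_used = is.na(.data$no_rt),
                  no_rt = dplyr::coalesce(.data$no_rt, max_cycle),
                  delta_ct = .data$no_rt - .data$none) |>
    dplyr::group_by(.data$sample, .data$amplicon) |>
    dplyr::summarise(mean_delta_ct = mean(.data$delta_ct),
                     sd_delta_ct = sd(.data$delta_ct),
                     n = dplyr::n(),
                     ceiling_used = any(.data$ceiling_used),
                     .groups = "drop")
}

#' Fit a serial-dilution standard curve
#'
#' Least-squares line of Ct against `log10(quantity)` over a dilution
#' series (canonically tenfold steps from 1 pg to 0.1 fg). The amplification
#' efficiency is `10^(-1/slope)`; a warning is raised when it falls outside
#' the conventional `[1.8, 2.1]` acceptance band.
#'
#' @param dilution_cts Tibble with `quantity` (> 0) and `ct` columns; at
#'   least three distinct quantities.
#' @param amplicon Optional amplicon label stored on the fit.
#' @return An object of class `standard_curve` with elements `slope`
#'   (cycles per decade), `intercept` (Ct at 1 unit), `efficiency`,
#'   `r_squared`, `quantity_range`, `fit` (the underlying `lm`). Supports
#'   [tidy()], [glance()], [ggplot2::autoplot()], and [absolute_quantify()].
#' @examples
#' d <- tibble::tibble(quantity = 10^(0:-4), ct = 20 - log2(10^(0:-4)))
#' fit_standard_curve(d)
#' @export
fit_standard_curve <- function(dilution_cts, amplicon = NA_character_) {
  ok <- !is.na(dilution_cts$ct)
  d <- dilution_cts[ok, , drop = FALSE]
  if (any(d$quantity <= 0)) abort("Dilution quantities must be positive.")
  if (length(unique(d$quantity)) < 3) {
    abort("At least three distinct dilution points are required.")
  }
  fit <- lm(ct ~ log10(quantity), data = d)
  ss_tot <- sum((d$ct - mean(d$ct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("Standard curve slope must be negative.")
  eff <- 10^(-1 / slope)
  if (eff < 1.8 || eff > 2.1) {
    warn(sprintf("Amplification efficiency %.3f outside [1.8, 2.1].", eff))
  }
  structure(list(amplicon = amplicon,
                 slope = slope,
                 intercept = unname(coef(fit)[1]),
                 efficiency = eff,
                 r_squared = r2,
                 quantity_range = range(d$quantity),
                 fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve>%s slope %.4f cycles/decade, efficiency %.3f, r2 %.4f\n",
    if (is.na(x$amplicon)) "" else paste0(" ", x$amplicon, ":"),
    x$slope, x$efficiency, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(amplicon = x$amplicon, slope = x$slope,
                 intercept = x$intercept, efficiency = x$efficiency,
                 r_squared = x$r_squared,
                 quantity_min = x$quantity_range[1],
                 quantity_max = x$quantity_range[2])
}

#' Absolute quantification from a standard curve
#'
#' Inverts the fitted dilution line: `quantity = 10^((ct - intercept) /
#' slope)`. Cts outside the fitted dilution range are still converted but
#' flagged as extrapolated.
#'
#' @param ct Quantification cycle(s); missing Cts give missing quantities.
#' @param curve A [fit_standard_curve()] object.
#' @return A tibble: `ct`, `quantity`, `extrapolated`.
#' @export
absolute_quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  quantity <- 10^((ct - curve$intercept) / curve$slope)
  tibble::tibble(
    ct = ct,
    quantity = quantity,
    extrapolated = !is.na(quantity) &
      (quantity < curve$quantity_range[1] |
         quantity > curve$quantity_range[2])
  )
}

#' Spike-in-normalized polysome gradient distribution
#'
#' For each amplicon, the Ct in each gradient fraction is first normalized
#' to the spike-in Ct of the same fraction (correcting per-fraction RNA
#' recovery), converted from the log2 cycle scale to linear levels, and
#' normalized to the amplicon's total across all fractions — the fraction-
#' of-total distribution. Fractions are then aggregated into gradient
#' portions (free, 40S/60S, 80S, light polysome, heavy polysome) and the
#' peak portion reported.
#'
#' @param ct_table Long-format Ct tibble with `amplicon`, `fraction`,
#'   `replicate`, `ct`, covering the spike amplicon in every fraction.
#' @param spike_amplicon Name of the spike-in amplicon.
#' @param portion_map Named list mapping portion label to the integer
#'   fraction indices it spans; portions must partition the fractions.
#' @return A list of class `gradient_profile`: `distribution` (tibble per
#'   amplicon and fraction: `rel_abundance`, `portion`), `portions` (per
#'   amplicon and portion totals), `peak` (per amplicon peak portion).
#' @export
polysome_distribution <- function(ct_table, spike_amplicon = "spike",
                                  portion_map = NULL) {
  tbl <- ct_table |>
    dplyr::filter(!is.na(.data$fraction)) |>
    dplyr::group_by(.data$amplicon, .data$fraction) |>
    dplyr::summarise(ct = mean_ct(.data$ct), .groups = "drop")
  spike <- tbl |>
    dplyr::filter(.data$amplicon == spike_amplicon) |>
    dplyr::select("fraction", spike_ct = "ct")
  if (nrow(spike) == 0) abort("Spike-in amplicon not found in any fraction.")

  dist <- tbl |>
    dplyr::filter(.data$amplicon != spike_amplicon) |>
    dplyr::left_join(spike, by = "fraction")
  bad <- dist |>
    dplyr::group_by(.data$amplicon) |>
    dplyr::summarise(bad = any(is.na(.data$spike_ct)), .groups = "drop")
  if (any(bad$bad)) {
    abort(sprintf("Missing spike-in Ct for fraction(s) of: %s",
                  paste(bad$amplicon[bad$bad], collapse = ", ")))
  }
  dist <- dist |>
    dplyr::mutate(level = rel_quantity(.data$ct, .data$spike_ct)) |>
    dplyr::group_by(.data$amplicon) |>
    dplyr::mutate(rel_abundance = .data$level / sum(.data$level)) |>
    dplyr::ungroup() |>
    dplyr::select("amplicon", "fraction", "rel_abundance")

  fractions <- sort(unique(dist$fraction))
  portion_map <- portion_map %||% default_portion_map(length(fractions))
  assign_tbl <- tibble::tibble(
    portion = rep(names(portion_map), lengths(portion_map)),
    fraction = unlist(portion_map, use.names = FALSE)
  )
  if (anyDuplicated(assign_tbl$fraction) ||
      !setequal(assign_tbl$fraction, fractions)) {
    abort("`portion_map` must partition the gradient fractions.")
  }
  dist <- dist |>
    dplyr::left_join(assign_tbl, by = "fraction") |>
    dplyr::mutate(portion = factor(.data$portion,
                                   levels = names(portion_map)))
  portions <- dist |>
    dplyr::group_by(.data$amplicon, .data$portion) |>
    dplyr::summarise(total = sum(.data$rel_abundance), .groups = "drop")
  peak <- portions |>
    dplyr::group_by(.data$amplicon) |>
    dplyr::slice_max(.data$total, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("amplicon", peak_portion = "portion")
  structure(list(distribution = dist, portions = portions, peak = peak),
            class = "gradient_profile")
}

# Five canonical gradient portions spread over the available fractions.
default_portion_map <- function(n_fractions) {
  labels <- c("free", "40S/60S", "80S", "light polysome", "heavy polysome")
  idx <- split(seq_len(n_fractions),
               cut(seq_len(n_fractions), breaks = 5, labels = FALSE))
  setNames(idx, labels)
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat("<gradient_profile>\n")
  print(x$peak)
  invisible(x)
}

#' Luciferase reporter activity, optionally mRNA-normalized
#'
#' Computes the Nluc/Fluc ratio per construct, optionally divided by a
#' relative mRNA level (e.g. reporter mRNA over a housekeeping transcript)
#' so that activity reflects translation rather than transcript abundance,
#' then rescales so the reference construct's mean activity is 1.
#'
#' @param data Tibble with `construct`, `nluc`, `fluc` (> 0), and optionally
#'   `mrna_ratio` (> 0).
#' @param reference Reference construct scaled to 1.
#' @return The input with `activity` (raw ratio) and `relative_activity`
#'   (reference-scaled) columns.
#' @export
reporter_activity <- function(data, reference) {
  if (any(data$fluc <= 0)) abort("`fluc` must be positive.")
  act <- data$nluc / data$fluc
  if ("mrna_ratio" %in% names(data)) {
    if (any(data$mrna_ratio <= 0)) abort("`mrna_ratio` must be positive.")
    act <- act / data$mrna_ratio
  }
  out <- dplyr::mutate(data, activity = act)
  if (!reference %in% data$construct) {
    abort(sprintf("Reference construct '%s' not found.", reference))
  }
  ref_mean <- mean(out$activity[out$construct == reference])
  dplyr::mutate(out, relative_activity = .data$activity / ref_mean)
}
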