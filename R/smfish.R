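#' Construct a registered multi-channel image stack
#'
#' Bundles the per-probe channel images of one smFISH field of view. All
#' channels must share dimensions and contain finite, nonnegative
#' intensities. Channel roles follow the assay: `cds` (CDS probe), `ires`
#' (IRES probe), `neg` (negative-control probes), `nuc` (nuclear stain).
#'
#' @param cds,ires,neg,nuc Numeric matrices (only `cds` is required).
#' @param pixel_size Optional pixel size in micrometers.
#' @param region,embryo Optional labels (e.g. `"somites 20-28"`).
#' @return An `image_stack`: a named list of matrices with metadata
#'   attributes.
#' @export
image_stack <- function(cds, ires = NULL, neg = NULL, nuc = NULL,
                        pixel_size = NULL, region = NA_character_,
                        embryo = NA_character_) {
  channels <- purrr::compact(list(cds = cds, ires = ires, neg = neg,
                                  nuc = nuc))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch)) {
      abort(sprintf("Channel '%s' must be a numeric matrix.", nm))
    }
    if (any(!is.finite(ch)) || any(ch < 0)) {
      abort(sprintf("Channel '%s' must be finite and nonnegative.", nm))
    }
  }
  dims <- unique(purrr::map(channels, dim))
  if (length(dims) != 1) abort("All channels must share dimensions.")
  structure(channels, class = "image_stack", pixel_size = pixel_size,
            region = region, embryo = embryo)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<image_stack> %d x %d px; channels: %s\n", d[1], d[2],
              paste(names(x), collapse = ", ")))
  if (!is.na(attr(x, "region"))) cat("  region:", attr(x, "region"), "\n")
  if (!is.na(attr(x, "embryo"))) cat("  embryo:", attr(x, "embryo"), "\n")
  invisible(x)
}

#' Detect single-molecule puncta by local median/MAD thresholding
#'
#' Calls fluorescence puncta on one channel: a pixel is foreground when its
#' intensity exceeds the local median by more than `k` times the local
#' median absolute deviation, both computed over a centered square window
#' (clipped at the image border). Foreground pixels are grouped into
#' 8-connected components; components whose area falls inside
#' `[min_area, max_area]` are returned as spots with an intensity-weighted
#' centroid and the integrated background-subtracted intensity. The
#' procedure is fully deterministic.
#'
#' @param image An [image_stack()] or a plain numeric matrix.
#' @param channel Channel role to analyze when `image` is a stack.
#' @param window Odd window side length (px), >= 3 and no larger than the
#'   image.
#' @param k Threshold in local-MAD units above the local median.
#' @param min_area,max_area Area bounds (px) for accepted components; blobs
#'   above `max_area` (e.g. merged spots) are rejected.
#' @return A tibble with one row per spot: `spot_id`, `row`, `col`
#'   (0-based centroid), `area_px`, `intensity`, and `mask`, a list-column of
#'   two-column integer matrices of 0-based pixel coordinates.
#' @examples
#' img <- matrix(100, 32, 32)
#' img[8:10, 8:10] <- 400
#' detect_spots(img, window = 9)
#' @export
detect_spots <- function(image, channel = "cds", window = 15, k = 5,
                         min_area = 2, max_area = 200) {
  img <- if (inherits(image, "image_stack")) {
    if (!channel %in% names(image)) {
      abort(sprintf("Channel '%s' not present in the stack.", channel))
    }
    image[[channel]]
  } else {
    stopifnot(is.matrix(image), is.numeric(image))
    image
  }
  if (window < 3 || window %% 2 == 0) {
    abort("`window` must be odd and >= 3.")
  }
  if (window > nrow(img) || window > ncol(img)) {
    abort("`window` must not exceed the image dimensions.")
  }
  if (min_area < 1) abort("`min_area` must be >= 1.")

  stats <- .local_median_mad(img, as.integer(window))
  fg <- img > stats$median + k * stats$mad
  labels <- .label_components(fg)
  n_comp <- max(labels)
  if (n_comp == 0) return(empty_spots(channel))

  excess <- img - stats$median
  comps <- purrr::map(seq_len(n_comp), function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    area <- nrow(px)
    if (area < min_area || area > max_area) return(NULL)
    w <- excess[px]
    list(area = area,
         row = sum((px[, 1] - 1) * w) / sum(w),
         col = sum((px[, 2] - 1) * w) / sum(w),
         intensity = sum(w),
         mask = cbind(row = px[, 1] - 1L, col = px[, 2] - 1L))
  })
  comps <- purrr::compact(comps)
  if (length(comps) == 0) return(empty_spots(channel))
  tibble::tibble(
    channel = channel,
    spot_id = seq_along(comps),
    row = purrr::map_dbl(comps, "row"),
    col = purrr::map_dbl(comps, "col"),
    area_px = purrr::map_int(comps, "area"),
    intensity = purrr::map_dbl(comps, "intensity"),
    mask = purrr::map(comps, "mask")
  )
}

empty_spots <- function(channel) {
  tibble::tibble(channel = character(), spot_id = integer(),
                 row = double(), col = double(), area_px = integer(),
                 intensity = double(), mask = list())
}

# Collapse a list-column of pixel-coordinate matrices into a set of
# integer keys; rows/cols are far below 2^15 so the key is exact.
mask_keys <- function(mask) mask[, 1] * 2^15 + mask[, 2]

#' Classify CDS puncta into long/short 5' UTR isoforms by colocalization
#'
#' A CDS-probe punctum whose pixel mask shares at least `min_overlap_px`
#' pixels with the union of IRES-probe masks is called a long 5' UTR isoform
#' molecule; otherwise it is a short-isoform molecule. Each CDS punctum is
#' counted once no matter how many IRES puncta it touches; IRES puncta
#' touching no CDS punctum are tallied separately as a quality-control
#' channel (IRES-only signal is not expected at biologically relevant
#' levels).
#'
#' @param cds_spots,ires_spots Spot tibbles from [detect_spots()] on the same
#'   image.
#' @param min_overlap_px Minimum shared pixels to call an overlap.
#' @param embryo,region Optional labels stored on the output row.
#' @return A one-row tibble: `embryo`, `region`, `n_colocalized`,
#'   `n_cds_only`, `n_ires_only`, `n_cds_total`, `n_ires_total`. The per-spot
#'   long/short calls are attached as attribute `"cds_long"`.
#' @export
classify_colocalization <- function(cds_spots, ires_spots,
                                    min_overlap_px = 1,
                                    embryo = NA_character_,
                                    region = NA_character_) {
  ires_union <- if (nrow(ires_spots) > 0) {
    unique(unlist(purrr::map(ires_spots$mask, mask_keys)))
  } else {
    numeric(0)
  }
  cds_union <- if (nrow(cds_spots) > 0) {
    unique(unlist(purrr::map(cds_spots$mask, mask_keys)))
  } else {
    numeric(0)
  }
  cds_long <- purrr::map_lgl(cds_spots$mask, function(m) {
    sum(mask_keys(m) %in% ires_union) >= min_overlap_px
  })
  ires_orphan <- purrr::map_lgl(ires_spots$mask, function(m) {
    sum(mask_keys(m) %in% cds_union) < min_overlap_px
  })
  out <- tibble::tibble(
    embryo = embryo, region = region,
    n_colocalized = sum(cds_long),
    n_cds_only = sum(!cds_long),
    n_ires_only = sum(ires_orphan),
    n_cds_total = nrow(cds_spots),
    n_ires_total = nrow(ires_spots)
  )
  attr(out, "cds_long") <- cds_long
  out
}

#' Per-image isoform call table from an image stack
#'
#' Runs [detect_spots()] on the CDS and IRES channels of a stack and
#' classifies colocalization, carrying the stack's embryo/region labels.
#'
#' @param stack An [image_stack()] with `cds` and `ires` channels.
#' @param ... Detection parameters passed to [detect_spots()].
#' @param min_overlap_px Passed to [classify_colocalization()].
#' @return The one-row tibble of [classify_colocalization()].
#' @export
smfish_counts <- function(stack, ..., min_overlap_px = 1) {
  cds <- detect_spots(stack, "cds", ...)
  ires <- detect_spots(stack, "ires", ...)
  classify_colocalization(cds, ires, min_overlap_px = min_overlap_px,
                          embryo = attr(stack, "embryo"),
                          region = attr(stack, "region"))
}

#' Negative-control channel quality control
#'
#' Detects puncta on the negative-control channel with the same detector and
#' compares its spot density (spots per megapixel) with the CDS channel's.
#' The image fails QC when the density ratio exceeds `max_density_ratio`.
#'
#' @param stack An [image_stack()].
#' @param max_density_ratio Maximum tolerated NEG/CDS density ratio.
#' @param ... Detection parameters passed to [detect_spots()].
#' @return A one-row tibble: `neg_density`, `cds_density`, `ratio`,
#'   `verdict` (`"PASS"`, `"FAIL"`, or `"not assessed"` when the NEG channel
#'   is absent).
#' @export
negcontrol_qc <- function(stack, max_density_ratio = 0.1, ...) {
  if (!"neg" %in% names(stack)) {
    return(tibble::tibble(neg_density = NA_real_, cds_density = NA_real_,
                          ratio = NA_real_, verdict = "not assessed"))
  }
  mpx <- prod(dim(stack[[1]])) / 1e6
  neg_d <- nrow(detect_spots(stack, "neg", ...)) / mpx
  cds_d <- nrow(detect_spots(stack, "cds", ...)) / mpx
  ratio <- if (cds_d > 0) neg_d / cds_d else ifelse(neg_d > 0, Inf, 0)
  tibble::tibble(neg_density = neg_d, cds_density = cds_d, ratio = ratio,
                 verdict = ifelse(ratio <= max_density_ratio, "PASS", "FAIL"))
}

#' Pool per-image counts into per-embryo isoform proportions
#'
#' Puncta counts from all images of one embryo are pooled before the ratio
#' is taken: the long-isoform proportion is the summed colocalized count over
#' the summed CDS count. Embryos with zero CDS puncta have an undefined
#' proportion; they are flagged `excluded` and dropped from downstream
#' summaries with a warning.
#'
#' @param calls Tibble of per-image call rows (from [smfish_counts()] or
#'   [classify_colocalization()]) with `embryo` and `region` labels.
#' @return A tibble with one row per embryo: `embryo`, `region`, `n_long`,
#'   `n_short`, `long_proportion`, `excluded`.
#' @export
pool_isoforms <- function(calls) {
  out <- calls |>
    dplyr::group_by(.data$embryo, .data$region) |>
    dplyr::summarise(n_long = sum(.data$n_colocalized),
                     n_short = sum(.data$n_cds_only),
                     .groups = "drop") |>
    dplyr::mutate(
      excluded = .data$n_long + .data$n_short == 0,
      long_proportion = dplyr::if_else(
        .data$excluded, NA_real_,
        .data$n_long / (.data$n_long + .data$n_short))
    )
  if (any(out$excluded)) {
    warn(sprintf("%d embryo(s) had zero CDS puncta and were excluded.",
                 sum(out$excluded)))
  }
  out
}

#' Summarize long-isoform proportions across embryos per region
#'
#' @param embryos Per-embryo tibble from [pool_isoforms()].
#' @return A tibble per region: `mean_long_proportion`, `sd_long_proportion`,
#'   `n_embryos`.
#' @export
summarize_isoforms <- function(embryos) {
  embryos |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(mean_long_proportion = mean(.data$long_proportion),
                     sd_long_proportion = sd(.data$long_proportion),
                     n_embryos = dplyr::n(), .groups = "drop")
}

#' End-to-end isoform quantification of a simulated or loaded cohort
#'
#' Convenience wrapper: computes per-image call tables for every stack in a
#' cohort tibble (as produced by [simulate_smfish_cohort()]), pools per
#' embryo, and summarizes per region.
#'
#' @param cohort Tibble with a `stack` list-column of [image_stack()]s.
#' @param ... Detection parameters passed to [smfish_counts()].
#' @return A list: `calls` (per image), `embryos` (per embryo), `summary`
#'   (per region).
#' @export
quantify_isoforms <- function(cohort, ...) {
  calls <- purrr::map(cohort$stack, smfish_counts, ...) |>
    purrr::list_rbind()
  embryos <- pool_isoforms(calls)
  list(calls = calls, embryos = embryos,
       summary = summarize_isoforms(embryos))
}
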