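#' Simulate a two-channel smFISH image with planted isoform ground truth
#'
#' Generates a registered multi-channel single-molecule FISH image of
#' diffraction-limited puncta. The CDS-probe channel carries `n_spots`
#' isotropic Gaussian spots; a `long_fraction` share of them (rounded to a
#' whole count) receive a paired IRES-probe spot whose center is displaced by
#' at most `coloc_offset` pixels, so that the pair's pixel masks overlap under
#' any reasonable detection threshold — these planted pairs are the long
#' 5' UTR isoform molecules. The negative-control channel contains only
#' background plus a small stated number of false spots.
#'
#' All intensities are `background` plus additive zero-mean Gaussian noise
#' (`noise_sd`) plus the spots, whose peak amplitudes are log-normal
#' (`amp_meanlog`, `amp_sdlog`). Spot centers are placed uniformly with a
#' minimum pairwise separation so puncta stay resolvable.
#'
#' @param n_spots Number of CDS-channel puncta (molecules) to plant.
#' @param long_fraction Proportion of CDS puncta paired with an IRES punctum,
#'   in `[0, 1]`.
#' @param dim Image dimensions `c(rows, cols)` in pixels.
#' @param psf_sigma Gaussian point-spread sigma in pixels.
#' @param background Constant background intensity.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param amp_meanlog,amp_sdlog Log-normal parameters of spot peak amplitude.
#' @param neg_spots Number of false puncta planted on the negative-control
#'   channel.
#' @param coloc_offset Maximum center displacement (px) of a paired IRES
#'   punctum from its CDS punctum.
#' @param min_separation Minimum distance (px) between planted CDS centers.
#' @param region,embryo Optional labels propagated to the image stack.
#' @param seed Integer seed; identical seeds give bit-identical images. The
#'   caller's RNG state is left untouched.
#' @param max_attempts Rejection-sampling budget for spot placement.
#'
#' @return A list with elements `image` (an [image_stack()]) and `truth`, a
#'   list holding the generator parameters plus `spots`, a tibble of planted
#'   centers (`channel`, `spot_id`, `row`, `col`, `amplitude`, `is_long`,
#'   `pair_id`) in 0-based pixel coordinates.
#' @examples
#' sim <- simulate_smfish_image(n_spots = 20, long_fraction = 0.5, seed = 1)
#' dplyr::count(sim$truth$spots, channel)
#' @export
simulate_smfish_image <- function(n_spots = 40,
                                  long_fraction = 0.8,
                                  dim = c(128L, 128L),
                                  psf_sigma = 1.3,
                                  background = 100,
                                  noise_sd = 5,
                                  amp_meanlog = log(60),
                                  amp_sdlog = 0.2,
                                  neg_spots = 2L,
                                  coloc_offset = 1,
                                  min_separation = 6 * psf_sigma,
                                  region = NA_character_,
                                  embryo = NA_character_,
                                  seed = NULL,
                                  max_attempts = 20000L) {
  stopifnot(length(dim) == 2, all(dim >= 4 * psf_sigma))
  if (long_fraction < 0 || long_fraction > 1) {
    abort("`long_fraction` must lie in [0, 1].")
  }
  if (n_spots < 0) abort("`n_spots` must be non-negative.")
  if (n_spots == 0 && long_fraction > 0) {
    abort("`long_fraction` > 0 requires at least one CDS spot.")
  }

  with_seed(seed, {
    centers <- place_centers(n_spots, dim, psf_sigma, min_separation,
                             max_attempts)
    n_long <- as.integer(round(long_fraction * n_spots))
    is_long <- c(rep(TRUE, n_long), rep(FALSE, n_spots - n_long))

    cds <- tibble::tibble(
      channel = rep("cds", n_spots),
      spot_id = seq_len(n_spots) + 0L,
      row = centers$row, col = centers$col,
      amplitude = rlnorm(n_spots, amp_meanlog, amp_sdlog),
      is_long = is_long,
      pair_id = ifelse(is_long, seq_len(n_spots), NA_integer_)
    )

    # IRES partners: displaced by at most `coloc_offset` px in a random
    # direction so their masks share pixels with the CDS spot.
    ires <- if (n_long > 0) {
      theta <- runif(n_long, 0, 2 * pi)
      rad <- coloc_offset * sqrt(runif(n_long))
      tibble::tibble(
        channel = "ires",
        spot_id = seq_len(n_long),
        row = cds$row[seq_len(n_long)] + rad * sin(theta),
        col = cds$col[seq_len(n_long)] + rad * cos(theta),
        amplitude = rlnorm(n_long, amp_meanlog, amp_sdlog),
        is_long = TRUE,
        pair_id = seq_len(n_long) + 0L
      )
    } else {
      cds[0, ]
    }

    neg <- if (neg_spots > 0) {
      nc <- place_centers(neg_spots, dim, psf_sigma, 0, max_attempts)
      tibble::tibble(
        channel = "neg",
        spot_id = seq_len(neg_spots) + 0L,
        row = nc$row, col = nc$col,
        amplitude = rlnorm(neg_spots, amp_meanlog, amp_sdlog),
        is_long = FALSE, pair_id = NA_integer_
      )
    } else {
      cds[0, ]
    }

    spots <- dplyr::bind_rows(cds, ires, neg)
    render <- function(chan) {
      s <- spots[spots$channel == chan, , drop = FALSE]
      img <- matrix(background, dim[1], dim[2]) +
        matrix(rnorm(prod(dim), 0, noise_sd), dim[1], dim[2])
      add_gaussian_spots(img, s$row, s$col, s$amplitude, psf_sigma)
    }
    image <- image_stack(cds = render("cds"), ires = render("ires"),
                         neg = render("neg"),
                         region = region, embryo = embryo)

    truth <- list(
      n_spots = n_spots, long_fraction = long_fraction,
      psf_sigma = psf_sigma, background_level = background,
      noise_sd = noise_sd, coloc_offset = coloc_offset,
      neg_spots = neg_spots, dim = dim, seed = seed,
      spots = spots
    )
    list(image = image, truth = truth)
  })
}

# Uniform placement with a minimum pairwise separation and a PSF-sized
# border margin; rejects when the budget is exhausted.
place_centers <- function(n, dim, sigma, min_sep, max_attempts) {
  margin <- 3 * sigma + 1
  if (n > 0 && (dim[1] <= 2 * margin || dim[2] <= 2 * margin)) {
    abort("Image too small for the requested PSF margin.")
  }
  rows <- numeric(0); cols <- numeric(0)
  attempts <- 0L
  while (length(rows) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("Could not place spots within `max_attempts`; image too crowded.")
    }
    r <- runif(1, margin, dim[1] - 1 - margin)
    c <- runif(1, margin, dim[2] - 1 - margin)
    if (min_sep > 0 && length(rows) > 0 &&
        min((rows - r)^2 + (cols - c)^2) < min_sep^2) {
      next
    }
    rows <- c(rows, r); cols <- c(cols, c)
  }
  list(row = rows, col = cols)
}

# Adds isotropic Gaussian spots (truncated at 4 sigma) to an image.
# Pixel (i, j) is centered at 0-based coordinates (i-1, j-1).
add_gaussian_spots <- function(img, rows, cols, amps, sigma) {
  ext <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  for (k in seq_along(rows)) {
    r0 <- rows[k]; c0 <- cols[k]
    ri <- max(0, floor(r0 - ext)):min(nr - 1, ceiling(r0 + ext))
    ci <- max(0, floor(c0 - ext)):min(nc - 1, ceiling(c0 + ext))
    d2 <- outer((ri - r0)^2, (ci - c0)^2, `+`)
    img[ri + 1, ci + 1] <- img[ri + 1, ci + 1] +
      amps[k] * exp(-d2 / (2 * sigma^2))
  }
  img
}

#' Preset generator parameters for the tissue regions
#'
#' `"somite"` plants 80% long-isoform molecules (the posterior-somite
#' proportion where the long 5' UTR isoform predominates); `"neural_tube"`
#' plants 20% (the anterior region where the short isoform predominates).
#'
#' @param preset `"somite"` or `"neural_tube"`.
#' @return A named list of [simulate_smfish_image()] arguments.
#' @export
smfish_preset <- function(preset = c("somite", "neural_tube")) {
  preset <- match.arg(preset)
  switch(preset,
    somite = list(long_fraction = 0.80, region = "somites 20-28"),
    neural_tube = list(long_fraction = 0.20, region = "neural tube")
  )
}

#' Simulate a cohort of embryos for isoform-recovery studies
#'
#' Generates `n_embryos` embryos with `images_per_embryo` fields of view each,
#' all sharing one planted `long_fraction`. Per-image seeds are derived
#' deterministically from `seed`.
#'
#' @inheritParams simulate_smfish_image
#' @param n_embryos,images_per_embryo Cohort layout.
#' @param preset Optional [smfish_preset()] name; overrides `long_fraction`
#'   and `region`.
#' @param ... Further arguments passed to [simulate_smfish_image()].
#' @return A tibble with one row per image: `embryo`, `image`, `region`,
#'   list-columns `stack` and `truth`.
#' @export
simulate_smfish_cohort <- function(n_embryos = 3,
                                   images_per_embryo = 5,
                                   long_fraction = 0.8,
                                   region = NA_character_,
                                   preset = NULL,
                                   seed = 1L,
                                   ...) {
  if (!is.null(preset)) {
    p <- smfish_preset(preset)
    long_fraction <- p$long_fraction
    region <- p$region
  }
  grid <- tidyr::expand_grid(embryo = paste0("embryo_", seq_len(n_embryos)),
                             image = seq_len(images_per_embryo))
  sims <- purrr::pmap(list(grid$embryo, seq_len(nrow(grid))), function(em, i) {
    simulate_smfish_image(long_fraction = long_fraction, region = region,
                          embryo = em,
                          seed = (as.integer(seed) %% 2000000L) * 1000L + i,
                          ...)
  })
  grid$region <- region
  grid$stack <- purrr::map(sims, "image")
  grid$truth <- purrr::map(sims, "truth")
  grid
}
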