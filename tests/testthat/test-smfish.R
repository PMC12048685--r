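test_that("detection is silent on flat images and validates parameters", {
  flat <- matrix(100, 32, 32)
  expect_equal(nrow(detect_spots(flat)), 0)
  expect_error(detect_spots(flat, window = 4), "odd")
  expect_error(detect_spots(flat, window = 41), "exceed")
  expect_error(detect_spots(flat, min_area = 0), "min_area")
  stack <- image_stack(cds = flat)
  expect_error(detect_spots(stack, "ires"), "not present")
})

test_that("planted spots are detected at their centers with disjoint masks", {
  base <- matrix(0, 32, 32)
  one <- irestoolbox:::add_gaussian_spots(base + 100, 8, 8, 80, 1.2)
  sp <- detect_spots(one, window = 9)
  expect_equal(nrow(sp), 1)
  expect_lt(sqrt((sp$row - 8)^2 + (sp$col - 8)^2), 0.5)
  expect_identical(spot_mask_keys(sp), oracle_mask_keys(
    oracle_detect(one, window = 9)))

  two <- irestoolbox:::add_gaussian_spots(base + 100, c(8, 20), c(8, 20),
                                          c(80, 80), 1.2)
  sp2 <- detect_spots(two, window = 9)
  expect_equal(nrow(sp2), 2)
  keys <- spot_mask_keys(sp2)
  expect_length(intersect(keys[[1]], keys[[2]]), 0)
})

test_that("colocalization counting honours its contract", {
  mk <- function(px) tibble::tibble(
    channel = "x", spot_id = seq_along(px), row = 0, col = 0,
    area_px = vapply(px, nrow, integer(1)), intensity = 1, mask = px)
  m <- function(...) {
    x <- rbind(...)
    cbind(row = x[, 1], col = x[, 2])
  }
  # identical masks colocalize
  r <- classify_colocalization(mk(list(m(c(5L, 5L)))), mk(list(m(c(5L, 5L)))))
  expect_equal(r$n_colocalized, 1); expect_equal(r$n_cds_only, 0)
  # disjoint masks do not
  r <- classify_colocalization(mk(list(m(c(5L, 5L)))), mk(list(m(c(9L, 9L)))))
  expect_equal(r$n_cds_only, 1); expect_equal(r$n_ires_only, 1)
  # one CDS spot over two IRES spots counts once
  cds <- mk(list(m(c(4L, 4L), c(4L, 5L), c(4L, 6L))))
  ires <- mk(list(m(c(4L, 4L)), m(c(4L, 6L))))
  r <- classify_colocalization(cds, ires)
  expect_equal(r$n_colocalized, 1)
  expect_equal(r$n_ires_only, 0)
  # empty inputs give all-zero counts
  r <- classify_colocalization(mk(list())[0, ], mk(list())[0, ])
  expect_true(all(r[, c("n_colocalized", "n_cds_only", "n_ires_only")] == 0))
})

test_that("counts are conserved and order-invariant", {
  sim <- simulate_smfish_image(n_spots = 30, long_fraction = 0.5, seed = 11)
  cds <- detect_spots(sim$image, "cds")
  ires <- detect_spots(sim$image, "ires")
  r <- classify_colocalization(cds, ires)
  expect_equal(r$n_colocalized + r$n_cds_only, nrow(cds))
  perm <- sample(nrow(cds))
  r2 <- classify_colocalization(cds[perm, ], ires[sample(nrow(ires)), ])
  expect_equal(r2[, -(1:2)], r[, -(1:2)], ignore_attr = TRUE)
})

test_that("degenerate planted fractions classify perfectly", {
  # at zero noise the local MAD vanishes and masks grow to the full PSF
  # footprint, so spots need generous separation to stay distinct
  all_long <- simulate_smfish_image(n_spots = 12, long_fraction = 1,
                                    noise_sd = 0, dim = c(256L, 256L),
                                    min_separation = 20, seed = 3)
  r <- smfish_counts(all_long$image)
  expect_equal(r$n_cds_only, 0)
  expect_equal(r$n_colocalized, 12)
  none_long <- simulate_smfish_image(n_spots = 12, long_fraction = 0,
                                     noise_sd = 0, dim = c(256L, 256L),
                                     min_separation = 20, seed = 3)
  r <- smfish_counts(none_long$image)
  expect_equal(r$n_colocalized, 0)
})

test_that("negative-control QC compares spot densities", {
  sim <- simulate_smfish_image(n_spots = 40, long_fraction = 0.5,
                               neg_spots = 1, seed = 7)
  qc <- negcontrol_qc(sim$image)
  expect_equal(qc$verdict, "PASS")
  # NEG as dense as CDS fails at any threshold below 1
  stack <- sim$image
  stack$neg <- stack$cds
  expect_equal(negcontrol_qc(stack, max_density_ratio = 0.99)$verdict, "FAIL")
  no_neg <- image_stack(cds = sim$image$cds)
  expect_equal(negcontrol_qc(no_neg)$verdict, "not assessed")
})

test_that("pooling sums counts per embryo before taking proportions", {
  calls <- tibble::tibble(
    embryo = c("e1", "e1", "e2"), region = "somites 20-28",
    n_colocalized = c(3, 5, 0), n_cds_only = c(1, 1, 0),
    n_ires_only = 0, n_cds_total = c(4, 6, 0), n_ires_total = 0)
  expect_warning(emb <- pool_isoforms(calls), "excluded")
  expect_equal(emb$long_proportion[emb$embryo == "e1"], 0.8)
  expect_true(emb$excluded[emb$embryo == "e2"])
  s <- summarize_isoforms(emb)
  expect_equal(s$n_embryos, 1)
  expect_equal(s$mean_long_proportion, 0.8)
})
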