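test_that("rel_quantity is the exponential delta-Ct transform", {
  expect_equal(rel_quantity(20, 20), 1)
  expect_equal(rel_quantity(21, 20), 0.5)
  expect_equal(rel_quantity(18, 20), 4)
  expect_true(is.na(rel_quantity(NA, 20)))
  # reciprocal identity and monotonicity
  for (i in 1:20) {
    a <- runif(1, 15, 35); b <- runif(1, 15, 35)
    expect_equal(rel_quantity(a, b) * rel_quantity(b, a), 1)
  }
  cts <- sort(runif(10, 15, 35))
  expect_true(all(diff(rel_quantity(cts, 20)) < 0))
})

test_that("RNase R enrichment reproduces the generator's decay identity", {
  # no digestion effect: all enrichments 1
  flat <- tidyr::expand_grid(sample = "s", amplicon = c("c", "l", "ref"),
                             treatment = c("none", "rnaser"),
                             replicate = 1L)
  flat$ct <- 25
  r <- rnaser_enrichment(flat, "c", "l", "ref")
  expect_equal(r$circ_enrichment, 1)
  expect_equal(r$linear_enrichment, 1)
  expect_equal(r$circ_linear_ratio, 1)
  # closed form: ratio = d_lin / d_circ regardless of the reference decay
  for (i in 1:10) {
    d_lin <- runif(1, 2, 40); d_circ <- runif(1, 1, 3)
    tr <- qpcr_truth(c(c = 0.2, l = 1, ref = 3),
                     amplicon_class = c(c = "circular", l = "linear",
                                        ref = "linear"),
                     rnaser_linear_decay = d_lin,
                     rnaser_circ_decay = d_circ)
    sim <- simulate_ct_table(tr, ct_design("s", c("c", "l", "ref"),
                                           c("none", "rnaser"), 1))
    r <- rnaser_enrichment(sim$ct, "c", "l", "ref")
    expect_equal(r$circ_linear_ratio, d_lin / d_circ)
  }
  # missing pair: skipped with a warning
  broken <- flat[!(flat$sample == "s" & flat$treatment == "rnaser" &
                     flat$amplicon == "c"), ]
  expect_warning(rnaser_enrichment(broken, "c", "l", "ref"), "skipped")
})

test_that("no-RT deltas average paired replicates with a ceiling fallback", {
  tbl <- tidyr::expand_grid(sample = "s", amplicon = "a",
                            treatment = c("none", "no_rt"),
                            fraction = NA_integer_, replicate = 1:3)
  tbl$ct <- ifelse(tbl$treatment == "none", 24, 34)
  r <- no_rt_delta(tbl)
  expect_equal(r$mean_delta_ct, 10)
  expect_equal(r$sd_delta_ct, 0)
  tbl$ct[tbl$treatment == "no_rt"] <- tbl$ct[tbl$treatment == "none"] +
    c(10, 11, 12)
  r <- no_rt_delta(tbl)
  expect_equal(r$mean_delta_ct, 11)
  expect_equal(r$sd_delta_ct, 1)
  expect_false(r$ceiling_used)
  # undetermined no-RT reported against the max-cycle ceiling, flagged
  tbl$ct[tbl$treatment == "no_rt"] <- NA
  tbl$ct[tbl$treatment == "none"] <- 30
  r <- no_rt_delta(tbl, max_cycle = 40)
  expect_equal(r$mean_delta_ct, 10)
  expect_true(r$ceiling_used)
})

test_that("standard curves fit, validate, and invert", {
  d <- tibble::tibble(quantity = 10^seq(0, -4), ct = 20 - log2(10^seq(0, -4)))
  curve <- fit_standard_curve(d)
  expect_equal(curve$slope, -1 / log10(2), tolerance = 1e-10)
  expect_equal(curve$efficiency, 2, tolerance = 1e-10)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(nrow(d), 5) # tenfold steps from 1 pg to 0.1 fg
  expect_error(fit_standard_curve(d[1:2, ]), "three distinct")
  expect_error(fit_standard_curve(dplyr::mutate(d, quantity = -quantity)),
               "positive")
  expect_warning(
    fit_standard_curve(tibble::tibble(quantity = 10^seq(0, -4),
                                      ct = 20 + 10 * log10(10^seq(0, -4)) * -1)),
    "efficiency")
  # inversion: the curve's own points round-trip exactly
  q <- absolute_quantify(d$ct, curve)
  expect_equal(q$quantity, d$quantity, tolerance = 1e-9)
  expect_false(any(q$extrapolated))
  out <- absolute_quantify(40, curve)
  expect_true(out$extrapolated)
  expect_true(is.na(absolute_quantify(NA_real_, curve)$quantity))
})

test_that("tidy, glance, and autoplot expose the curve fit", {
  d <- tibble::tibble(quantity = 10^seq(0, -4),
                      ct = 20 - log2(10^seq(0, -4)) + rnorm(5, 0, 0.05))
  curve <- fit_standard_curve(d, amplicon = "CDS2")
  td <- tidy(curve)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(curve)
  expect_equal(gl$amplicon, "CDS2")
  expect_s3_class(autoplot(curve), "ggplot")
})

test_that("noisy dilution series still quantify within tolerance", {
  set.seed(42)
  rel_err <- replicate(100, {
    q_true <- 10^runif(1, -3.5, -0.5)
    tr <- qpcr_truth(c(a = 1), ct_noise_sd = 0.2)
    dil <- simulate_ct_table(tr, ct_design_dilution("a"),
                             seed = sample.int(1e6, 1))
    curve <- fit_standard_curve(dil$ct)
    ct_obs <- 20 - log2(q_true) + rnorm(1, 0, 0.2)
    abs(absolute_quantify(ct_obs, curve)$quantity - q_true) / q_true
  })
  expect_lt(median(rel_err), 0.15)
})

test_that("polysome distributions normalize, partition, and stay invariant", {
  tbl <- tidyr::expand_grid(sample = "s", amplicon = c("a", "spike"),
                            treatment = "none", fraction = 1:5,
                            replicate = 1L)
  tbl$ct <- ifelse(tbl$amplicon == "spike", 23, 25)
  p <- polysome_distribution(tbl, "spike")
  expect_equal(p$distribution$rel_abundance, rep(0.2, 5))
  expect_equal(sum(p$distribution$rel_abundance), 1, tolerance = 1e-9)
  expect_equal(as.character(p$distribution$portion),
               c("free", "40S/60S", "80S", "light polysome",
                 "heavy polysome"))
  # uniform spike offset leaves the distribution unchanged
  tbl2 <- tbl
  tbl2$ct[tbl2$amplicon == "spike"] <- tbl2$ct[tbl2$amplicon == "spike"] + 3
  p2 <- polysome_distribution(tbl2, "spike")
  expect_equal(p2$distribution$rel_abundance, p$distribution$rel_abundance)
  # replicate order relabeling leaves the distribution unchanged
  tbl3 <- tidyr::expand_grid(sample = "s", amplicon = c("a", "spike"),
                             treatment = "none", fraction = 1:5,
                             replicate = 1:2)
  tbl3$ct <- ifelse(tbl3$amplicon == "spike", 23, 25) +
    rep(c(-0.5, 0.5), length.out = nrow(tbl3))
  tbl4 <- tbl3
  tbl4$replicate <- 3 - tbl4$replicate
  expect_equal(polysome_distribution(tbl3, "spike")$distribution,
               polysome_distribution(tbl4, "spike")$distribution)
  # missing spike rejects
  expect_error(polysome_distribution(tbl[tbl$amplicon != "spike", ],
                                     "spike"), "Spike")
  bad <- tbl[!(tbl$amplicon == "spike" & tbl$fraction == 3), ]
  expect_error(polysome_distribution(bad, "spike"), "Missing spike")
})

test_that("planted gradient peaks are recovered in the right portion", {
  w <- c(1, 1, 1, 2, 3, 4, 8, 6, 3, 2) # peaks in the light-polysome span
  tr <- qpcr_truth(c(a = 0.2), amplicon_class = c(a = "linear",
                                                  spike = "spike"),
                   gradient_weights = list(a = w), ct_noise_sd = 0.1)
  sim <- simulate_ct_table(tr, ct_design("s", c("a", "spike"),
                                         fractions = 1:10, replicates = 3),
                           seed = 8)
  p <- polysome_distribution(sim$ct, "spike")
  expect_equal(as.character(p$peak$peak_portion), "light polysome")
})

test_that("reporter activity is the Nluc/Fluc ratio with reference scaling", {
  d <- tibble::tibble(construct = c("ref", "x"), nluc = c(50, 100),
                      fluc = c(50, 50))
  r <- reporter_activity(d, "ref")
  expect_equal(r$activity, c(1, 2))
  expect_equal(r$relative_activity, c(1, 2))
  d$mrna_ratio <- c(1, 2)
  r <- reporter_activity(d, "ref")
  expect_equal(r$relative_activity[2], 1) # mRNA normalization halves it
  expect_error(reporter_activity(dplyr::mutate(d, fluc = 0), "ref"), "fluc")
  expect_error(reporter_activity(d, "nope"), "not found")
})
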