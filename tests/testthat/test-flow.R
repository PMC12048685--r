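# local mirror of the tier mapping used for independent checks
p_to_tier_ref <- function(p) {
  if (p > 0.05) "ns" else if (p > 0.01) "*" else if (p > 0.001) "**"
  else if (p > 1e-4) "***" else "****"
}

test_that("QC excludes flagged clogs and planted rate spikes", {
  sim <- simulate_facs_events(10000, clog_window = c(2001, 3000), seed = 1)
  qc <- qc_exclude(sim$events)
  expect_equal(which(!qc), 2001:3000)
  rate <- qc_exclude(sim$events, "rate")
  expect_gt(mean(!rate[sim$events$anomaly]), 0.95)
  expect_lt(mean(!rate[!sim$events$anomaly]), 0.02)
  clean <- simulate_facs_events(5000, seed = 2)
  expect_true(all(qc_exclude(clean$events, "rate")))
  expect_length(qc_exclude(clean$events[0, ]), 0)
})

test_that("scatter gates nest and exclude debris and doublets", {
  sim <- simulate_facs_events(20000, debris_fraction = 0.1,
                              doublet_fraction = 0.1, seed = 3)
  g <- gate_viable_singlets(sim$events, qc_exclude(sim$events))
  expect_true(all(g$viable[g$singlet]))
  expect_true(all(g$qc_pass[g$viable]))
  expect_true(all(diff(g$counts$n) <= 0))
  cat_ <- sim$truth$category
  expect_gt(mean(!g$viable[cat_ == "debris"]), 0.95)
  expect_gt(mean(!g$singlet[cat_ == "doublet"]), 0.95)
  # homogeneous FSC-H == FSC-A: all viable events are singlets
  ev <- sim$events
  ev$fsc_h <- ev$fsc_a
  g2 <- gate_viable_singlets(ev)
  expect_equal(g2$singlet, g2$viable)
  expect_error(gate_viable_singlets(sim$events[1:10, ]), "Fewer than")
})

test_that("the mRuby gate is a control-percentile threshold", {
  ctrl <- simulate_facs_events(20000, transfected_fraction = 0, seed = 4)
  g <- gate_viable_singlets(ctrl$events)
  # sample identical to control: about (100 - q)% positive
  gg <- gate_mruby(ctrl$events, g, ctrl$events, control_gates = g, q = 99)
  expect_equal(sum(gg$mruby_pos) / sum(gg$singlet), 0.01, tolerance = 0.25)
  # half the sample far above control: about half gated positive
  sim <- simulate_facs_events(20000, debris_fraction = 0,
                              doublet_fraction = 0,
                              transfected_fraction = 0.5, seed = 5)
  gs <- gate_viable_singlets(sim$events)
  gs <- gate_mruby(sim$events, gs, ctrl$events, control_gates = g)
  expect_equal(sum(gs$mruby_pos) / sum(gs$singlet), 0.5, tolerance = 0.05)
  # q = 100 with the sample maximum below the control maximum: none positive
  lo <- sim$events
  lo$mruby <- pmin(lo$mruby, max(ctrl$events$mruby) * 0.9)
  gl <- gate_mruby(lo, gs, ctrl$events, control_gates = g, q = 100)
  expect_equal(sum(gl$mruby_pos), 0)
  expect_error(gate_mruby(sim$events, gs, NULL), "control")
})

test_that("MFI follows the median convention and mask invariances", {
  ev <- tibble::tibble(egfp = c(1, 2, 3))
  expect_equal(egfp_mfi(ev, rep(TRUE, 3)), 2)
  ev4 <- tibble::tibble(egfp = c(1, 2, 3, 4))
  expect_equal(egfp_mfi(ev4, rep(TRUE, 4)), 2.5)
  # invariant to event order and to events outside the mask
  sim <- simulate_facs_events(1000, seed = 6)
  mask <- sim$events$mruby > median(sim$events$mruby)
  base <- egfp_mfi(sim$events, mask)
  perm <- sample(nrow(sim$events))
  expect_equal(egfp_mfi(sim$events[perm, ], mask[perm]), base)
  extra <- dplyr::bind_rows(sim$events, sim$events)
  expect_equal(egfp_mfi(extra, c(mask, rep(FALSE, nrow(sim$events)))), base)
  expect_warning(out <- egfp_mfi(sim$events, rep(FALSE, 1000)), "Empty")
  expect_true(is.na(out))
})

test_that("fold activity normalizes the reference to 1 with Welch statistics", {
  mfis <- tibble::tibble(
    construct = rep(c("empty_vector", "cvb3"), each = 3),
    mfi = c(100, 110, 90, 1200, 1400, 1300))
  act <- fold_activity(mfis)
  ref <- act[act$construct == "empty_vector", ]
  expect_equal(ref$mean_fold, 1)
  expect_equal(ref$p_value, 1)
  # hand-computed Welch t-test as the independent check
  f_c <- c(1200, 1400, 1300) / 100
  f_r <- c(100, 110, 90) / 100
  tstat <- (mean(f_c) - mean(f_r)) /
    sqrt(var(f_c) / 3 + var(f_r) / 3)
  df <- (var(f_c) / 3 + var(f_r) / 3)^2 /
    ((var(f_c) / 3)^2 / 2 + (var(f_r) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(tstat), df)
  expect_equal(act$p_value[act$construct == "cvb3"], p_hand)
  expect_equal(act$tier[act$construct == "cvb3"], p_to_tier_ref(p_hand))
  # ratio invariance: rescaling all MFIs leaves folds unchanged
  act2 <- fold_activity(dplyr::mutate(mfis, mfi = mfi * 7))
  expect_equal(act2$mean_fold, act$mean_fold)
  # degenerate zero-variance folds: identical means give p = 1
  same <- tibble::tibble(construct = rep(c("empty_vector", "x"), each = 2),
                         mfi = c(1, 1, 2, 2))
  a <- fold_activity(same)
  expect_equal(a$p_value[a$construct == "x"], 0)
  expect_equal(a$tier[a$construct == "x"], "****")
  expect_error(fold_activity(mfis, reference = "missing"), "not found")
})

test_that("significance tiers follow the published cutpoints", {
  expect_equal(p_to_tier_ref(0.03), "*")
  tiers <- fold_activity(tibble::tibble(
    construct = rep(c("empty_vector", "a"), each = 2),
    mfi = c(1, 1.2, 1.1, 1.3)))
  expect_true(all(tiers$tier %in% c("ns", "*", "**", "***", "****")))
})
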