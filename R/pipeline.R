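#' Run an end-to-end synthetic demo pipeline for one assay
#'
#' Ties the synthetic generators to the matching analysis stage and writes
#' the results plus a machine-readable provenance sidecar (parameters, seed,
#' package version) to `out_dir`. Identical configuration and seed reproduce
#' identical result files.
#'
#' Assays: `"smfish"` simulates a cohort and writes per-image calls,
#' per-embryo proportions, and the region summary; `"flow"` simulates an
#' empty-vector and a construct well, gates them, and writes fold activity;
#' `"qpcr"` simulates an RNase R experiment, a dilution series, and a
#' gradient, writing enrichment, curve, and distribution tables; `"seq"`
#' scans a demo insert for uAUGs and writes the report.
#'
#' @param assay One of `"smfish"`, `"flow"`, `"qpcr"`, `"seq"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the provenance sidecar.
#' @param params Named list of overrides passed to the generator.
#' @return Invisibly, a character vector of the files written.
#' @export
run_demo_pipeline <- function(assay = c("smfish", "flow", "qpcr", "seq"),
                              out_dir, seed = 1L, params = list()) {
  assay <- match.arg(assay)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(assay,
    smfish = demo_smfish(out_dir, seed, params),
    flow = demo_flow(out_dir, seed, params),
    qpcr = demo_qpcr(out_dir, seed, params),
    seq = demo_seq(out_dir, params)
  )
  prov <- file.path(out_dir, paste0(assay, "_provenance.yaml"))
  yaml::write_yaml(list(
    assay = assay, seed = seed, params = params,
    package = "irestoolbox",
    version = as.character(utils::packageVersion("irestoolbox"))
  ), prov)
  invisible(c(files, prov))
}

write_tsv_out <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_tsv(x, path)
  path
}

demo_smfish <- function(out_dir, seed, params) {
  args <- utils::modifyList(list(preset = "somite", seed = seed), params)
  cohort <- do.call(simulate_smfish_cohort, args)
  res <- quantify_isoforms(cohort)
  c(write_tsv_out(res$calls, out_dir, "smfish_calls.tsv"),
    write_tsv_out(res$embryos, out_dir, "smfish_embryos.tsv"),
    write_tsv_out(res$summary, out_dir, "smfish_region_summary.tsv"))
}

demo_flow <- function(out_dir, seed, params) {
  folds <- params$activity_folds %||% c(empty_vector = 1, construct = 4)
  n <- params$n_events %||% 20000
  reps <- params$replicates %||% 3
  mfis <- purrr::imap(folds, function(fold, construct) {
    purrr::map_dbl(seq_len(reps), function(r) {
      sim <- simulate_facs_events(
        n_events = n, activity_fold = fold,
        seed = seed + 7919L * r + 104729L * match(construct, names(folds)))
      ev <- sim$events
      qc <- qc_exclude(ev)
      gates <- gate_viable_singlets(ev, qc)
      ctrl <- simulate_facs_events(n_events = n, transfected_fraction = 0,
                                   seed = seed + 31L * r)
      gates <- gate_mruby(ev, gates, ctrl$events)
      egfp_mfi(ev, gates$mruby_pos)
    })
  })
  tbl <- tibble::tibble(
    construct = rep(names(folds), each = reps),
    replicate = rep(seq_len(reps), length(folds)),
    mfi = unlist(mfis, use.names = FALSE)
  )
  act <- fold_activity(tbl, reference = "empty_vector") |>
    dplyr::select(-"folds")
  c(write_tsv_out(tbl, out_dir, "flow_mfis.tsv"),
    write_tsv_out(act, out_dir, "flow_fold_activity.tsv"))
}

demo_qpcr <- function(out_dir, seed, params) {
  truth <- qpcr_truth(
    true_quantities = c(circ_junction = 0.05, linear_egfp = 0.5,
                        Nupl1 = 2),
    amplicon_class = c(circ_junction = "circular", linear_egfp = "linear",
                       Nupl1 = "linear"),
    ct_noise_sd = params$ct_noise_sd %||% 0.15,
    rnaser_linear_decay = params$rnaser_linear_decay %||% 10
  )
  sim <- simulate_ct_table(
    truth, ct_design("construct_1", names(truth$true_quantities),
                     treatments = c("none", "rnaser")), seed = seed)
  enr <- rnaser_enrichment(sim$ct, "circ_junction", "linear_egfp", "Nupl1")

  dil <- simulate_ct_table(truth, ct_design_dilution("linear_egfp"),
                           seed = seed + 1L)
  curve <- fit_standard_curve(dil$ct)

  gt <- qpcr_truth(
    true_quantities = c(ires_like = 0.2),
    amplicon_class = c(ires_like = "linear", spike = "spike"),
    gradient_weights = list(ires_like = c(1, 1, 1, 2, 3, 4, 8, 6, 3, 2)),
    ct_noise_sd = params$ct_noise_sd %||% 0.15
  )
  grad <- simulate_ct_table(
    gt, ct_design("tissue", c("ires_like", "spike"),
                  fractions = 1:10, replicates = 2), seed = seed + 2L)
  prof <- polysome_distribution(grad$ct, spike_amplicon = "spike")

  c(write_tsv_out(enr, out_dir, "qpcr_rnaser_enrichment.tsv"),
    write_tsv_out(glance(curve), out_dir, "qpcr_standard_curve.tsv"),
    write_tsv_out(prof$distribution, out_dir, "qpcr_gradient.tsv"),
    write_tsv_out(prof$portions, out_dir, "qpcr_gradient_portions.tsv"))
}

demo_seq <- function(out_dir, params) {
  utr <- params$utr %||% "GGCATGAAATAGCCCGATGCCACCATGGCAGCC"
  rec <- insert_record(params$name %||% "demo_insert", utr)
  inv <- make_inverse(rec)
  report <- scan_uaugs(rec$sequence)
  c(write_tsv_out(dplyr::bind_rows(rec, inv), out_dir, "seq_inserts.tsv"),
    write_tsv_out(report, out_dir, "seq_uaug_report.tsv"))
}
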