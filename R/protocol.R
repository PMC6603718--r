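#' Default protocol configuration
#'
#' Study conditions for [run_protocol()]: 80 samples spanning 10-1300 mg/L
#' on a log-spaced grid, a rank-stratified 56/24 calibration/test split,
#' three simulated cobalt electrodes, the four spectral pretreatments
#' (`raw`, `ma:11`, `ma:11+snv`, `ma:11+msc`), 11 PC scores for the fused
#' network and the seven candidate network cases. Any element can be
#' overridden through the `config` argument of [run_protocol()].
#'
#' @return named list of protocol settings.
#' @export
protocol_config <- function() {
  list(
    seed = 1L,
    n = 80L, lo = 10, hi = 1300, scheme = "grid",
    n_calib = 56L, n_test = 24L, split_strategy = "rank_stratified",
    spectra_cfg = list(), emf_cfg = list(),
    include_emf = TRUE,
    pretreatments = c("raw", "ma:11", "ma:11+snv", "ma:11+msc"),
    k_grid = 1:15, cv_folds = 10,
    n_pc = 11L, nn_cases = 1:7,
    nn_algorithm = "lm", nn_max_epochs = 100L,
    emf_ann_hidden = c(12L, 10L), emf_ann_acts = c("tanh", "logistic")
  )
}

#' Run the full model-comparison protocol
#'
#' Executes the complete comparison grid on simulated (or supplied) sensor
#' data: the four-pretreatment x \{PLSR, PCR\} spectral grid, per-electrode
#' log-linear calibration, an EMF-only neural network, raw-concatenation
#' fusion into PLSR and PCR, and the PC-NN fusion under each requested
#' hidden-node case. All data-dependent fitting uses calibration rows only.
#'
#' @param config named list overriding entries of [protocol_config()].
#' @param data optional list with pre-loaded `conc` ([conc_vector]),
#'   `spectra` ([spectra_set]) and `emf` ([electrode_set]); when omitted the
#'   simulator generates them under the master seed.
#' @return data.frame report, one row per fitted model, with columns
#'   `stage`, `preprocessing`, `model`, `n_components`, `calib_r2`,
#'   `calib_rmse`, `test_r2`, `test_rmse`, `test_slope`, `test_offset`.
#'   The master seed is attached as `attr(, "seed")`.
#' @export
run_protocol <- function(config = list(), data = NULL) {
  cfg <- utils::modifyList(protocol_config(), config)
  seed <- as.integer(cfg$seed)

  if (is.null(data)) {
    conc <- design_concentrations(cfg$n, cfg$lo, cfg$hi, cfg$scheme,
                                  seed = seed)
    sp_cfg <- do.call(spectra_sim_config,
                      utils::modifyList(list(seed = seed + 1L), cfg$spectra_cfg))
    spectra <- simulate_spectra(conc, sp_cfg)
    emf <- NULL
    if (cfg$include_emf) {
      em_cfg <- do.call(emf_sim_config,
                        utils::modifyList(list(seed = seed + 2L), cfg$emf_cfg))
      emf <- simulate_emf(conc, em_cfg)
    }
  } else {
    conc <- data$conc; spectra <- data$spectra; emf <- data$emf
    if (!cfg$include_emf) emf <- NULL
  }

  split <- split_samples(names(conc), cfg$n_calib, cfg$n_test,
                         strategy = cfg$split_strategy, seed = seed + 3L,
                         conc = conc)
  cal <- split$calib; tst <- split$test
  in_cal <- names(conc) %in% cal
  in_tst <- names(conc) %in% tst
  calib <- list(spectra = spectra[in_cal],
                emf = if (is.null(emf)) NULL else emf[in_cal],
                y = conc[in_cal])
  test <- list(spectra = spectra[in_tst],
               emf = if (is.null(emf)) NULL else emf[in_tst],
               y = conc[in_tst])

  rows <- list()
  add_row <- function(stage, preprocessing, model, k, met_cal, met_tst) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, preprocessing = preprocessing, model = model,
      n_components = k,
      calib_r2 = met_cal$r2, calib_rmse = met_cal$rmse,
      test_r2 = met_tst$r2, test_rmse = met_tst$rmse,
      test_slope = met_tst$slope, test_offset = met_tst$offset,
      stringsAsFactors = FALSE)
  }

  # --- NIR-only grid: pretreatment x {PLSR, PCR} -------------------------
  for (pt in cfg$pretreatments) {
    pre <- fit_pretreatment(calib$spectra, pt)
    xc <- predict(pre, calib$spectra)$intensity
    xt <- predict(pre, test$spectra)$intensity
    for (kind in c("plsr", "pcr")) {
      cv <- cross_validate(xc, as.numeric(calib$y), cfg$k_grid,
                           folds = cfg$cv_folds, seed = seed + 10L,
                           method = kind)
      k <- attr(cv, "best_k")
      m <- if (kind == "plsr") fit_plsr(xc, as.numeric(calib$y), k) else
        fit_pcr(xc, as.numeric(calib$y), k)
      add_row("nir", pt, toupper(kind), k,
              score_metrics(as.numeric(calib$y), predict(m, xc)),
              score_metrics(as.numeric(test$y), predict(m, xt)))
    }
  }

  if (!is.null(emf)) {
    # --- per-electrode log-linear calibration ----------------------------
    nm <- fit_nikolsky(calib$emf, calib$y)
    pc_cal <- suppressWarnings(predict_conc(nm, calib$emf, "per_electrode"))
    pc_tst <- suppressWarnings(predict_conc(nm, test$emf, "per_electrode"))
    for (eid in colnames(calib$emf$emf)) {
      add_row("electrode", "raw", paste0("nikolsky_", eid), NA_integer_,
              score_metrics(as.numeric(calib$y), pc_cal[, eid]),
              score_metrics(as.numeric(test$y), pc_tst[, eid]))
    }

    # --- EMF-only neural network ----------------------------------------
    net <- init_network(c(ncol(calib$emf$emf), cfg$emf_ann_hidden, 1L),
                        cfg$emf_ann_acts, seed = seed + 20L)
    net <- nn_train(net, calib$emf$emf, as.numeric(calib$y),
                    train_config(algorithm = cfg$nn_algorithm,
                                 max_epochs = cfg$nn_max_epochs))
    add_row("electrode", "raw",
            sprintf("ann_%s", paste(cfg$emf_ann_hidden, collapse = "_")),
            NA_integer_,
            score_metrics(as.numeric(calib$y), nn_forward(net, calib$emf$emf)),
            score_metrics(as.numeric(test$y), nn_forward(net, test$emf$emf)))

    # --- fusion method A: raw concatenation into PLSR / PCR --------------
    for (meth in c("plsr_concat", "pcr_concat")) {
      fd <- build_fusion(spectra, emf, method = meth, fit_ids = cal)
      fm <- fit_fusion(fd, conc, list(seed = seed + 30L,
                                      cv_folds = cfg$cv_folds))
      ev <- evaluate_split(fm, calib, test)
      add_row("fusion_concat", "raw", toupper(sub("_concat", "", meth)),
              fm$fit$n_components, ev$calibration, ev$test)
    }

    # --- fusion method B: PC scores + EMF into the network (PC-NN) -------
    fd <- build_fusion(spectra, emf, method = "pc_nn", n_pc = cfg$n_pc,
                       fit_ids = cal)
    cases <- hidden_node_cases()
    for (cs in cfg$nn_cases) {
      fm <- fit_fusion(fd, conc,
                       list(case = cs, algorithm = cfg$nn_algorithm,
                            max_epochs = cfg$nn_max_epochs,
                            seed = seed + 40L + cs))
      ev <- evaluate_split(fm, calib, test)
      add_row("fusion_pcnn", "raw",
              sprintf("pcnn_case%d_%d%s_%d%s", cs,
                      cases$nodes1[cs], cases$act1[cs],
                      cases$nodes2[cs], cases$act2[cs]),
              cfg$n_pc, ev$calibration, ev$test)
    }
  }

  report <- do.call(rbind, rows)
  attr(report, "seed") <- seed
  attr(report, "n_calib") <- length(cal)
  attr(report, "n_test") <- length(tst)
  report
}

#' Write a protocol report to CSV
#'
#' Prepends provenance comment lines (master seed, split sizes) so a report
#' file is self-describing; [read.csv][utils::read.csv] with `comment.char =
#' "#"` reads it back.
#'
#' @param report a [run_protocol()] report.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", attr(report, "seed")), con)
  writeLines(sprintf("# split: %d calibration / %d test",
                     attr(report, "n_calib"), attr(report, "n_test")), con)
  utils::write.csv(report, con, row.names = FALSE)
  invisible(path)
}
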