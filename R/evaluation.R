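# Evaluation: per-spectrum conversion MSE (Table-1-style), quantification
# MAPE, the three-way LF-MLP / HF-MLP / convert-then-quantify comparison,
# and overlay figure export.

# inference honoring a max-scaling factor learned at training time
predict_scaled <- function(net, X, batch_size = 32L) {
  sc <- net$scale %||% 1
  predict(net, X / sc, batch_size = batch_size) * sc
}

#' Per-spectrum conversion MSE report
#'
#' Runs the converter on every low-field test spectrum and reports the MSE
#' against the paired ground-truth high-field spectrum, per spectrum and as
#' the arithmetic mean.
#'
#' @param net a trained conversion network.
#' @param test_pairs either a corpus split (list with matrices `lf` and
#'   `hf`) or a list of `paired_sample` objects.
#' @param corpus_id identifier recorded in the report.
#' @return a `conversion_report`: `per_spectrum`, `mean_mse`,
#'   `architecture`, `corpus_id`.
#' @export
spectrum_mse_report <- function(net, test_pairs, corpus_id = "corpus") {
  if (is.list(test_pairs) && !is.null(test_pairs[[1]]) &&
      inherits(test_pairs[[1]], "paired_sample"))
    test_pairs <- list(
      lf = do.call(rbind, lapply(test_pairs, function(s) s$lf$intensities)),
      hf = do.call(rbind, lapply(test_pairs, function(s) s$hf$intensities)))
  if (!nrow(test_pairs$lf %||% matrix(nrow = 0, ncol = 0)))
    stopf("empty test set")
  pred <- predict_scaled(net, test_pairs$lf)
  per <- rowMeans((pred - test_pairs$hf)^2)
  structure(list(per_spectrum = per, mean_mse = mean(per),
                 architecture = net$architecture, corpus_id = corpus_id),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("<conversion_report:%s> %d spectra, mean MSE %.4g\n",
              x$architecture, length(x$per_spectrum), x$mean_mse))
  invisible(x)
}

#' Mean absolute percent error of concentration estimates
#'
#' `(100 / K) * sum(|est - truth| / truth)`, defined only for strictly
#' positive truth values.
#'
#' @param est,truth concentration vectors (mM) of equal length.
#' @return MAPE in percent.
#' @export
quant_mape <- function(est, truth) {
  if (length(est) != length(truth))
    stopf("length mismatch: est has %d entries, truth %d",
          length(est), length(truth))
  if (any(truth <= 0))
    stopf("MAPE undefined: all truth entries must be > 0")
  100 * mean(abs(est - truth) / truth)
}

#' Convert a low-field spectrum, then quantify with the high-field MLP
#'
#' The two-stage pipeline: `hf_mlp(converter(lf))`, with negative
#' concentration estimates clamped to zero at reporting time.
#'
#' @param lf a [spectrum_record()] or intensity vector (low field).
#' @param converter trained conversion network.
#' @param hf_mlp trained quantification MLP (high field).
#' @return concentration estimates (mM), one per MLP output.
#' @export
convert_then_quantify <- function(lf, converter, hf_mlp) {
  x <- if (inherits(lf, "spectrum_record")) lf$intensities else as.numeric(lf)
  if (length(x) != converter$spec$input_len)
    stopf("dimension mismatch: converter expects %d points, got %d",
          converter$spec$input_len, length(x))
  if (converter$spec$input_len != hf_mlp$spec$input_len)
    stopf("dimension mismatch: converter output length %d but MLP expects %d",
          converter$spec$input_len, hf_mlp$spec$input_len)
  hf_est <- predict_scaled(converter, matrix(x, nrow = 1))
  pmax(drop(predict_scaled(hf_mlp, hf_est)), 0)
}

#' Direct MLP quantification
#'
#' @param spec_or_vec spectrum to quantify.
#' @param mlp trained quantification MLP.
#' @return concentration estimates (mM), negatives clamped to 0.
#' @export
quantify_direct <- function(spec_or_vec, mlp) {
  x <- if (inherits(spec_or_vec, "spectrum_record"))
    spec_or_vec$intensities else as.numeric(spec_or_vec)
  pmax(drop(predict_scaled(mlp, matrix(x, nrow = 1))), 0)
}

#' Analytic noise floor of a corpus
#'
#' High-field targets carry uniform noise with peak-to-peak amplitude
#' `a = noise_pp_frac * reference height`; the pointwise MSE of any
#' noise-free prediction is bounded below by the noise variance `a^2 / 12`.
#' A trained model's test MSE falling below this floor indicates leakage.
#'
#' @param corpus a `spectra_corpus`.
#' @export
noise_floor <- function(corpus) {
  ref <- render_metabolite(reference_model(corpus$aug), corpus$hf_axis,
                           corpus$aug$ref_conc)
  a <- corpus$aug$noise_pp_frac * max(ref$intensities)
  a^2 / 12
}

#' Overlay figure: ground truth vs predicted high-field spectrum
#'
#' Full spectrum plus two zoom panels, truth and prediction overlaid, MSE
#' annotated.  Writes a PNG when `file` is given, otherwise draws on the
#' current device.
#'
#' @param truth,pred high-field intensity vectors.
#' @param axis the shared [make_axis()].
#' @param file optional output path (PNG).
#' @param zooms list of two ppm ranges for the zoom panels; defaults to the
#'   two windows with the highest truth signal.
#' @param lf optional low-field input shown behind the overlay.
#' @export
overlay_plot <- function(truth, pred, axis, file = NULL, zooms = NULL,
                         lf = NULL) {
  grid <- ppm_values(axis)
  if (is.null(zooms)) {
    win <- floor(axis$n_points / 10)
    strength <- vapply(seq_len(10), function(i)
      sum(truth[((i - 1) * win + 1):(i * win)]), 0)
    top <- order(strength, decreasing = TRUE)[1:2]
    zooms <- lapply(top, function(i)
      range(grid[c((i - 1) * win + 1, i * win)]))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 400, res = 100)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  panel <- function(xlim, main) {
    sel <- grid >= xlim[1] & grid <= xlim[2]
    graphics::plot(grid[sel], truth[sel], type = "l", col = "red",
                   xlim = rev(xlim),   # NMR convention: high ppm left
                   xlab = "ppm", ylab = "intensity", main = main)
    if (!is.null(lf))
      graphics::lines(grid[sel], lf[sel], col = "grey70")
    graphics::lines(grid[sel], pred[sel], col = "blue")
  }
  panel(c(axis$ppm_min, axis$ppm_max),
        sprintf("MSE %.3g", mean((truth - pred)^2)))
  panel(zooms[[1]], "zoom 1")
  panel(zooms[[2]], "zoom 2")
  invisible(file)
}

#' Train and compare conversion architectures on one corpus
#'
#' Trains each requested architecture on the corpus's training split,
#' monitors its validation split, evaluates per-spectrum MSE on the held-out
#' test pairs, and (optionally) writes a Table-1-shaped CSV plus overlay
#' figures for a sample of test spectra.
#'
#' @param corpus a `spectra_corpus`.
#' @param archs named list of [model_spec()]s (names label report rows).
#' @param cfgs a single [train_config()] applied to all architectures, or a
#'   named list parallel to `archs`.
#' @param out_dir optional artifact directory (CSV + PNG overlays).
#' @param overlay_n test spectra per architecture to plot.
#' @return list: `table` (data.frame architecture/mean_mse/epochs),
#'   `reports`, `nets`, `histories`.
#' @export
run_comparison_suite <- function(corpus, archs, cfgs = train_config(),
                                 out_dir = NULL, overlay_n = 2L) {
  stopifnot(inherits(corpus, "spectra_corpus"), length(archs) > 0)
  if (inherits(cfgs, "train_config"))
    cfgs <- stats::setNames(rep(list(cfgs), length(archs)), names(archs))
  reports <- list(); nets <- list(); histories <- list()
  for (nm in names(archs)) {
    message(sprintf("[fieldlift] training %s ...", nm))
    t0 <- proc.time()[3]
    net <- build_network(archs[[nm]])
    fit <- tryCatch(
      train_model(net, list(x = corpus$train$lf, y = corpus$train$hf),
                  list(x = corpus$val$lf, y = corpus$val$hf), cfgs[[nm]]),
      error = function(e) stopf("stage 'train:%s' failed: %s", nm,
                                conditionMessage(e)))
    nets[[nm]] <- fit$net
    histories[[nm]] <- fit$history
    reports[[nm]] <- spectrum_mse_report(fit$net, corpus$test, corpus_id = nm)
    message(sprintf("[fieldlift]   %s: mean test MSE %.5g (%d epochs, %.1fs)",
                    nm, reports[[nm]]$mean_mse, fit$history$n_epochs,
                    proc.time()[3] - t0))
  }
  table <- data.frame(
    architecture = names(archs),
    mean_mse = vapply(reports, function(r) r$mean_mse, 0),
    epochs = vapply(histories, function(h) h$n_epochs, 0L),
    best_epoch = vapply(histories, function(h) h$best_epoch, 0L),
    row.names = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "conversion_mse.csv"),
                     row.names = FALSE)
    n_plot <- min(overlay_n, nrow(corpus$test$lf))
    for (nm in names(nets)) for (i in seq_len(n_plot)) {
      pred <- predict_scaled(nets[[nm]],
                             corpus$test$lf[i, , drop = FALSE])
      try(overlay_plot(corpus$test$hf[i, ], drop(pred), corpus$hf_axis,
                       file.path(out_dir, sprintf("overlay_%s_%d.png", nm, i)),
                       lf = corpus$test$lf[i, ]), silent = TRUE)
    }
  }
  list(table = table, reports = reports, nets = nets, histories = histories)
}

#' Three-way quantification comparison
#'
#' Trains (or accepts) low-field and high-field quantification MLPs on a
#' no-triplet corpus and evaluates MAPE on fixed-concentration test pairs
#' for the three pipelines: direct LF-MLP, direct HF-MLP, and
#' convert-then-quantify (LF -> converter -> HF-MLP).
#'
#' @param corpus quantification `spectra_corpus` (concentration labels).
#' @param converter trained conversion network (for the two-stage pipeline).
#' @param cfg a [train_config()] for the MLPs.
#' @param test_samples list of `paired_sample`s from
#'   [build_fixed_concentration_tests()].
#' @param mlp_seed initialization seed for both MLPs.
#' @param hidden MLP hidden-layer width (200 at full scale).
#' @return a `quant_report`: data.frame `mape` with one row per
#'   (level, pipeline), the per-metabolite absolute percent errors, and the
#'   trained MLPs.
#' @export
run_quant_comparison <- function(corpus, converter, test_samples,
                                 cfg = train_config(task = "quantification"),
                                 mlp_seed = 7L, hidden = 200L) {
  k <- length(corpus$library_names)
  p <- ncol(corpus$train$lf)
  fit_mlp <- function(field) {
    net <- build_quant_mlp(input_len = p, seed = mlp_seed,
                           hidden = hidden, n_outputs = k)
    train_model(net, list(x = corpus$train[[field]], y = corpus$train$conc),
                list(x = corpus$val[[field]], y = corpus$val$conc), cfg)
  }
  lf_fit <- fit_mlp("lf")
  hf_fit <- fit_mlp("hf")
  ev <- evaluate_quant_pipelines(lf_fit$net, hf_fit$net, converter,
                                 test_samples)
  structure(list(mape = ev$mape, per_metabolite = ev$per_metabolite,
                 lf_mlp = lf_fit$net, hf_mlp = hf_fit$net,
                 histories = list(lf = lf_fit$history, hf = hf_fit$history)),
            class = "quant_report")
}

#' Score the three quantification pipelines on fixed-concentration samples
#'
#' @param lf_mlp,hf_mlp trained quantification MLPs.
#' @param converter trained conversion network, or `NULL` to skip the
#'   two-stage pipeline.
#' @param test_samples list of `paired_sample`s.
#' @return list: data.frame `mape` (level, pipeline, mape) and
#'   `per_metabolite` absolute percent errors.
#' @export
evaluate_quant_pipelines <- function(lf_mlp, hf_mlp, converter,
                                     test_samples) {
  rows <- list(); per_met <- list()
  for (s in test_samples) {
    truth <- s$conc
    lvl <- unique(truth)[1]
    ests <- list(
      lf_direct = quantify_direct(s$lf, lf_mlp),
      hf_direct = quantify_direct(s$hf, hf_mlp),
      convert_then_quantify =
        if (!is.null(converter))
          convert_then_quantify(s$lf, converter, hf_mlp) else NULL)
    for (nm in names(ests)) {
      if (is.null(ests[[nm]])) next
      rows[[length(rows) + 1]] <- data.frame(
        level_mM = lvl, pipeline = nm,
        mape = quant_mape(ests[[nm]], truth))
      per_met[[sprintf("%s_%gmM", nm, lvl)]] <-
        100 * abs(ests[[nm]] - truth) / truth
    }
  }
  list(mape = do.call(rbind, rows), per_metabolite = per_met)
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  print(x$mape)
  invisible(x)
}
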