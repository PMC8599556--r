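# Applying a clock to species absent from its training set: rank-order
# accuracy (R) versus calibration (MedAE, bias, slope), and an optional
# linear recalibration.

#' Evaluate a clock on species outside its training set
#'
#' Applies the model unchanged to every species in the sheet (for
#' chronological clocks the training transform is kept, as when a
#' domestic-cat clock is applied to lions) and reports, per species, the
#' sample size, Pearson R, median absolute error, mean signed offset
#' (bias), and the slope of prediction on truth. R only reflects
#' rank-order agreement, so a transferred clock can combine high R with a
#' large MedAE — the decoupling this report is designed to expose.
#'
#' For relative-age clocks the truth is `age / max_lifespan`, so the
#' target species must appear in `species_params`.
#'
#' @param model a `clock_model`.
#' @param mat samples x probes beta matrix for the new panel.
#' @param sheet aligned sample sheet.
#' @param species_params species parameter table covering the sheet's
#'   species (needed for relative-age truth; optional for chronological
#'   clocks).
#' @param fallback_species forwarded to [predict_clock()].
#' @return a `transfer_report`: data frame with one row per species
#'   (`species`, `n`, `R`, `medae`, `bias`, `slope`) plus the per-sample
#'   predictions as attribute `"predictions"`. Species with fewer than 3
#'   samples are excluded with a warning.
#' @export
transfer_evaluate <- function(model, mat, sheet, species_params = NULL,
                              fallback_species = model$training_species[1]) {
  stopifnot(inherits(model, "clock_model"), nrow(mat) == nrow(sheet))
  pred <- predict_clock(model, mat, sheet,
                        fallback_species = fallback_species)
  truth <- if (model$target_kind == "relative") {
    if (is.null(species_params))
      stop("relative-age evaluation needs species_params for the target ",
           "species", call. = FALSE)
    .build_targets_vec(sheet, species_params, "relative")
  } else {
    sheet$age
  }
  rows <- list()
  for (sp in unique(sheet$species)) {
    i <- which(sheet$species == sp)
    if (length(i) < 3) {
      warning("species ", sp, " has n < 3; excluded from transfer report")
      next
    }
    fit <- if (stats::sd(truth[i]) > 0)
      stats::lm.fit(cbind(1, truth[i]), pred[i])$coefficients[2]
    else NA_real_
    rows[[sp]] <- data.frame(
      species = sp, n = length(i),
      R = if (stats::sd(truth[i]) > 0 && stats::sd(pred[i]) > 0)
        stats::cor(pred[i], truth[i]) else NA_real_,
      medae = stats::median(abs(pred[i] - truth[i])),
      bias = mean(pred[i] - truth[i]),
      slope = fit,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no species with n >= 3 to evaluate", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  preds <- data.frame(sample_id = sheet$sample_id, species = sheet$species,
                      truth = truth, pred = pred, stringsAsFactors = FALSE)
  structure(out, predictions = preds, class = c("transfer_report",
                                                "data.frame"))
}

#' Linear recalibration of transferred clock predictions
#'
#' Fits, per species, the least-squares line mapping raw predictions to
#' truth and reports the corrected predictions and errors. This is a
#' post-hoc convenience for rank-order use of an off-species clock — the
#' correction is estimated on the evaluation samples themselves, so the
#' corrected MedAE is an in-sample quantity, not a validated accuracy.
#'
#' @param predictions numeric raw clock predictions.
#' @param truth numeric true values (same scale as predictions' target).
#' @param groups optional species factor; one line is fit per group.
#' @return data frame per group: `group`, `n`, `intercept`, `slope` (of
#'   the correction `truth ~ pred`), `medae_raw`, `medae_corrected`;
#'   corrected per-sample values as attribute `"corrected"`.
#' @export
recalibrate_linear <- function(predictions, truth, groups = NULL) {
  stopifnot(length(predictions) == length(truth))
  if (is.null(groups)) groups <- rep("all", length(truth))
  corrected <- rep(NA_real_, length(truth))
  rows <- list()
  for (g in unique(as.character(groups))) {
    i <- which(groups == g)
    if (length(i) < 3)
      stop("group ", g, " has fewer than 3 samples", call. = FALSE)
    if (stats::sd(predictions[i]) == 0)
      stop("degenerate prediction variance in group ", g, call. = FALSE)
    cf <- stats::lm.fit(cbind(1, predictions[i]), truth[i])$coefficients
    corrected[i] <- cf[1] + cf[2] * predictions[i]
    rows[[g]] <- data.frame(
      group = g, n = length(i), intercept = cf[1], slope = cf[2],
      medae_raw = stats::median(abs(predictions[i] - truth[i])),
      medae_corrected = stats::median(abs(corrected[i] - truth[i])),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "corrected") <- corrected
  out
}
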