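# Elastic-net epigenetic clocks: training, prediction, and the external
# cross-validation schemes used to report unbiased accuracy.

new_clock_model <- function(probes, coefficients, intercept, alpha, lambda,
                            target_kind, transforms, training_species) {
  stopifnot(length(probes) == length(coefficients),
            target_kind %in% c("raw_age", "loglinear", "relative"))
  structure(list(probes = as.character(probes),
                 coefficients = as.numeric(coefficients),
                 intercept = as.numeric(intercept),
                 alpha = as.numeric(alpha),
                 lambda = as.numeric(lambda),
                 target_kind = target_kind,
                 transforms = transforms,
                 training_species = as.character(training_species)),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("Epigenetic clock (", x$target_kind, " target)\n", sep = "")
  cat("  ", length(x$probes), " CpGs, alpha = ", x$alpha,
      ", lambda = ", signif(x$lambda, 4), "\n", sep = "")
  cat("  trained on:", paste(x$training_species, collapse = ", "), "\n")
  invisible(x)
}

# loglinear_age is scalar in its parameters; vectorize over per-sample
# (maturity, offset).
loglinear_age_vec <- function(age, maturity, offset) {
  mapply(loglinear_age, age, maturity, offset)
}

# Mean-impute missing betas per probe (training-time only), with a count.
.impute_means <- function(x) {
  n_missing <- sum(is.na(x))
  if (n_missing > 0) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- mu[j]
    }
    message(n_missing, " missing beta value(s) mean-imputed per probe")
  }
  x
}

#' Train an elastic-net epigenetic clock
#'
#' Fits a penalized linear model of the (transformed) age on CpG betas
#' with the elastic-net mixing parameter fixed at `alpha = 0.5` (midway
#' between ridge and lasso; not tuned). The penalty strength is chosen
#' automatically by tenfold internal cross-validation minimizing mean
#' squared error (`lambda.min` rule). For dual-species targets each
#' species' samples are transformed with that species' own parameters.
#' Only probes with nonzero coefficients are retained in the model.
#'
#' @param mat samples x probes beta matrix.
#' @param sheet aligned sample sheet (same row order as `mat`).
#' @param species_params species parameter table (`species`,
#'   `max_lifespan`, `maturity`, `offset`).
#' @param target `"raw_age"`, `"loglinear"` or `"relative"`.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param seed integer seed fixing the internal fold assignment.
#' @param weights optional per-sample weights; samples with weight 0 are
#'   dropped before fitting (so zeroing one species exactly reproduces the
#'   single-species clock).
#' @param nfolds internal cross-validation folds (default 10).
#' @return a `clock_model`.
#' @export
train_clock <- function(mat, sheet, species_params,
                        target = c("raw_age", "loglinear", "relative"),
                        alpha = 0.5, seed = 1L, weights = NULL,
                        nfolds = 10L) {
  target <- match.arg(target)
  stopifnot(nrow(mat) == nrow(sheet))
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(mat), all(weights >= 0))
    keep <- weights > 0
    mat <- mat[keep, , drop = FALSE]
    sheet <- sheet[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  n <- nrow(mat)
  if (n < 20)
    stop("need at least 20 samples to train a clock (got ", n, ")",
         call. = FALSE)
  if (n < nfolds)
    stop("fewer samples than internal folds", call. = FALSE)
  y <- .build_targets_vec(sheet, species_params, target)
  if (stats::sd(y) == 0)
    stop("constant regression target; cannot fit a clock", call. = FALSE)
  x <- .impute_means(mat)
  set.seed(seed)
  fit <- glmnet::cv.glmnet(x, y, alpha = alpha, nfolds = nfolds,
                           family = "gaussian", standardize = TRUE,
                           weights = weights)
  cf <- as.matrix(stats::coef(fit, s = "lambda.min"))
  intercept <- cf[1, 1]
  nz <- which(cf[-1, 1] != 0)
  sp_used <- unique(sheet$species)
  tr <- species_params[species_params$species %in% sp_used, , drop = FALSE]
  new_clock_model(probes = colnames(mat)[nz],
                  coefficients = cf[-1, 1][nz],
                  intercept = intercept, alpha = alpha,
                  lambda = fit$lambda.min, target_kind = target,
                  transforms = tr[, c("species", "maturity", "offset",
                                      "max_lifespan")],
                  training_species = sp_used)
}

# Vectorized target construction (per-sample species parameters).
.build_targets_vec <- function(sheet, species_params, target_kind) {
  idx <- match(sheet$species, species_params$species)
  if (anyNA(idx))
    stop("species without parameters: ",
         paste(unique(sheet$species[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  sp <- species_params[idx, , drop = FALSE]
  switch(target_kind,
         raw_age   = sheet$age,
         loglinear = loglinear_age_vec(sheet$age, sp$maturity, sp$offset),
         relative  = sheet$age / sp$max_lifespan,
         stop("unknown target kind: ", target_kind))
}

#' Predict DNAm age with a trained clock
#'
#' Computes the linear score `intercept + sum(coef * beta)` over the
#' model's CpGs (aligned by probe id, so column order is irrelevant) and
#' applies the model's inverse age transform per sample. Chronological
#' clocks report years; relative-age clocks report the lifespan ratio.
#'
#' For species absent from the model's transform table a chronological
#' clock falls back to the transform of `fallback_species` (by default the
#' first training species), matching how such clocks are applied
#' unchanged to new species; a relative-age clock needs no parameters to
#' report the ratio (its truth, however, does — see
#' [transfer_evaluate()]).
#'
#' @param model a `clock_model`.
#' @param mat samples x probes beta matrix containing the model's probes.
#' @param sheet aligned sample sheet (needed for per-species inverse
#'   transforms; may be omitted for `raw_age` models).
#' @param fallback_species species whose transform is used for samples of
#'   species the model was not trained on.
#' @param missing_probes `"error"` (default) or `"impute"`: mean-impute a
#'   missing model probe from the available samples with a warning.
#' @param floor_zero clamp negative predicted ages at 0.
#' @return numeric vector of predictions, named by sample id.
#' @export
predict_clock <- function(model, mat, sheet = NULL,
                          fallback_species = model$training_species[1],
                          missing_probes = c("error", "impute"),
                          floor_zero = FALSE) {
  stopifnot(inherits(model, "clock_model"))
  missing_probes <- match.arg(missing_probes)
  miss <- setdiff(model$probes, colnames(mat))
  if (length(miss)) {
    if (missing_probes == "error")
      stop(length(miss), " model probe(s) absent from matrix: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    warning(length(miss), " missing model probe(s) imputed at 0.5")
    fill <- matrix(0.5, nrow(mat), length(miss),
                   dimnames = list(rownames(mat), miss))
    mat <- cbind(mat, fill)
  }
  score <- as.numeric(model$intercept)
  if (length(model$probes)) {
    x <- mat[, model$probes, drop = FALSE]
    if (anyNA(x)) x <- .impute_means(x)
    score <- model$intercept + as.numeric(x %*% model$coefficients)
  } else {
    score <- rep(model$intercept, nrow(mat))
  }
  names(score) <- rownames(mat)

  if (model$target_kind %in% c("raw_age", "relative")) {
    return(if (floor_zero) pmax(score, 0) else score)
  }
  # loglinear: invert with each sample's species parameters.
  if (is.null(sheet))
    stop("loglinear clocks need a sample sheet for the inverse transform",
         call. = FALSE)
  stopifnot(nrow(mat) == nrow(sheet))
  tr <- model$transforms
  idx <- match(sheet$species, tr$species)
  if (anyNA(idx)) {
    fi <- match(fallback_species, tr$species)
    if (is.na(fi))
      stop("fallback species has no transform parameters: ",
           fallback_species, call. = FALSE)
    idx[is.na(idx)] <- fi
  }
  pred <- mapply(loglinear_inverse, score, tr$maturity[idx], tr$offset[idx],
                 MoreArgs = list(floor_zero = floor_zero))
  names(pred) <- rownames(mat)
  pred
}

#' Accuracy metrics for age predictions
#'
#' Pearson correlation R and median absolute error (MedAE) between
#' predictions and truth, overall and per group. R measures rank/linear
#' agreement and is invariant to affine miscalibration; MedAE is not —
#' the pair separates rank-order accuracy from calibration.
#'
#' @param pred numeric predictions.
#' @param truth numeric true ages (same length, `>= 3`).
#' @param groups optional grouping factor (e.g. species) for per-group
#'   rows.
#' @return data frame with columns `group`, `n`, `R`, `medae`; the first
#'   row is `group = "overall"`.
#' @export
evaluate_predictions <- function(pred, truth, groups = NULL) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(truth) == 0)
    stop("zero-variance truth; correlation undefined", call. = FALSE)
  row1 <- data.frame(group = "overall", n = length(pred),
                     R = if (stats::sd(pred) > 0) stats::cor(pred, truth)
                         else NA_real_,
                     medae = stats::median(abs(pred - truth)),
                     stringsAsFactors = FALSE)
  if (is.null(groups)) return(row1)
  stopifnot(length(groups) == length(pred))
  per <- lapply(split(seq_along(pred), groups), function(i) {
    data.frame(group = as.character(groups[i[1]]), n = length(i),
               R = if (length(i) >= 3 && stats::sd(truth[i]) > 0 &&
                       stats::sd(pred[i]) > 0)
                 stats::cor(pred[i], truth[i]) else NA_real_,
               medae = stats::median(abs(pred[i] - truth[i])),
               stringsAsFactors = FALSE)
  })
  out <- rbind(row1, do.call(rbind, per))
  rownames(out) <- NULL
  out
}

# Assemble a CVResult from out-of-fold predictions.
.cv_result <- function(pred, sheet, fold, target_kind, species_params) {
  truth <- switch(target_kind,
                  relative = .build_targets_vec(sheet, species_params,
                                                "relative"),
                  sheet$age)
  metrics <- evaluate_predictions(pred, truth, groups = sheet$species)
  structure(list(predictions = data.frame(sample_id = sheet$sample_id,
                                          species = sheet$species,
                                          truth = truth, pred = pred,
                                          fold = fold,
                                          stringsAsFactors = FALSE),
                 metrics = metrics, target_kind = target_kind),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated clock (", x$target_kind, " target), ",
      nrow(x$predictions), " out-of-fold predictions\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out cross-validation of a clock
#'
#' Refits the clock `n` times, each excluding one sample, and predicts
#' that sample with the excluded-fit model. The assembled out-of-fold
#' predictions give unbiased (or at least less biased) estimates of the
#' age correlation R and the median absolute error.
#'
#' @inheritParams train_clock
#' @return a `cv_result`: per-sample out-of-fold predictions with fold
#'   bookkeeping, plus overall and per-species metrics. Chronological
#'   targets are scored in years, relative targets on the ratio scale.
#' @export
loocv <- function(mat, sheet, species_params,
                  target = c("raw_age", "loglinear", "relative"),
                  alpha = 0.5, seed = 1L, nfolds = 10L) {
  target <- match.arg(target)
  stopifnot(nrow(mat) == nrow(sheet))
  n <- nrow(mat)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      train_clock(mat[-i, , drop = FALSE], sheet[-i, , drop = FALSE],
                  species_params, target = target, alpha = alpha,
                  seed = seed, nfolds = nfolds),
      error = function(e) stop("LOOCV fold ", i, " (leaving out ",
                               sheet$sample_id[i], ") failed: ",
                               conditionMessage(e), call. = FALSE))
    pred[i] <- predict_clock(fit, mat[i, , drop = FALSE],
                             sheet[i, , drop = FALSE])
  }
  names(pred) <- sheet$sample_id
  .cv_result(pred, sheet, fold = seq_len(n), target_kind = target,
             species_params = species_params)
}

#' k-fold external cross-validation of a clock
#'
#' Random folds, by default stratified by species so that every training
#' fold contains all species (required for dual-species clocks); fold
#' sizes within a stratum differ by at most one. `k = n` reduces exactly
#' to leave-one-out (the assignment becomes deterministic).
#'
#' @inheritParams train_clock
#' @param k number of folds (default 10).
#' @param stratify_by_species balance species across folds (default TRUE).
#' @return a `cv_result` (see [loocv()]).
#' @export
kfold_cv <- function(mat, sheet, species_params,
                     target = c("raw_age", "loglinear", "relative"),
                     k = 10L, stratify_by_species = TRUE,
                     alpha = 0.5, seed = 1L, nfolds = 10L) {
  target <- match.arg(target)
  stopifnot(nrow(mat) == nrow(sheet))
  n <- nrow(mat)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of samples", call. = FALSE)
  if (k == n) {
    fold <- seq_len(n)
  } else {
    set.seed(seed)
    fold <- integer(n)
    strata <- if (stratify_by_species) split(seq_len(n), sheet$species)
              else list(seq_len(n))
    for (idx in strata) {
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  pred <- numeric(n)
  for (f in sort(unique(fold))) {
    hold <- fold == f
    fit <- tryCatch(
      train_clock(mat[!hold, , drop = FALSE], sheet[!hold, , drop = FALSE],
                  species_params, target = target, alpha = alpha,
                  seed = seed, nfolds = nfolds),
      error = function(e) stop("fold ", f, " failed: ",
                               conditionMessage(e), call. = FALSE))
    pred[hold] <- predict_clock(fit, mat[hold, , drop = FALSE],
                                sheet[hold, , drop = FALSE])
  }
  names(pred) <- sheet$sample_id
  .cv_result(pred, sheet, fold = fold, target_kind = target,
             species_params = species_params)
}
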