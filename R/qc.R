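# Sample quality control: inter-array correlation clustering, sex-mismatch
# flagging, and random-forest out-of-bag trait prediction.

#' Inter-array Pearson correlation matrix
#'
#' Pairwise Pearson correlation between samples over their shared
#' non-missing probes (pairwise complete observations). High values
#' (R > 0.97 on a real array) indicate good technical quality.
#'
#' @param mat samples x probes beta matrix, at least 2 samples and 2
#'   probes.
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
interarray_correlation <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 2)
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("zero-variance sample(s): ",
         paste(rownames(mat)[!is.finite(sds) | sds == 0], collapse = ", "),
         call. = FALSE)
  cc <- stats::cor(t(mat), use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' Average-linkage clustering of samples
#'
#' Hierarchical clustering of the inter-array correlation matrix using
#' distance `1 - correlation` and average linkage (UPGMA). Low merge
#' heights correspond to high inter-array correlation.
#'
#' @param corr symmetric correlation matrix (from
#'   [interarray_correlation()]).
#' @return an [stats::hclust] tree with `n - 1` monotone merges.
#' @export
average_linkage_tree <- function(corr) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix is not symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(1 - corr), method = "average")
}

#' Export a sample dendrogram as Newick
#'
#' @param tree an [stats::hclust] tree.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Flag samples whose annotated sex disagrees with their methylation
#' neighborhood
#'
#' On a real array, samples cluster by sex through the sex-linked probes;
#' a sample whose annotated sex differs from that of its neighboring
#' samples is a likely labeling error. This is operationalized
#' deterministically: a sample is flagged when its annotated sex differs
#' from the strict majority sex of its `k` nearest neighbors by
#' inter-array correlation (neighbors restricted to samples with a known
#' sex label; ties do not flag).
#'
#' @param mat samples x probes beta matrix.
#' @param sheet aligned sample sheet with a `sex` column
#'   (`female` / `male` / `unknown`).
#' @param k neighbor count (default 5); must leave at least `k` labeled
#'   neighbors per sample.
#' @return character vector of flagged sample ids; attribute `"detail"`
#'   holds a data frame with each flagged sample's annotated and
#'   neighborhood-majority sex.
#' @export
flag_sex_mismatches <- function(mat, sheet, k = 5L) {
  stopifnot(nrow(mat) == nrow(sheet))
  known <- sheet$sex %in% c("female", "male")
  if (k >= nrow(mat)) stop("k must be smaller than the sample count",
                           call. = FALSE)
  if (sum(known) < k + 1)
    stop("need at least k + 1 samples with known sex", call. = FALSE)
  cc <- interarray_correlation(mat)
  flagged <- character(0)
  detail <- list()
  for (i in which(known)) {
    cand <- setdiff(which(known), i)
    nb <- cand[order(cc[i, cand], decreasing = TRUE)[seq_len(k)]]
    votes <- table(sheet$sex[nb])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1 && top != sheet$sex[i]) {
      flagged <- c(flagged, sheet$sample_id[i])
      detail[[length(detail) + 1]] <-
        data.frame(sample_id = sheet$sample_id[i],
                   annotated = sheet$sex[i], neighborhood = top,
                   stringsAsFactors = FALSE)
    }
  }
  attr(flagged, "detail") <- if (length(detail)) do.call(rbind, detail)
    else data.frame(sample_id = character(0), annotated = character(0),
                    neighborhood = character(0))
  flagged
}

#' Random-forest out-of-bag accuracy for a categorical trait
#'
#' Fits a random forest of the trait on the beta matrix (500 trees,
#' `sqrt(p)` candidate features per split) and reports the out-of-bag
#' misclassification rate — an internal cross-validation estimate that
#' needs no held-out set. OOB votes are tallied per sample; vote ties are
#' broken toward the alphabetically first class so the result is
#' deterministic given the seed.
#'
#' @param mat samples x probes beta matrix.
#' @param labels character or factor trait labels, one per sample; `NA`s
#'   are dropped.
#' @param subset optional logical vector selecting samples before fitting
#'   (e.g. `sheet$age < 0.8` to decorrelate a trait from age).
#' @param n_trees number of trees (default 500).
#' @param seed integer RNG seed.
#' @return OOB misclassification rate in \[0,1\]; attributes
#'   `"confusion"` (true x predicted table) and `"n"` (samples used).
#' @export
oob_trait_accuracy <- function(mat, labels, subset = NULL,
                               n_trees = 500L, seed = 1L) {
  stopifnot(nrow(mat) == length(labels))
  keep <- !is.na(labels)
  if (!is.null(subset)) {
    stopifnot(length(subset) == length(labels))
    keep <- keep & subset
  }
  x <- mat[keep, , drop = FALSE]
  y <- factor(as.character(labels[keep]))
  if (nlevels(y) < 2)
    stop("need at least 2 classes after subsetting", call. = FALSE)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  votes <- rf$votes  # OOB vote fractions, rows sum to 1
  pred <- apply(votes, 1, function(v) {
    top <- colnames(votes)[v == max(v)]
    sort(top)[1]  # alphabetical tie-break
  })
  err <- mean(pred != as.character(y))
  structure(err,
            confusion = table(truth = y, predicted = factor(pred,
                                                            levels(y))),
            n = length(y))
}

#' Assemble a QC report for a methylation panel
#'
#' Runs [interarray_correlation()], [average_linkage_tree()],
#' [flag_sex_mismatches()] and (when sex labels exist)
#' [oob_trait_accuracy()] for sex, and bundles the summaries.
#'
#' @param mat samples x probes beta matrix.
#' @param sheet aligned sample sheet.
#' @param k neighbor count for the sex-mismatch rule.
#' @param n_trees,seed forwarded to [oob_trait_accuracy()].
#' @return a `qc_report` list: min/median inter-array correlation, the
#'   dendrogram, flagged samples with reasons, OOB results.
#' @export
qc_report <- function(mat, sheet, k = 5L, n_trees = 500L, seed = 1L) {
  cc <- interarray_correlation(mat)
  off <- cc[upper.tri(cc)]
  tree <- average_linkage_tree(cc)
  flags <- tryCatch(flag_sex_mismatches(mat, sheet, k = k),
                    error = function(e) {
                      warning("sex-mismatch check skipped: ",
                              conditionMessage(e))
                      character(0)
                    })
  flagged <- if (length(flags))
    data.frame(sample_id = as.vector(flags), reason = "sex_mismatch",
               stringsAsFactors = FALSE)
  else data.frame(sample_id = character(0), reason = character(0))
  oob <- list()
  if (sum(sheet$sex %in% c("female", "male")) >= 10 &&
      length(unique(sheet$sex[sheet$sex %in% c("female", "male")])) == 2) {
    known <- sheet$sex %in% c("female", "male")
    labels <- ifelse(known, sheet$sex, NA_character_)
    oob$sex <- as.numeric(oob_trait_accuracy(mat, labels,
                                             n_trees = n_trees,
                                             seed = seed))
  }
  structure(list(min_correlation = min(off),
                 median_correlation = stats::median(off),
                 tree = tree, flagged = flagged, oob = oob),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  inter-array correlation: min %.4f, median %.4f\n",
              x$min_correlation, x$median_correlation))
  cat("  flagged samples:", if (nrow(x$flagged)) nrow(x$flagged) else "none",
      "\n")
  if (nrow(x$flagged)) print(x$flagged, row.names = FALSE)
  for (trait in names(x$oob)) {
    cat(sprintf("  OOB error (%s): %.3f\n", trait, x$oob[[trait]]))
  }
  invisible(x)
}

#' Write a QC report summary as JSON (plus optional Newick dendrogram)
#'
#' @param report a `qc_report`.
#' @param path JSON output path.
#' @param newick_path optional path for a Newick export of the dendrogram.
#' @return invisibly, `path`.
#' @export
write_qc_report <- function(report, path, newick_path = NULL) {
  out <- list(min_correlation = report$min_correlation,
              median_correlation = report$median_correlation,
              flagged = report$flagged, oob = report$oob)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(newick_path)) write_dendrogram_newick(report$tree,
                                                     newick_path)
  invisible(path)
}
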