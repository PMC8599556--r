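# Epigenome-wide association of age: per-CpG correlation-test Z
# statistics, Stouffer combination across tissues, top-CpG selection, and
# genomic-context summaries.

#' Correlation-test Z statistic for one probe
#'
#' The screening statistic chain: Pearson `r` between ages and betas;
#' Student `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of
#' freedom; two-sided `p` from the t distribution; and the signed
#' standard-normal equivalent `z = sign(r) * qnorm(1 - p/2)`. `z` is
#' computed on the log-p scale so it does not underflow, and is capped at
#' `zmax` (default 40) with a saturation flag; at `|r| = 1` the statistic
#' saturates by construction.
#'
#' @param x numeric ages (length `n >= 3`, nonzero variance).
#' @param y numeric betas for one probe (same length, nonzero variance).
#' @param zmax cap on `|z|` (default 40).
#' @return one-row data frame: `n`, `r`, `t`, `p`, `z`, `saturated`,
#'   `valid`.
#' @export
cor_test_z <- function(x, y, zmax = 40) {
  stopifnot(length(x) == length(y))
  n <- sum(is.finite(x) & is.finite(y))
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(n = n, r = NA_real_, t = NA_real_, p = NA_real_,
                      z = NA_real_, saturated = FALSE, valid = FALSE))
  }
  r <- stats::cor(x, y)
  .z_from_r(r, n, zmax)
}

# Vectorized r -> t -> p -> z chain (log-scale p to avoid underflow).
.z_from_r <- function(r, n, zmax = 40) {
  df <- n - 2
  r <- pmin(pmax(r, -1), 1)
  sat_r <- abs(r) >= 1
  t <- ifelse(sat_r, sign(r) * Inf,
              r * sqrt(df) / sqrt(1 - r^2))
  logp <- ifelse(sat_r, -Inf,
                 stats::pt(-abs(t), df, log.p = TRUE) + log(2))
  p <- exp(logp)
  # z = sign(r) * Phi^{-1}(1 - p/2), evaluated from log(p/2)
  zmag <- ifelse(sat_r, Inf,
                 stats::qnorm(logp - log(2), lower.tail = FALSE,
                              log.p = TRUE))
  saturated <- sat_r | zmag >= zmax
  z <- sign(r) * pmin(zmag, zmax)
  z[r == 0] <- 0
  data.frame(n = n, r = r, t = t, p = p, z = z,
             saturated = saturated, valid = TRUE)
}

#' Epigenome-wide screen of age
#'
#' Runs the correlation-test Z chain of [cor_test_z()] over every probe
#' of the matrix (vectorized; identical results to the per-probe loop).
#' Zero-variance probes are marked invalid and excluded downstream.
#'
#' @param mat samples x probes beta matrix.
#' @param ages numeric ages aligned to the matrix rows.
#' @param zmax cap on `|z|`.
#' @return data frame with one row per probe: `probe_id`, `n`, `r`, `t`,
#'   `p`, `z`, `saturated`, `valid`, `direction` (`hyper` / `hypo` /
#'   `none`).
#' @export
ewas_screen <- function(mat, ages, zmax = 40) {
  stopifnot(nrow(mat) == length(ages))
  n <- nrow(mat)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(ages) == 0) stop("ages have zero variance", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  valid <- is.finite(sds) & sds > 0
  r <- rep(NA_real_, ncol(mat))
  r[valid] <- as.numeric(stats::cor(ages, mat[, valid, drop = FALSE]))
  out <- .z_from_r(r, n, zmax)
  out$valid <- valid & is.finite(out$r)
  out[!out$valid, c("r", "t", "p", "z")] <- NA_real_
  out$saturated[!out$valid] <- FALSE
  out <- cbind(probe_id = colnames(mat), out, stringsAsFactors = FALSE)
  out$direction <- ifelse(!out$valid | out$z == 0, "none",
                          ifelse(out$z > 0, "hyper", "hypo"))
  rownames(out) <- NULL
  out
}

#' Stouffer combination of z scores across tissues
#'
#' `Z = sum(w_i * z_i) / sqrt(sum(w_i^2))`, default equal weights.
#' Missing entries (probes absent in a tissue) contribute nothing —
#' they are dropped together with their weights, not treated as `z = 0`.
#'
#' @param z numeric vector of per-tissue z scores for one probe, or a
#'   probes x tissues matrix (combination is row-wise).
#' @param weights optional nonnegative weights, one per tissue.
#' @return combined z (scalar, or vector with one entry per matrix row).
#' @export
stouffer_combine <- function(z, weights = NULL) {
  if (is.matrix(z)) {
    return(apply(z, 1, stouffer_combine, weights = weights))
  }
  if (is.null(weights)) weights <- rep(1, length(z))
  stopifnot(length(weights) == length(z), all(weights >= 0, na.rm = TRUE))
  ok <- is.finite(z) & is.finite(weights)
  if (!any(ok)) stop("no finite z to combine", call. = FALSE)
  z <- z[ok]; w <- weights[ok]
  sum(w * z) / sqrt(sum(w^2))
}

#' Select top age-associated CpGs
#'
#' Keeps probes with `p` below the genome-wide threshold, splits them by
#' direction (sign of `z`), and within each direction retains up to `cap`
#' probes with the most extreme `|z|`. Ties at the boundary are broken by
#' probe id (lexicographically smaller kept), so the selection is
#' deterministic and invariant to input row order.
#'
#' @param records EWAS table from [ewas_screen()] (or any data frame with
#'   `probe_id`, `p`, `z`).
#' @param p_threshold genome-wide significance threshold (default 1e-8).
#' @param cap maximum probes per direction (default 500).
#' @return a `top_cpg_set` list: `hyper` and `hypo` character vectors of
#'   probe ids, plus the threshold and cap used.
#' @export
select_top_cpgs <- function(records, p_threshold = 1e-8, cap = 500L) {
  stopifnot(all(c("probe_id", "p", "z") %in% colnames(records)))
  ok <- !is.na(records$p) & !is.na(records$z) & records$p < p_threshold &
    records$z != 0
  recs <- records[ok, , drop = FALSE]
  pick <- function(side) {
    sub <- recs[sign(recs$z) == side, , drop = FALSE]
    sub <- sub[order(-abs(sub$z), sub$probe_id), , drop = FALSE]
    utils::head(sub$probe_id, cap)
  }
  structure(list(hyper = pick(1), hypo = pick(-1),
                 p_threshold = p_threshold, cap = as.integer(cap)),
            class = "top_cpg_set")
}

#' @export
print.top_cpg_set <- function(x, ...) {
  cat("Top CpG set (p < ", format(x$p_threshold), ", cap ", x$cap,
      " per direction)\n", sep = "")
  cat("  hypermethylated:", length(x$hyper), "\n")
  cat("  hypomethylated: ", length(x$hypo), "\n")
  invisible(x)
}

#' Genomic-region summary of top CpGs
#'
#' Counts top CpGs per region class (relative to the closest TSS) for the
#' hyper- and hypomethylated lists and for a background probe set, and
#' reports per region the proportion of direction-assigned top CpGs that
#' are hypermethylated.
#'
#' @param topset a `top_cpg_set` from [select_top_cpgs()].
#' @param annotation probe annotation data frame (`probe_id`, `region`,
#'   `island`); every top probe must be annotated.
#' @param background character vector of background probe ids (defaults
#'   to all annotated probes).
#' @return data frame with one row per region class: `region`, `hyper`,
#'   `hypo`, `background`, `prop_hyper`.
#' @export
region_summary <- function(topset, annotation,
                           background = annotation$probe_id) {
  stopifnot(inherits(topset, "top_cpg_set"))
  all_top <- c(topset$hyper, topset$hypo)
  missing <- setdiff(all_top, annotation$probe_id)
  if (length(missing))
    stop("unannotated top probe(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  reg <- function(ids) {
    r <- annotation$region[match(ids, annotation$probe_id)]
    table(factor(r, levels = region_classes))
  }
  hyper <- reg(topset$hyper)
  hypo <- reg(topset$hypo)
  bg <- reg(intersect(background, annotation$probe_id))
  out <- data.frame(region = region_classes,
                    hyper = as.integer(hyper),
                    hypo = as.integer(hypo),
                    background = as.integer(bg),
                    stringsAsFactors = FALSE)
  tot <- out$hyper + out$hypo
  out$prop_hyper <- ifelse(tot > 0, out$hyper / tot, NA_real_)
  out
}

#' Island versus non-island association with age
#'
#' Compares the distribution of EWAS z scores between CpG-island probes
#' and other probes: group sizes, mean and median z, and a two-sided
#' Wilcoxon rank-sum p value. A positive island-minus-other difference
#' means islands preferentially gain methylation with age.
#'
#' @param records EWAS table from [ewas_screen()].
#' @param annotation probe annotation with `probe_id` and `island`.
#' @return list with `summary` (per-group n / mean_z / median_z),
#'   `mean_difference` (island minus other) and `rank_sum_p`.
#' @export
island_association_summary <- function(records, annotation) {
  idx <- match(records$probe_id, annotation$probe_id)
  if (anyNA(idx))
    stop("probe(s) missing island annotation: ",
         paste(utils::head(records$probe_id[is.na(idx)], 10),
               collapse = ", "), call. = FALSE)
  island <- annotation$island[idx]
  ok <- !is.na(records$z)
  z <- records$z[ok]; island <- island[ok]
  if (sum(island) < 2 || sum(!island) < 2)
    stop("each group (island / non-island) needs at least 2 probes",
         call. = FALSE)
  sm <- data.frame(group = c("island", "other"),
                   n = c(sum(island), sum(!island)),
                   mean_z = c(mean(z[island]), mean(z[!island])),
                   median_z = c(stats::median(z[island]),
                                stats::median(z[!island])),
                   stringsAsFactors = FALSE)
  wt <- stats::wilcox.test(z[island], z[!island], exact = FALSE)
  list(summary = sm,
       mean_difference = sm$mean_z[1] - sm$mean_z[2],
       rank_sum_p = wt$p.value)
}

#' Write an EWAS table as TSV
#'
#' @param records EWAS table from [ewas_screen()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_ewas_table <- function(records, path) {
  .write_tsv(records[, c("probe_id", "n", "r", "t", "p", "z", "direction")],
             path)
  invisible(path)
}
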