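#' Describe one species in a synthetic methylation panel
#'
#' @param name species name (e.g. `"cat"`).
#' @param n_samples number of samples to simulate; at least 3 (Pearson
#'   correlation downstream is undefined below that).
#' @param age_range numeric length-2, min and max age in years, min < max.
#' @param max_lifespan maximum recorded lifespan in years; drives relative
#'   age and hence the aging trajectory of every age probe.
#' @param maturity age of sexual maturity in years (used by the log-linear
#'   transform when clocks are trained on this species).
#' @param baseline_shift constant added to every beta value of this
#'   species (beta units); models a systematic array/species offset.
#' @param has_age_signal if `FALSE`, age probes are flat in this species
#'   (slope 0) — a negative control for cross-species transfer.
#' @return a `species_spec` list.
#' @export
species_spec <- function(name, n_samples, age_range, max_lifespan,
                         maturity = 1, baseline_shift = 0,
                         has_age_signal = TRUE) {
  stopifnot(is.character(name), nchar(name) > 0)
  if (n_samples < 3)
    stop("n_samples must be >= 3 for species ", name, call. = FALSE)
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be [min, max] with min < max", call. = FALSE)
  if (age_range[1] < 0) stop("ages must be nonnegative", call. = FALSE)
  stopifnot(max_lifespan > 0, maturity > 0, maturity < max_lifespan)
  structure(list(name = name, n_samples = as.integer(n_samples),
                 age_range = as.numeric(age_range),
                 max_lifespan = max_lifespan, maturity = maturity,
                 baseline_shift = baseline_shift,
                 has_age_signal = isTRUE(has_age_signal)),
            class = "species_spec")
}

#' Configuration for the synthetic panel generator
#'
#' The generator emulates a conserved-CpG mammalian methylation array: a
#' minority of probes drift monotonically with *relative* age (shared
#' across species), some probes are sex-linked, some carry species-specific
#' baseline offsets, and the rest are null.
#'
#' @param species list of [species_spec()] objects.
#' @param n_probes total probes on the simulated array.
#' @param n_age_probes probes with a monotone age trend (half gain, half
#'   lose methylation).
#' @param n_sex_probes probes with a sex effect.
#' @param n_species_marker_probes probes with per-species baseline offsets
#'   (these make samples cluster by species).
#' @param age_effect_size beta-value change of an age probe over the full
#'   relative-age range \[0,1\] (default 0.3).
#' @param sex_effect_size absolute male-female beta difference at sex
#'   probes (default 0.15).
#' @param species_offset_sd s.d. of the Gaussian per-species offsets at
#'   marker probes (default 0.1, beta units).
#' @param noise_sd s.d. of Gaussian measurement noise added to every beta
#'   (default 0.03).
#' @param shared_fraction fraction of age probes whose slope is identical
#'   in every species; the remainder keep the probe's sign but draw an
#'   independent magnitude per species.
#' @param seed integer RNG seed; identical seeds give bit-identical panels.
#' @return a `generator_config` list, validated.
#' @export
generator_config <- function(species,
                             n_probes = 1000L,
                             n_age_probes = 100L,
                             n_sex_probes = 20L,
                             n_species_marker_probes = 50L,
                             age_effect_size = 0.3,
                             sex_effect_size = 0.15,
                             species_offset_sd = 0.1,
                             noise_sd = 0.03,
                             shared_fraction = 1,
                             seed = 1L) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 1,
            all(vapply(species, inherits, logical(1), "species_spec")))
  counts <- c(n_probes, n_age_probes, n_sex_probes, n_species_marker_probes)
  if (any(counts < 0) || n_probes <= 0)
    stop("probe counts must be nonnegative and n_probes positive",
         call. = FALSE)
  if (n_age_probes + n_sex_probes + n_species_marker_probes > n_probes)
    stop("special probes exceed n_probes", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  if (age_effect_size < 0 || sex_effect_size < 0 ||
      species_offset_sd < 0 || noise_sd < 0)
    stop("effect sizes and s.d.s must be nonnegative", call. = FALSE)
  nm <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate species names", call. = FALSE)
  structure(list(species = species,
                 n_probes = as.integer(n_probes),
                 n_age_probes = as.integer(n_age_probes),
                 n_sex_probes = as.integer(n_sex_probes),
                 n_species_marker_probes = as.integer(n_species_marker_probes),
                 age_effect_size = age_effect_size,
                 sex_effect_size = sex_effect_size,
                 species_offset_sd = species_offset_sd,
                 noise_sd = noise_sd,
                 shared_fraction = shared_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw sample ages uniformly within a range
#'
#' @param n number of ages, `>= 1`.
#' @param age_range numeric length-2 `[min, max]` in years with
#'   `0 <= min < max`.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used (so the caller's stream continues).
#' @return numeric vector of `n` ages.
#' @export
sample_ages <- function(n, age_range, seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be a positive count", call. = FALSE)
  if (length(age_range) != 2 || !all(is.finite(age_range)) ||
      age_range[1] < 0 || age_range[1] >= age_range[2])
    stop("age_range must satisfy 0 <= min < max", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, age_range[1], age_range[2])
}

# Region vocabulary shared by the annotation generator and the readers.
region_classes <- c("promoter", "5'UTR", "exon", "intron", "3'UTR",
                    "upstream", "downstream", "intergenic")

#' Generate a multi-species synthetic methylation panel
#'
#' Betas follow
#' `beta_ij = clip(b0_j(species_i) + slope_j * relative_age_i +
#' sex_delta_j * male_i + noise, 0, 1)` with Gaussian noise, baselines
#' uniform in \[0.1, 0.9\] (limiting clipping), and ages uniform within
#' each species' range. The aging trajectory is linear in *relative* age
#' (age / max lifespan), so that shared age probes are genuinely
#' cross-species conserved. Probe annotation is generated alongside, with
#' hypermethylating age probes biased toward promoters and CpG islands and
#' hypomethylating ones toward gene bodies and open sea, mirroring the
#' genomic distribution typical of aging methylation.
#'
#' @param config a [generator_config()].
#' @return a list of class `meth_panel` with elements
#'   \describe{
#'     \item{matrix}{samples x probes beta matrix with dimnames.}
#'     \item{sheet}{sample sheet data frame (sample_id, species, tissue,
#'       age, sex, neutered).}
#'     \item{annotation}{probe annotation data frame (probe_id, gene,
#'       region, island, dist_tss).}
#'     \item{truth}{ground-truth data frame: role, per-species slope
#'       columns, sex delta, baseline, per-species offset columns.}
#'     \item{species_params}{data frame species / max_lifespan / maturity /
#'       offset usable by the clock builders.}
#'     \item{clip_fraction}{fraction of betas clipped into \[0,1\].}
#'   }
#' @examples
#' cfg <- generator_config(
#'   species = list(species_spec("cat", 20, c(0.2, 21), 30)),
#'   n_probes = 200, n_age_probes = 40, seed = 7)
#' panel <- generate_panel(cfg)
#' dim(panel$matrix)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  p <- config$n_probes
  sp <- config$species
  ns <- length(sp)
  sp_names <- vapply(sp, `[[`, character(1), "name")

  probe_id <- sprintf("cg%06d", seq_len(p))
  role <- rep("null", p)
  i_age <- seq_len(config$n_age_probes)
  i_sex <- seq_len(config$n_sex_probes) + config$n_age_probes
  i_mark <- seq_len(config$n_species_marker_probes) +
    config$n_age_probes + config$n_sex_probes
  n_pos <- ceiling(config$n_age_probes / 2)
  if (config$n_age_probes > 0) {
    role[i_age] <- c(rep("age+", n_pos),
                     rep("age-", config$n_age_probes - n_pos))
  }
  if (config$n_sex_probes > 0) role[i_sex] <- "sex"
  if (config$n_species_marker_probes > 0) role[i_mark] <- "species-marker"

  # Baselines and effect structure (probe x species slope matrix).
  b0 <- stats::runif(p, 0.1, 0.9)
  slope <- matrix(0, p, ns, dimnames = list(probe_id, sp_names))
  if (config$n_age_probes > 0) {
    sign_j <- ifelse(role[i_age] == "age+", 1, -1)
    shared <- stats::runif(config$n_age_probes) < config$shared_fraction
    mag_shared <- stats::runif(config$n_age_probes, 0.5, 1) *
      config$age_effect_size
    for (s in seq_len(ns)) {
      mag_own <- stats::runif(config$n_age_probes, 0.5, 1) *
        config$age_effect_size
      mag <- ifelse(shared, mag_shared, mag_own)
      slope[i_age, s] <- sign_j * mag
    }
    # Center baseline of age probes so the full-lifespan excursion stays in
    # range: start low for gaining probes, high for losing ones.
    b0[i_age] <- ifelse(sign_j > 0,
                        stats::runif(config$n_age_probes, 0.15, 0.45),
                        stats::runif(config$n_age_probes, 0.55, 0.85))
  }
  sex_delta <- numeric(p)
  if (config$n_sex_probes > 0) {
    sex_delta[i_sex] <- sample(c(-1, 1), config$n_sex_probes,
                               replace = TRUE) * config$sex_effect_size
  }
  sp_offset <- matrix(0, p, ns, dimnames = list(probe_id, sp_names))
  if (config$n_species_marker_probes > 0) {
    sp_offset[i_mark, ] <- stats::rnorm(
      config$n_species_marker_probes * ns, 0, config$species_offset_sd)
  }

  # Samples.
  sheets <- vector("list", ns)
  betas <- vector("list", ns)
  clipped <- 0
  for (s in seq_len(ns)) {
    spc <- sp[[s]]
    n <- spc$n_samples
    age <- sample_ages(n, spc$age_range)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    ids <- sprintf("%s_%03d", spc$name, seq_len(n))
    rel <- age / spc$max_lifespan
    sl <- slope[, s] * if (spc$has_age_signal) 1 else 0
    mu <- matrix(b0 + sp_offset[, s] + spc$baseline_shift,
                 n, p, byrow = TRUE) +
      outer(rel, sl) +
      outer(as.numeric(sex == "male"), sex_delta)
    eps <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    bb <- mu + eps
    clipped <- clipped + sum(bb < 0 | bb > 1)
    bb <- pmin(pmax(bb, 0), 1)
    dimnames(bb) <- list(ids, probe_id)
    betas[[s]] <- bb
    sheets[[s]] <- data.frame(sample_id = ids, species = spc$name,
                              tissue = "blood", age = age, sex = sex,
                              neutered = "unknown",
                              stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, betas)
  sheet <- do.call(rbind, sheets)
  rownames(sheet) <- NULL

  annotation <- .generate_annotation(probe_id, role)

  truth <- data.frame(probe_id = probe_id, role = role,
                      baseline = b0, sex_delta = sex_delta,
                      stringsAsFactors = FALSE)
  for (s in seq_len(ns)) {
    truth[[paste0("slope_", sp_names[s])]] <-
      slope[, s] * if (sp[[s]]$has_age_signal) 1 else 0
    truth[[paste0("offset_", sp_names[s])]] <- sp_offset[, s]
  }

  species_params <- data.frame(
    species = sp_names,
    max_lifespan = vapply(sp, `[[`, numeric(1), "max_lifespan"),
    maturity = vapply(sp, `[[`, numeric(1), "maturity"),
    offset = 0,
    stringsAsFactors = FALSE)

  structure(list(matrix = mat, sheet = sheet, annotation = annotation,
                 truth = truth, species_params = species_params,
                 clip_fraction = clipped / length(mat)),
            class = "meth_panel")
}

# Annotation with realistic genomic-context structure: hypermethylating age
# probes sit mostly in promoters/5'UTRs on CpG islands, hypomethylating ones
# in gene bodies and intergenic open sea; everything else follows a
# background mix.
.generate_annotation <- function(probe_id, role) {
  p <- length(probe_id)
  bg_prob <- c(promoter = 0.15, `5'UTR` = 0.05, exon = 0.15, intron = 0.25,
               `3'UTR` = 0.05, upstream = 0.05, downstream = 0.05,
               intergenic = 0.25)
  hyper_prob <- c(promoter = 0.55, `5'UTR` = 0.15, exon = 0.10,
                  intron = 0.08, `3'UTR` = 0.02, upstream = 0.05,
                  downstream = 0.02, intergenic = 0.03)
  hypo_prob <- c(promoter = 0.05, `5'UTR` = 0.02, exon = 0.15, intron = 0.35,
                 `3'UTR` = 0.08, upstream = 0.05, downstream = 0.05,
                 intergenic = 0.25)
  region <- character(p)
  for (i in seq_len(p)) {
    pr <- switch(role[i], `age+` = hyper_prob, `age-` = hypo_prob, bg_prob)
    region[i] <- sample(region_classes, 1, prob = pr[region_classes])
  }
  island_p <- ifelse(role == "age+", 0.8,
                     ifelse(role == "age-", 0.15, 0.3))
  island <- stats::runif(p) < island_p
  data.frame(probe_id = probe_id,
             gene = sprintf("GENE%04d", 1 + (seq_len(p) - 1) %/% 5),
             region = region, island = island,
             dist_tss = as.integer(round(stats::rnorm(p, 0, 5000))),
             stringsAsFactors = FALSE)
}

#' @export
print.meth_panel <- function(x, ...) {
  cat("Synthetic methylation panel:", nrow(x$matrix), "samples x",
      ncol(x$matrix), "probes\n")
  cat("Species:", paste(unique(x$sheet$species), collapse = ", "), "\n")
  cat("Probe roles:\n")
  print(table(x$truth$role))
  cat(sprintf("Clipped betas: %.3f%%\n", 100 * x$clip_fraction))
  invisible(x)
}

#' Write the four panel tables to a directory
#'
#' Emits `matrix.tsv`, `sheet.tsv`, `annotation.tsv`, `truth.tsv` and
#' `species_params.tsv` as tab-separated files with a single header line.
#'
#' @param panel a `meth_panel` from [generate_panel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "meth_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             sheet = file.path(dir, "sheet.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"),
             species_params = file.path(dir, "species_params.tsv"))
  write_beta_matrix(panel$matrix, paths["matrix"])
  .write_tsv(panel$sheet, paths["sheet"])
  .write_tsv(panel$annotation, paths["annotation"])
  .write_tsv(panel$truth, paths["truth"])
  .write_tsv(panel$species_params, paths["species_params"])
  invisible(paths)
}
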