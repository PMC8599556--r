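# Readers/writers for the tables the pipeline touches. All files are plain
# delimited text; numeric columns are serialized with 17 significant digits
# so that write -> read round-trips doubles bit-exactly.

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.double(df2[[j]])) df2[[j]] <- .fmt_num(df2[[j]])
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a methylation beta matrix
#'
#' @param mat numeric matrix, samples as rows, probes as columns, with
#'   dimnames set.
#' @param path output file.
#' @param orientation `"samples"` writes samples as rows (first column
#'   `sample_id`, header of probe ids); `"probes"` writes the transpose
#'   (first column `probe_id`, header of sample ids) for vendors that ship
#'   probes-as-rows tables.
#' @param sep field separator, tab by default.
#' @return invisibly, `path`.
#' @export
write_beta_matrix <- function(mat, path, orientation = c("samples", "probes"),
                              sep = "\t") {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (orientation == "probes") mat <- t(mat)
  idcol <- if (orientation == "samples") "sample_id" else "probe_id"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(idcol, colnames(mat)), collapse = sep), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], .fmt_num(mat[i, ])), collapse = sep)
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a methylation beta matrix
#'
#' Expects a delimited table whose first column holds ids and whose header
#' row names the other axis; `orientation` says which axis the file's rows
#' are. The result is always samples-as-rows internally.
#'
#' @param path input file (tab- or comma-separated; sniffed from the
#'   header line unless `sep` is given).
#' @param orientation `"samples"` if file rows are samples, `"probes"` if
#'   file rows are probes (the matrix is transposed on read).
#' @param strict if `TRUE` (default) any value outside \[0,1\] is an
#'   error; if `FALSE` such values are set to `NA` with a warning.
#' @param sep optional explicit separator.
#' @return numeric matrix, samples x probes, beta values in \[0,1\] or `NA`.
#' @export
read_beta_matrix <- function(path, orientation = c("samples", "probes"),
                             strict = TRUE, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE,
                          comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ids in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  other <- colnames(df)[-1]
  if (anyDuplicated(other)) {
    stop("duplicate ids in header: ",
         paste(unique(other[duplicated(other)]), collapse = ", "),
         call. = FALSE)
  }
  body <- df[, -1, drop = FALSE]
  nonnum <- !vapply(body, is.numeric, logical(1))
  if (any(nonnum)) {
    stop("non-numeric cells in column(s): ",
         paste(other[nonnum], collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(body)
  rownames(mat) <- ids
  bad <- is.finite(mat) & (mat < 0 | mat > 1)
  if (any(bad)) {
    if (strict) {
      stop(sum(bad), " beta value(s) outside [0,1]; ",
           "use strict = FALSE to mask them as NA", call. = FALSE)
    }
    warning(sum(bad), " beta value(s) outside [0,1] set to NA")
    mat[bad] <- NA_real_
  }
  if (orientation == "probes") mat <- t(mat)
  mat
}

#' Read / write a sample sheet
#'
#' Columns: `sample_id`, `species`, `tissue`, `age` (years), `sex`
#' (`female`/`male`/`unknown`), `neutered` (`yes`/`no`/`unknown`).
#'
#' @param path file path.
#' @return `read_sample_sheet`: validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "age")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"tissue" %in% colnames(df)) df$tissue <- "unknown"
  if (!"sex" %in% colnames(df)) df$sex <- "unknown"
  if (!"neutered" %in% colnames(df)) df$neutered <- "unknown"
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sheet", call. = FALSE)
  if (any(!is.finite(df$age)) || any(df$age < 0))
    stop("ages must be finite and nonnegative", call. = FALSE)
  bad_sex <- !df$sex %in% c("female", "male", "unknown")
  if (any(bad_sex))
    stop("invalid sex value(s): ", paste(unique(df$sex[bad_sex]),
                                         collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  .write_tsv(sheet, path)
  invisible(path)
}

#' Read / write a species parameter table
#'
#' Columns: `species`, `max_lifespan` (years), `maturity` (years),
#' `offset` (years, used inside the log-linear transform). Requires
#' `0 < maturity < max_lifespan` and `offset >= 0`.
#'
#' @param path file path.
#' @return data frame of species parameters.
#' @export
read_species_params <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("species", "max_lifespan", "maturity")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("species params missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"offset" %in% colnames(df)) df$offset <- 0
  validate_species_params(df)
  df
}

#' @rdname read_species_params
#' @param params species parameter data frame.
#' @export
write_species_params <- function(params, path) {
  validate_species_params(params)
  .write_tsv(params, path)
  invisible(path)
}

validate_species_params <- function(params) {
  with(params, {
    if (any(maturity <= 0) || any(maturity >= max_lifespan))
      stop("require 0 < maturity < max_lifespan for every species",
           call. = FALSE)
    if (any(offset < 0)) stop("transform offset must be >= 0", call. = FALSE)
  })
  if (anyDuplicated(params$species))
    stop("duplicate species in parameter table", call. = FALSE)
  invisible(params)
}

#' Read a probe annotation table
#'
#' Columns: `probe_id`, optional `gene`, `region` (one of the closed
#' vocabulary promoter / 5'UTR / exon / intron / 3'UTR / upstream /
#' downstream / intergenic), `island` (logical), optional `dist_tss`.
#'
#' @param path file path.
#' @return validated annotation data frame.
#' @export
read_probe_annotation <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "region", "island")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !df$region %in% region_classes
  if (any(bad))
    stop("unknown region class(es): ",
         paste(unique(df$region[bad]), collapse = ", "), call. = FALSE)
  df$island <- as.logical(df$island)
  if (anyNA(df$island))
    stop("island flag must be defined for every probe", call. = FALSE)
  df
}

#' Align a methylation matrix with a sample sheet
#'
#' Reorders both to the matrix's sample order restricted to the common
#' ids; unmatched ids on either side are dropped with a warning naming
#' them.
#'
#' @param mat samples x probes beta matrix.
#' @param sheet sample sheet data frame with a `sample_id` column.
#' @return list with elements `matrix` and `sheet`, row-aligned.
#' @export
align_samples <- function(mat, sheet) {
  common <- intersect(rownames(mat), sheet$sample_id)
  if (length(common) == 0)
    stop("no sample ids shared between matrix and sheet", call. = FALSE)
  drop_m <- setdiff(rownames(mat), common)
  drop_s <- setdiff(sheet$sample_id, common)
  if (length(drop_m) || length(drop_s)) {
    warning("dropped unmatched sample id(s): ",
            paste(c(drop_m, drop_s), collapse = ", "))
  }
  ord <- rownames(mat)[rownames(mat) %in% common]
  sheet2 <- sheet[match(ord, sheet$sample_id), , drop = FALSE]
  rownames(sheet2) <- NULL
  list(matrix = mat[ord, , drop = FALSE], sheet = sheet2)
}

#' Write a clock model to a flat file
#'
#' Two-part format: a metadata header of `# key<TAB>value` lines
#' (target kind, alpha, lambda, intercept, training species, and one
#' `# transform` line per species carrying maturity / offset /
#' max lifespan), then tab-separated `probe` / `coefficient` records.
#' Decimals are written with 17 significant digits, so a read-back model
#' predicts bit-identically.
#'
#' @param model a `clock_model` (see [train_clock()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("# format\tclockforge-clock-v1"),
    paste0("# target_kind\t", model$target_kind),
    paste0("# alpha\t", .fmt_num(model$alpha)),
    paste0("# lambda\t", .fmt_num(model$lambda)),
    paste0("# intercept\t", .fmt_num(model$intercept)),
    paste0("# training_species\t",
           paste(model$training_species, collapse = ",")))
  tr <- model$transforms
  for (i in seq_len(nrow(tr))) {
    hdr <- c(hdr, paste0("# transform\t", tr$species[i], "\t",
                         .fmt_num(tr$maturity[i]), "\t",
                         .fmt_num(tr$offset[i]), "\t",
                         .fmt_num(tr$max_lifespan[i])))
  }
  writeLines(hdr, con)
  writeLines("probe\tcoefficient", con)
  if (length(model$probes)) {
    writeLines(paste(model$probes, .fmt_num(model$coefficients), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read a clock model written by [write_clock()]
#'
#' @param path clock file.
#' @return a `clock_model`.
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  fields <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  keys <- vapply(fields, `[[`, character(1), 1L)
  get1 <- function(key) {
    i <- which(keys == key)
    if (!length(i)) stop("clock file missing field: ", key, call. = FALSE)
    fields[[i[1]]][2]
  }
  target_kind <- get1("target_kind")
  alpha <- as.numeric(get1("alpha"))
  lambda <- as.numeric(get1("lambda"))
  intercept <- as.numeric(get1("intercept"))
  training_species <- strsplit(get1("training_species"), ",",
                               fixed = TRUE)[[1]]
  tri <- which(keys == "transform")
  transforms <- data.frame(
    species = vapply(fields[tri], `[[`, character(1), 2L),
    maturity = as.numeric(vapply(fields[tri], `[[`, character(1), 3L)),
    offset = as.numeric(vapply(fields[tri], `[[`, character(1), 4L)),
    max_lifespan = as.numeric(vapply(fields[tri], `[[`, character(1), 5L)),
    stringsAsFactors = FALSE)
  miss <- setdiff(training_species, transforms$species)
  if (length(miss))
    stop("missing transform parameters for training species: ",
         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(identical(body[1], "probe\tcoefficient"))
  recs <- body[-1]
  recs <- recs[nzchar(recs)]
  if (length(recs)) {
    parts <- strsplit(recs, "\t", fixed = TRUE)
    probes <- vapply(parts, `[[`, character(1), 1L)
    coefs <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  } else {
    probes <- character(0)
    coefs <- numeric(0)
  }
  new_clock_model(probes = probes, coefficients = coefs,
                  intercept = intercept, alpha = alpha, lambda = lambda,
                  target_kind = target_kind, transforms = transforms,
                  training_species = training_species)
}
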