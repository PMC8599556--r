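#' Age transform specification
#'
#' Describes how chronological age is mapped to the regression target of a
#' clock. Three kinds are supported:
#' \describe{
#'   \item{`raw_age`}{identity; the clock is trained on age in years.}
#'   \item{`loglinear`}{logarithmic below the age of sexual maturity and
#'     linear above it, continuous and differentiable at maturity; used for
#'     dual-species chronological-age clocks so that the fast epigenetic
#'     changes of development and the slower changes of adulthood are on
#'     comparable scales.}
#'   \item{`relative`}{age divided by the species' maximum recorded
#'     lifespan, a dimensionless ratio in \[0,1\] that aligns species with
#'     very different lifespans.}
#' }
#'
#' @param kind one of `"raw_age"`, `"loglinear"`, `"relative"`.
#' @param maturity age of sexual maturity in years (`loglinear` only); must
#'   be positive.
#' @param offset nonnegative offset in years added inside the logarithm so
#'   that newborn ages remain finite.
#' @param max_lifespan maximum recorded lifespan in years (`relative` only).
#' @return an object of class `age_transform`.
#' @examples
#' sp <- age_transform("loglinear", maturity = 1, offset = 0)
#' loglinear_age(0.5, maturity = 1)
#' @export
age_transform <- function(kind = c("raw_age", "loglinear", "relative"),
                          maturity = NULL, offset = 0, max_lifespan = NULL) {
  kind <- match.arg(kind)
  if (kind == "loglinear") {
    if (is.null(maturity) || !is.finite(maturity) || maturity <= 0)
      stop("loglinear transform requires maturity > 0", call. = FALSE)
    if (!is.finite(offset) || offset < 0)
      stop("offset must be nonnegative", call. = FALSE)
  }
  if (kind == "relative") {
    if (is.null(max_lifespan) || !is.finite(max_lifespan) || max_lifespan <= 0)
      stop("relative transform requires max_lifespan > 0", call. = FALSE)
  }
  structure(list(kind = kind, maturity = maturity, offset = offset,
                 max_lifespan = max_lifespan),
            class = "age_transform")
}

#' Log-linear age transform
#'
#' `F(a) = log((a + offset) / (m + offset))` for `a < m` and
#' `F(a) = (a - m) / (m + offset)` for `a >= m`, where `m` is the age of
#' maturity. The two branches meet at `F(m) = 0` with common slope
#' `1 / (m + offset)`, so the transform is continuous and differentiable
#' everywhere on its domain and strictly increasing.
#'
#' @param age chronological age(s) in years, `>= 0`.
#' @param maturity age of maturity `m` in years, `> 0`.
#' @param offset nonnegative offset in years; `age + offset` must be
#'   positive.
#' @return transformed value(s), unbounded below, unbounded above.
#' @seealso [loglinear_inverse()]
#' @export
loglinear_age <- function(age, maturity, offset = 0) {
  stopifnot(is.numeric(age), is.finite(maturity), maturity > 0,
            is.finite(offset), offset >= 0)
  if (any(age + offset <= 0, na.rm = TRUE))
    stop("age + offset must be positive", call. = FALSE)
  ifelse(age < maturity,
         log((age + offset) / (maturity + offset)),
         (age - maturity) / (maturity + offset))
}

#' Inverse of the log-linear age transform
#'
#' Maps a transformed value back to years:
#' `a = (m + offset) * exp(y) - offset` for `y < 0` and
#' `a = y * (m + offset) + m` for `y >= 0`. Exact inverse of
#' [loglinear_age()] on the whole real line. Large negative `y` approach
#' `-offset` from above; set `floor_zero = TRUE` to clamp reported ages at 0.
#'
#' @param y transformed value(s) (any real number).
#' @inheritParams loglinear_age
#' @param floor_zero clamp results below 0 to 0 (reporting convenience).
#' @return age(s) in years.
#' @export
loglinear_inverse <- function(y, maturity, offset = 0, floor_zero = FALSE) {
  stopifnot(is.numeric(y), is.finite(maturity), maturity > 0,
            is.finite(offset), offset >= 0)
  age <- ifelse(y < 0,
                (maturity + offset) * exp(y) - offset,
                y * (maturity + offset) + maturity)
  if (floor_zero) age <- pmax(age, 0)
  age
}

#' Relative age
#'
#' The ratio of chronological age to the species' maximum recorded
#' lifespan: `age / max_lifespan`. Dimensionless; not clamped, so values
#' above 1 are possible for an animal older than the recorded maximum.
#'
#' @param age chronological age(s) in years, `>= 0`.
#' @param max_lifespan maximum recorded lifespan in years, `> 0`.
#' @return ratio(s) of age to maximum lifespan.
#' @examples
#' relative_age(15, 30)   # a middle-aged cat
#' relative_age(61, 122)  # the equivalent human
#' @export
relative_age <- function(age, max_lifespan) {
  stopifnot(is.numeric(age), is.numeric(max_lifespan))
  if (any(!is.finite(max_lifespan)) || any(max_lifespan <= 0))
    stop("max_lifespan must be positive", call. = FALSE)
  if (any(age < 0, na.rm = TRUE))
    stop("age must be nonnegative", call. = FALSE)
  age / max_lifespan
}

# Apply a transform spec to a vector of ages (internal).
apply_age_transform <- function(spec, age) {
  switch(spec$kind,
         raw_age   = age,
         loglinear = loglinear_age(age, spec$maturity, spec$offset),
         relative  = relative_age(age, spec$max_lifespan),
         stop("unknown transform kind: ", spec$kind))
}

# Invert a transform spec on the linear-predictor scale (internal).
invert_age_transform <- function(spec, y, floor_zero = FALSE) {
  switch(spec$kind,
         raw_age   = if (floor_zero) pmax(y, 0) else y,
         loglinear = loglinear_inverse(y, spec$maturity, spec$offset,
                                       floor_zero = floor_zero),
         relative  = if (floor_zero) pmax(y, 0) else y,
         stop("unknown transform kind: ", spec$kind))
}
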