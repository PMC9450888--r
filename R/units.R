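#' Expansion-factor and physical-length bookkeeping
#'
#' Expansion microscopy enlarges a specimen by a linear factor `s`; areas
#' scale as `s^2` and volumes as `s^3`. These helpers convert measured
#' area/volume ratios into linear factors and convert lengths between the
#' post-expansion frame (what the microscope measures) and the
#' pre-expansion frame (the biological scale).
#'
#' All lengths inside the package are stored in nanometres; micrometres
#' appear only at I/O and in formatted reports.
#'
#' @name units
NULL

#' Construct an expansion factor
#'
#' @param linear_factor positive linear expansion factor.
#' @param method one of `"area"`, `"volume"`, `"macro"`, `"assumed"` —
#'   how the factor was obtained.
#' @param ratio the raw area or volume ratio the factor was derived from
#'   (kept for audit; `NA` for macro/assumed factors).
#' @param provenance free-text note on the measurement.
#' @return an object of class `exm_expansion_factor`.
#' @export
expansion_factor <- function(linear_factor, method = "assumed", ratio = NA_real_,
                             provenance = "") {
  stopifnot(is.numeric(linear_factor), length(linear_factor) == 1L)
  if (!is.finite(linear_factor) || linear_factor <= 0)
    stop("linear_factor must be a positive finite number", call. = FALSE)
  method <- match.arg(method, c("area", "volume", "macro", "assumed"))
  if (method == "area" && is.finite(ratio) &&
      abs(linear_factor - sqrt(ratio)) > 1e-9 * linear_factor)
    stop("area-derived factor must equal sqrt(ratio)", call. = FALSE)
  if (method == "volume" && is.finite(ratio) &&
      abs(linear_factor - ratio^(1 / 3)) > 1e-9 * linear_factor)
    stop("volume-derived factor must equal ratio^(1/3)", call. = FALSE)
  structure(
    list(linear_factor = linear_factor, method = method, ratio = ratio,
         provenance = provenance),
    class = "exm_expansion_factor"
  )
}

#' @export
print.exm_expansion_factor <- function(x, ...) {
  cat(sprintf("Expansion factor %.4g (method: %s", x$linear_factor, x$method))
  if (is.finite(x$ratio)) cat(sprintf(", ratio %.4g", x$ratio))
  cat(")\n")
  invisible(x)
}

#' Linear expansion factor from an area ratio
#'
#' A nucleus whose cross-sectional area increases `r`-fold has expanded
#' linearly by `sqrt(r)`; a ~16-fold area increase corresponds to a linear
#' factor of 4.
#'
#' @param area_ratio positive post/pre area ratio.
#' @return an [expansion_factor()] with `method = "area"`.
#' @export
linear_factor_from_area_ratio <- function(area_ratio) {
  if (!is.numeric(area_ratio) || length(area_ratio) != 1L ||
      !is.finite(area_ratio) || area_ratio <= 0)
    stop("area_ratio must be a positive finite number", call. = FALSE)
  expansion_factor(sqrt(area_ratio), method = "area", ratio = area_ratio)
}

#' Linear expansion factor from a volume ratio
#'
#' A ~52-fold volume increase corresponds to a linear factor of
#' `52^(1/3) = 3.7`.
#'
#' @param volume_ratio positive post/pre volume ratio.
#' @return an [expansion_factor()] with `method = "volume"`.
#' @export
linear_factor_from_volume_ratio <- function(volume_ratio) {
  if (!is.numeric(volume_ratio) || length(volume_ratio) != 1L ||
      !is.finite(volume_ratio) || volume_ratio <= 0)
    stop("volume_ratio must be a positive finite number", call. = FALSE)
  expansion_factor(volume_ratio^(1 / 3), method = "volume", ratio = volume_ratio)
}

#' Construct a physical length
#'
#' @param value non-negative length value.
#' @param unit `"nm"` or `"um"`.
#' @param frame `"pre_expansion"` or `"post_expansion"`.
#' @return an object of class `exm_length`.
#' @export
physical_length <- function(value, unit = c("nm", "um"),
                            frame = c("post_expansion", "pre_expansion")) {
  unit <- match.arg(unit)
  frame <- match.arg(frame)
  stopifnot(is.numeric(value))
  if (any(!is.finite(value)) || any(value < 0))
    stop("length value must be finite and non-negative", call. = FALSE)
  structure(list(value = value, unit = unit, frame = frame),
            class = "exm_length")
}

#' @export
print.exm_length <- function(x, ...) {
  cat(sprintf("%s %s (%s)\n", paste(signif(x$value, 6), collapse = ", "),
              if (x$unit == "um") "µm" else x$unit,
              sub("_", "-", x$frame)))
  invisible(x)
}

#' Convert a length between nm and µm
#'
#' @param length an [physical_length()].
#' @param unit target unit.
#' @return the converted `exm_length`.
#' @export
convert_unit <- function(length, unit = c("nm", "um")) {
  stopifnot(inherits(length, "exm_length"))
  unit <- match.arg(unit)
  if (unit == length$unit) return(length)
  f <- if (unit == "nm") 1000 else 1 / 1000
  physical_length(length$value * f, unit = unit, frame = length$frame)
}

as_factor_value <- function(factor) {
  if (inherits(factor, "exm_expansion_factor")) factor$linear_factor
  else if (is.numeric(factor) && length(factor) == 1L && factor > 0) factor
  else stop("factor must be an exm_expansion_factor or a positive number",
            call. = FALSE)
}

#' Convert a post-expansion length to its pre-expansion equivalent
#'
#' Divides by the linear expansion factor, e.g. a 1.27 µm peak-to-peak
#' distance measured post-expansion corresponds to 0.32 µm at factor 4.
#'
#' @param length an [physical_length()] in the post-expansion frame.
#' @param factor an [expansion_factor()] or a positive number (default 4,
#'   the macroscale gel expansion).
#' @return a pre-expansion `exm_length`, unit preserved.
#' @export
to_pre_expansion <- function(length, factor = 4) {
  stopifnot(inherits(length, "exm_length"))
  if (length$frame != "post_expansion")
    stop("frame mismatch: expected a post_expansion length", call. = FALSE)
  s <- as_factor_value(factor)
  physical_length(length$value / s, unit = length$unit, frame = "pre_expansion")
}

#' Convert a pre-expansion length to its post-expansion equivalent
#'
#' Inverse of [to_pre_expansion()]; multiplies by the linear factor.
#'
#' @inheritParams to_pre_expansion
#' @param length an [physical_length()] in the pre-expansion frame.
#' @return a post-expansion `exm_length`, unit preserved.
#' @export
to_post_expansion <- function(length, factor = 4) {
  stopifnot(inherits(length, "exm_length"))
  if (length$frame != "pre_expansion")
    stop("frame mismatch: expected a pre_expansion length", call. = FALSE)
  s <- as_factor_value(factor)
  physical_length(length$value * s, unit = length$unit, frame = "post_expansion")
}

#' Round half-up to a fixed number of decimals
#'
#' Report-table formatting helper matching the usual half-up convention of
#' printed tables (R's `round()` rounds half to even). Applied only when
#' formatting, never during computation.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
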