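#' Shell geometry for mark-recapture growth increments
#'
#' Marked horn snails deposit paint-free shell beyond the marked whorl; the
#' new material is quantified as degrees of growth around the columellar
#' axis.  These helpers convert the raw shell measurements into volumes:
#' the volume of new growth is the aperture area (a circle of radius one
#' quarter the shell width) times the fraction of a full turn grown, and the
#' standing shell volume is approximated by a cone.  A cube-root scaling
#' relation interconverts shell length (mm) and volume (mm^3).
#'
#' @name shell_geometry
NULL

#' Scaling relation between shell length and volume
#'
#' The cube root of shell volume scales linearly with shell length,
#' \eqn{V^{1/3} = a L + b}.  The defaults are the coefficients estimated by
#' ordinary least squares across all measured snails (slope 0.326,
#' intercept 0.497, R^2 = 0.889).
#'
#' @param slope slope in mm^(1/3) per mm; must be positive.
#' @param intercept intercept in mm^(1/3).
#' @return an object of class \code{"scaling_relation"}.
#' @export
scaling_relation <- function(slope = 0.326, intercept = 0.497) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L,
            is.finite(intercept))
  if (slope <= 0)
    stop("scaling relation slope must be > 0")
  structure(list(slope = slope, intercept = intercept, r_squared = NA_real_),
            class = "scaling_relation")
}

#' @export
print.scaling_relation <- function(x, ...) {
  cat(sprintf("Length-volume scaling: volume^(1/3) = %.4g * length + %.4g\n",
              x$slope, x$intercept))
  if (!is.na(x$r_squared))
    cat(sprintf("  (fit R^2 = %.3f)\n", x$r_squared))
  invisible(x)
}

#' Volume of new shell growth
#'
#' New growth volume is the aperture area times the grown fraction of a
#' whorl: \eqn{\pi (w/4)^2 \cdot d/360}, with \eqn{w} the shell width (mm)
#' and \eqn{d} the degrees of new growth.  Degrees may exceed 360 when a
#' snail adds more than one whorl; no modular reduction is applied.  The
#' width used should be the final width, since the new aperture belongs to
#' the new shell.
#'
#' @param width shell width in mm (> 0); vectorized.
#' @param degrees degrees of new shell growth (>= 0); vectorized.
#' @return growth volume in mm^3, zero exactly when \code{degrees} is zero.
#' @examples
#' growth_volume(4, 360)   # pi
#' growth_volume(10, 180)  # 9.817
#' @export
growth_volume <- function(width, degrees) {
  stopifnot(is.numeric(width), is.numeric(degrees))
  if (any(width <= 0, na.rm = TRUE))
    stop("shell width must be positive")
  if (any(degrees < 0, na.rm = TRUE))
    stop("degrees of growth must be non-negative")
  pi * (width / 4)^2 * (degrees / 360)
}

#' Standing shell volume by the cone approximation
#'
#' The shell is approximated by a cone of height equal to shell length.
#' The cone's base radius defaults to half the shell width (the shell's
#' maximal radius); \code{radius_fraction} makes the base configurable.
#'
#' @param length shell length in mm (> 0); vectorized.
#' @param width shell width in mm (> 0); vectorized.
#' @param radius_fraction base radius as a fraction of width (default 0.5).
#' @return shell volume in mm^3.
#' @examples
#' initial_volume(12, 6)  # (1/3) * pi * 9 * 12 = 113.1
#' @export
initial_volume <- function(length, width, radius_fraction = 0.5) {
  stopifnot(is.numeric(length), is.numeric(width))
  if (any(length <= 0, na.rm = TRUE) || any(width <= 0, na.rm = TRUE))
    stop("shell length and width must be positive")
  (1 / 3) * pi * (radius_fraction * width)^2 * length
}

#' Interconvert shell length and volume
#'
#' Applies the cube-root scaling relation \eqn{V^{1/3} = aL + b} and its
#' inverse.  The two functions are mutual inverses on their valid domains.
#'
#' @param length shell length in mm (> 0).
#' @param volume shell volume in mm^3 (> 0).
#' @param s a \code{\link{scaling_relation}}.
#' @return \code{length_to_volume}: volume in mm^3;
#'   \code{volume_to_length}: length in mm.
#' @examples
#' length_to_volume(25.9)          # 714.6
#' volume_to_length(705)           # 25.78
#' @export
length_to_volume <- function(length, s = scaling_relation()) {
  stopifnot(inherits(s, "scaling_relation"), is.numeric(length))
  if (any(length <= 0, na.rm = TRUE))
    stop("length must be positive")
  (s$slope * length + s$intercept)^3
}

#' @rdname length_to_volume
#' @export
volume_to_length <- function(volume, s = scaling_relation()) {
  stopifnot(inherits(s, "scaling_relation"), is.numeric(volume))
  if (any(volume <= 0, na.rm = TRUE))
    stop("volume must be positive")
  len <- (volume^(1 / 3) - s$intercept) / s$slope
  if (any(len <= 0, na.rm = TRUE))
    stop("volume implies non-positive length (cube root below intercept)")
  len
}

#' Fit the length-volume scaling relation
#'
#' Ordinary least squares of cube-root volume on length.
#'
#' @param length shell lengths in mm (>= 3 distinct values).
#' @param volume shell volumes in mm^3, same length as \code{length}.
#' @return a \code{\link{scaling_relation}} with the fitted \code{r_squared}.
#' @export
fit_scaling <- function(length, volume) {
  stopifnot(is.numeric(length), is.numeric(volume),
            length(length) == length(volume))
  ok <- is.finite(length) & is.finite(volume)
  length <- length[ok]; volume <- volume[ok]
  if (length(length) < 2L)
    stop("need at least 2 (length, volume) points")
  if (stats::sd(length) == 0)
    stop("cannot fit scaling relation: lengths are constant")
  fit <- stats::lm(I(volume^(1 / 3)) ~ length)
  co <- stats::coef(fit)
  if (co[["length"]] <= 0)
    stop("fitted scaling slope is not positive")
  out <- scaling_relation(slope = unname(co[["length"]]),
                          intercept = unname(co[["(Intercept)"]]))
  out$r_squared <- summary(fit)$r.squared
  out
}
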