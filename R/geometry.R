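#' Cochlear duct geometry for the two-layer flow and transport domain
#'
#' Describes the uncoiled cochlea as two stacked rectangular fluid layers: the
#' Corti fluid (extracellular fluid inside the organ of Corti) on top and the
#' scala tympani below, separated by the basilar membrane. The axial
#' coordinate `x` runs from the base (round-window side, `x = 0`) toward the
#' apex. Defaults describe the gerbil cochlea (12 mm long); layer heights are
#' modelling choices since the radially reduced 2-D duct has no unique height.
#'
#' @param length_mm Duct length in mm (gerbil: 12).
#' @param corti_height_um Height of the Corti-fluid layer in micrometres.
#' @param scala_height_um Height of the scala-tympani layer in micrometres.
#' @param dx_um Axial grid spacing in micrometres (must divide `length_mm`
#'   to within one cell).
#'
#' @return An object of class `cochlear_geometry`.
#' @examples
#' cochlear_geometry()
#' cochlear_geometry(length_mm = 3, scala_height_um = 480, dx_um = 25)
#' @export
cochlear_geometry <- function(length_mm = 12, corti_height_um = 60,
                              scala_height_um = 500, dx_um = 25) {
  stop_if_not_scalar_pos(length_mm, "length_mm")
  stop_if_not_scalar_pos(corti_height_um, "corti_height_um")
  stop_if_not_scalar_pos(scala_height_um, "scala_height_um")
  stop_if_not_scalar_pos(dx_um, "dx_um")
  nx <- round(length_mm * 1000 / dx_um)  # dx divides L to within one cell
  structure(
    list(length_mm = length_mm,
         corti_height_um = corti_height_um,
         scala_height_um = scala_height_um,
         dx_um = dx_um, nx = as.integer(nx)),
    class = "cochlear_geometry")
}

#' @export
print.cochlear_geometry <- function(x, ...) {
  cat(sprintf(
    "<cochlear_geometry> L = %g mm, Corti %g um / scala %g um, dx = %g um (nx = %d)\n",
    x$length_mm, x$corti_height_um, x$scala_height_um, x$dx_um, x$nx))
  invisible(x)
}

#' Place-frequency map of the cochlea
#'
#' Greenwood-form map between characteristic frequency (CF) and place along
#' the basilar membrane, `CF(kHz) = A (10^(alpha d) - k)` with `d` the
#' percentage distance from the apex. Defaults are the published gerbil
#' constants (A = 0.398 kHz, alpha = 0.022 per percent, k = 0.631), giving a
#' CF range of roughly 0.15-63 kHz over a 12-mm cochlea. CF decreases
#' monotonically from base to apex and the map is analytically invertible.
#'
#' @param A_khz,alpha,k Map constants (see Description).
#' @param length_mm Cochlear length in mm used to convert percentage distance
#'   to millimetres from the base.
#' @return An object of class `place_frequency_map`.
#' @examples
#' pf <- place_frequency_map()
#' place_to_cf(pf, 6)          # CF at 6 mm from the base
#' cf_to_place(pf, 4.5)        # place of the 4.5-kHz CF
#' @export
place_frequency_map <- function(A_khz = 0.398, alpha = 0.022, k = 0.631,
                                length_mm = 12) {
  stop_if_not_scalar_pos(A_khz, "A_khz")
  stop_if_not_scalar_pos(alpha, "alpha")
  stop_if_not_scalar_pos(length_mm, "length_mm")
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0)
  m <- structure(
    list(A_khz = A_khz, alpha = alpha, k = k, length_mm = length_mm),
    class = "place_frequency_map")
  m$cf_range_khz <- c(place_to_cf(m, length_mm), place_to_cf(m, 0))
  m
}

#' @export
print.place_frequency_map <- function(x, ...) {
  cat(sprintf("<place_frequency_map> CF %0.3g-%0.3g kHz over %g mm\n",
              x$cf_range_khz[1], x$cf_range_khz[2], x$length_mm))
  invisible(x)
}

#' Convert place to characteristic frequency
#'
#' @param map A [place_frequency_map()].
#' @param x_mm Place in mm from the base; must lie in `[0, length_mm]`.
#' @return CF in kHz.
#' @export
place_to_cf <- function(map, x_mm) {
  stopifnot(inherits(map, "place_frequency_map"), is.numeric(x_mm))
  if (any(x_mm < 0 | x_mm > map$length_mm)) {
    stop(sprintf("`x_mm` must lie within [0, %g] mm", map$length_mm),
         call. = FALSE)
  }
  d <- 100 * (1 - x_mm / map$length_mm)  # percent distance from apex
  map$A_khz * (10^(map$alpha * d) - map$k)
}

#' Convert characteristic frequency to place
#'
#' @param map A [place_frequency_map()].
#' @param cf_khz CF in kHz; must lie within the map's CF range.
#' @return Place in mm from the base.
#' @export
cf_to_place <- function(map, cf_khz) {
  stopifnot(inherits(map, "place_frequency_map"), is.numeric(cf_khz))
  rng <- map$cf_range_khz
  if (any(cf_khz < rng[1] | cf_khz > rng[2])) {
    stop(sprintf("`cf_khz` must lie within [%0.4g, %0.4g] kHz",
                 rng[1], rng[2]), call. = FALSE)
  }
  d <- log10(cf_khz / map$A_khz + map$k) / map$alpha
  map$length_mm * (1 - d / 100)
}
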