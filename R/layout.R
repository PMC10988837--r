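#' Eight-region insole sensor layout
#'
#' Builds the sensor map of the wearable insole used throughout the package:
#' eight discrete pressure sensors per foot, one per anatomical region.
#' Coordinates live in a foot-local frame of arbitrary length units
#' (foot length roughly 1): `y` increases anteriorly (heel to toe) and `x`
#' increases laterally *within each foot's own frame*, so left and right
#' centre-of-pressure statistics are directly comparable. The column
#' `x_global` gives the physical medial-to-lateral position in a common
#' body frame, in which the two layouts are mirror images.
#'
#' @param side `"left"` or `"right"`.
#' @return A `sensor_layout`: data frame with columns `sensor` (1-8),
#'   `region`, `x`, `y`, `x_global` and attribute `side`.
#' @examples
#' sensor_layout("left")
#' @export
sensor_layout <- function(side = c("left", "right")) {
  side <- match.arg(side)
  regions <- c(
    "great toe", "first metatarsal head", "second/third metatarsal head",
    "fourth/fifth metatarsal head", "medial midfoot", "lateral midfoot",
    "medial heel", "lateral heel"
  )
  # foot-local frame: x lateral-positive, y anterior-positive
  x <- c(-0.20, -0.15, 0.00, 0.18, -0.08, 0.15, -0.07, 0.07)
  y <- c(0.85, 0.62, 0.65, 0.58, 0.35, 0.33, 0.08, 0.06)
  out <- data.frame(
    sensor = 1:8,
    region = regions,
    x = x,
    y = y,
    # physical frame: lateral is +x on the right foot, -x on the left
    x_global = if (side == "left") -x else x,
    stringsAsFactors = FALSE
  )
  attr(out, "side") <- side
  class(out) <- c("sensor_layout", class(out))
  out
}
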