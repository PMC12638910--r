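#' 14-channel saline-electrode montage
#'
#' Channel labels, schematic 2D head coordinates (10-20 template positions,
#' unit head radius, nose up) and hemisphere tags for the 14-channel
#' consumer headset layout used throughout the package (AF3, F7, F3, FC5, T7,
#' P7, O1, O2, P8, T8, FC6, F4, F8, AF4; CMS/DRL references at P3/P4 are not
#' data channels). The layout is left/right symmetric with 7 channels per
#' hemisphere and no midline electrodes.
#'
#' @return a tibble with columns `channel`, `x`, `y`, `hemisphere`.
#' @examples
#' emotiv_montage()
#' @export
emotiv_montage <- function() {
  tibble::tibble(
    channel = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                "O2", "P8", "T8", "FC6", "F4", "F8", "AF4"),
    x = c(-0.25, -0.81, -0.34, -0.59, -1.00, -0.81, -0.31,
           0.31,  0.81,  1.00,  0.59,  0.34,  0.81,  0.25),
    y = c(0.82, 0.59, 0.54, 0.27, 0.00, -0.59, -0.95,
          -0.95, -0.59, 0.00, 0.27, 0.54, 0.59, 0.82),
    hemisphere = rep(c("left", "right"), each = 7L)
  )
}

#' Channel names of a hemisphere
#'
#' @param side `"left"`, `"right"` or `"whole"`.
#' @param montage montage tibble as returned by [emotiv_montage()].
#' @return character vector of channel names.
#' @export
hemisphere_channels <- function(side = c("whole", "left", "right"),
                                montage = emotiv_montage()) {
  side <- match.arg(side)
  if (side == "whole") return(montage$channel)
  montage$channel[montage$hemisphere == side]
}

#' @keywords internal
validate_montage <- function(montage) {
  stop_if_not(nrow(montage) == 14L, "montage must have exactly 14 channels")
  stop_if_not(!anyDuplicated(montage$channel), "montage channel names must be unique")
  stop_if_not(sum(montage$hemisphere == "left") == 7L &&
              sum(montage$hemisphere == "right") == 7L,
              "montage must have 7 left and 7 right channels")
  invisible(montage)
}

#' Pairwise electrode distances on the schematic head
#' @keywords internal
montage_distances <- function(montage = emotiv_montage()) {
  as.matrix(stats::dist(cbind(montage$x, montage$y)))
}
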