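#' Prefrontal channel-to-ROI montage
#'
#' Returns the fixed mapping of the 48 prefrontal channels of the NIRSIT
#' 3.0-cm montage onto 10 regions of interest (ROIs). The ROIs tile the
#' prefrontal cortex: right/left dorsolateral PFC (ROI 1/2), right/left
#' DLPFC-rostral PFC border (ROI 3/4), right/left medial PFC (ROI 5/6),
#' right/left orbitofrontal cortex (ROI 7/8) and right/left ventrolateral
#' PFC (ROI 9/10).
#'
#' @return A named list of class `roi_map` with one integer vector of
#'   channel ids per ROI (`ROI1` ... `ROI10`), plus a `labels` attribute
#'   with the anatomical names.
#' @examples
#' m <- roi_channel_map()
#' m$ROI5            # channels 18, 22, 26
#' length(unlist(m)) # 48
#' @export
roi_channel_map <- function() {
  m <- list(
    ROI1  = c(1L, 2L, 6L, 7L, 11L, 12L),
    ROI2  = c(34L, 35L, 37L, 38L, 42L, 43L),
    ROI3  = c(3L, 8L, 13L, 17L, 21L, 25L),
    ROI4  = c(20L, 24L, 28L, 33L, 36L, 41L),
    ROI5  = c(18L, 22L, 26L),
    ROI6  = c(19L, 23L, 27L),
    ROI7  = c(14L, 15L, 16L, 29L, 30L),
    ROI8  = c(31L, 32L, 46L, 47L, 48L),
    ROI9  = c(4L, 5L, 9L, 10L),
    ROI10 = c(39L, 40L, 44L, 45L)
  )
  attr(m, "labels") <- c(
    "right DLPFC", "left DLPFC", "right DLPFC/RPFC", "left DLPFC/RPFC",
    "right MPFC", "left MPFC", "right OFC", "left OFC",
    "right VLPFC", "left VLPFC"
  )
  class(m) <- "roi_map"
  m
}

#' Number of channels expected by the montage
#' @keywords internal
n_montage_channels <- function() 48L
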