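#' Methods thresholds used throughout the pipeline
#'
#' All tracking, classification and filtering thresholds live here so they are
#' never inlined at call sites. Pixel-based thresholds are converted to
#' micrometres once, using the configured pixel pitch.
#'
#' @param pixel_size_um Pixel pitch of the imaging system in micrometres per
#'   pixel (default 3.25, typical for x2 optics).
#' @return A named list of thresholds:
#' \describe{
#'   \item{bas_len_um}{Edge length below which an edge is a BAS (criterion 1), 400.}
#'   \item{bas_tip_len_um}{Length bound for the tip-ended BAS criterion 2, 1000.}
#'   \item{bas_width_um}{Width bound for criterion 3, 7.}
#'   \item{bas_width_len_um2}{Width x length bound for criterion 3, 9000.}
#'   \item{growing_tip_px}{Minimum per-frame displacement, in pixels, for a
#'     degree-1 node to count as a growing tip, 40.}
#'   \item{growing_tip_um}{The same displacement converted to micrometres.}
#'   \item{rh_tip_net_displacement_mm}{Net displacement separating runner-hypha
#'     tips from BAS tips, 2.5 mm.}
#'   \item{min_traj_frames}{Minimum kymograph trajectory duration, 10 frames.}
#'   \item{immotile_um_s}{Speed threshold below which a trajectory is treated
#'     as diffusive, 0.8 um/s.}
#'   \item{kymo_roi_um}{Spatial extent of a kymograph line ROI, 20 um.}
#'   \item{flow_map_tol_um}{Maximum video-to-network alignment error, 100 um.}
#'   \item{pixel_size_um}{The pixel pitch used for the conversions.}
#' }
#' @export
am_thresholds <- function(pixel_size_um = 3.25) {
  stopifnot(is.numeric(pixel_size_um), pixel_size_um > 0)
  list(
    bas_len_um = 400,
    bas_tip_len_um = 1000,
    bas_width_um = 7,
    bas_width_len_um2 = 9000,
    growing_tip_px = 40,
    growing_tip_um = 40 * pixel_size_um,
    rh_tip_net_displacement_mm = 2.5,
    min_traj_frames = 10,
    immotile_um_s = 0.8,
    kymo_roi_um = 20,
    flow_map_tol_um = 100,
    pixel_size_um = pixel_size_um
  )
}
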