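# Slit-transit flow physics: converts peak widths (in digitized samples,
# "points") to object sizes and back. An object of diameter d crossing an
# illumination slit of width s at plug-flow velocity v = Q/A produces a
# pulse of duration dt = (d + s)/v; at sampling rate fs that is dt * fs
# points. These relations size detected events and set the minimum-width
# gate that separates cell clusters from single cells.

#' Acquisition configuration
#'
#' Bundles the sampling and microfluidic parameters of an acquisition:
#' sampling rate, segment duration, volumetric flow rate, channel
#' cross-section and illumination slit width. Defaults describe a 60 kHz
#' acquisition through a 30 x 30 um channel at 3 uL/min with a 5 um slit,
#' read out in 1.5-min segments.
#'
#' @param sample_rate_hz sampling frequency in Hz.
#' @param segment_duration_s duration of one trace segment in seconds.
#'   Must give an integral number of samples.
#' @param flow_rate_ul_min volumetric flow rate Q in uL/min.
#' @param channel_area_um2 channel cross-sectional area A in um^2.
#' @param slit_width_um illumination slit width in um.
#' @return an object of class `bsfc_config`.
#' @export
#' @examples
#' cfg <- acquisition_config(segment_duration_s = 10)
#' cfg$n_samples
acquisition_config <- function(sample_rate_hz = 60000,
                               segment_duration_s = 90,
                               flow_rate_ul_min = 3,
                               channel_area_um2 = 900,
                               slit_width_um = 5) {
  if (sample_rate_hz <= 0) stop_bsfc("sample_rate_hz must be > 0")
  if (channel_area_um2 <= 0) stop_bsfc("channel_area_um2 must be > 0")
  if (slit_width_um < 0) stop_bsfc("slit_width_um must be >= 0")
  if (segment_duration_s <= 0) stop_bsfc("segment_duration_s must be > 0")
  n <- sample_rate_hz * segment_duration_s
  if (abs(n - round(n)) > 1e-9) {
    stop_bsfc("segment length %g samples is not integral", n)
  }
  structure(
    list(
      sample_rate_hz = sample_rate_hz,
      segment_duration_s = segment_duration_s,
      flow_rate_ul_min = flow_rate_ul_min,
      channel_area_um2 = channel_area_um2,
      slit_width_um = slit_width_um,
      n_samples = as.integer(round(n)),
      channel_order = bsfc_channels()
    ),
    class = "bsfc_config"
  )
}

#' @export
print.bsfc_config <- function(x, ...) {
  cat("<bsfc acquisition config>\n")
  cat(sprintf("  fs = %g Hz, segment = %g s (%d samples)\n",
              x$sample_rate_hz, x$segment_duration_s, x$n_samples))
  cat(sprintf("  Q = %g uL/min, A = %g um^2, slit = %g um (v = %.1f mm/s)\n",
              x$flow_rate_ul_min, x$channel_area_um2, x$slit_width_um,
              flow_velocity(x$flow_rate_ul_min, x$channel_area_um2)))
  invisible(x)
}

#' Plug-flow velocity from flow rate and channel cross-section
#'
#' v = Q/A with unit conversion: uL/min -> mm^3/s and um^2 -> mm^2, so v
#' comes out in mm/s. For the default acquisition (Q = 3 uL/min,
#' A = 900 um^2) this is 55.6 mm/s.
#'
#' @param flow_rate_ul_min flow rate Q in uL/min.
#' @param channel_area_um2 cross-sectional area A in um^2.
#' @return velocity in mm/s.
#' @export
#' @examples
#' flow_velocity(3, 900) # 55.6 mm/s
flow_velocity <- function(flow_rate_ul_min, channel_area_um2) {
  if (flow_rate_ul_min <= 0 || channel_area_um2 <= 0) {
    stop_bsfc("flow rate and area must be positive")
  }
  (flow_rate_ul_min / 60) / (channel_area_um2 * 1e-6)
}

#' Slit transit time of an object
#'
#' dt = d_eff / v where the effective diameter d_eff is the object
#' diameter plus the slit width (the pulse lasts as long as any part of
#' the object overlaps the slit).
#'
#' @param object_diameter_um object diameter in um.
#' @param slit_width_um illumination slit width in um.
#' @param velocity_mm_s flow velocity in mm/s.
#' @return transit time in seconds.
#' @export
#' @examples
#' transit_time(15, 5, flow_velocity(3, 900)) # 3.6e-4 s
transit_time <- function(object_diameter_um, slit_width_um, velocity_mm_s) {
  if (velocity_mm_s <= 0) stop_bsfc("velocity must be positive")
  if (object_diameter_um < 0 || slit_width_um < 0) {
    stop_bsfc("diameters must be non-negative")
  }
  ((object_diameter_um + slit_width_um) * 1e-3) / velocity_mm_s
}

#' Pulse width in sampled points for a transit time
#'
#' floor(dt * fs). The floor is the conservative choice when the result
#' feeds a minimum-width gate.
#'
#' @param transit_time_s transit time in seconds.
#' @param sample_rate_hz sampling rate in Hz.
#' @return integer number of points.
#' @export
#' @examples
#' width_in_points(3.6e-4, 60000) # 21
width_in_points <- function(transit_time_s, sample_rate_hz) {
  if (transit_time_s < 0) stop_bsfc("transit time must be non-negative")
  as.integer(floor(transit_time_s * sample_rate_hz))
}

#' Object size implied by a pulse width
#'
#' Inverse of the transit relation: (w / fs) * v - slit, in um. Sub-slit
#' results are clamped to zero with a warning.
#'
#' @param width_points pulse width in points.
#' @param sample_rate_hz sampling rate in Hz.
#' @param velocity_mm_s flow velocity in mm/s.
#' @param slit_width_um slit width in um.
#' @return object diameter in um.
#' @export
#' @examples
#' points_to_object_size(20, 60000, flow_velocity(3, 900), 5) # ~13.5 um
points_to_object_size <- function(width_points, sample_rate_hz,
                                  velocity_mm_s, slit_width_um) {
  if (sample_rate_hz <= 0 || velocity_mm_s <= 0) {
    stop_bsfc("sample rate and velocity must be positive")
  }
  d <- (width_points / sample_rate_hz) * velocity_mm_s * 1e3 - slit_width_um
  if (any(d < 0)) {
    warning("pulse width implies sub-slit object; clamping size to 0 um")
    d <- pmax(d, 0)
  }
  d
}
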