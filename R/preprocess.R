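# Raw-trace conditioning: zero-phase Butterworth band-pass filtering,
# daily illumination-power normalization against a 99% diffuse-reflectance
# (spectralon) standard, and the cumulative scattering signal used for
# peak detection.

#' Band-pass filter specification
#'
#' Second-order Butterworth band-pass, 50-6000 Hz by default, applied
#' forward-backward (zero phase) so that detected peak locations are not
#' shifted by filtering.
#'
#' @param order filter order (per band edge).
#' @param band numeric length-2 passband (low, high) in Hz.
#' @return object of class `bsfc_filter`.
#' @export
filter_spec <- function(order = 2, band = c(50, 6000)) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop_bsfc("band must satisfy 0 < low < high")
  }
  structure(list(order = order, band = band), class = "bsfc_filter")
}

#' Zero-phase Butterworth band-pass filtering of a trace
#'
#' Removes DC/baseline drift and high-frequency noise. Each channel is
#' mean-subtracted and filtered forward-backward
#' ([signal::filtfilt()]), which squares the magnitude response and
#' cancels phase so peak locations are preserved. The filter start-up
#' transient is confined to the segment edges; downstream peak calling
#' excludes an edge margin (see [detect_peaks()]).
#'
#' @param trace a `bsfc_trace` (or plain numeric vector with `fs` given).
#' @param spec a [filter_spec()].
#' @param fs sampling rate, required only for vector input.
#' @return filtered trace (same class/shape as input).
#' @export
bandpass_filter <- function(trace, spec = filter_spec(), fs = NULL) {
  stopifnot(inherits(spec, "bsfc_filter"))
  filt1 <- function(x, fs) {
    if (spec$band[2] >= fs / 2) {
      stop_bsfc("band (%g, %g) Hz exceeds Nyquist %g Hz",
                spec$band[1], spec$band[2], fs / 2)
    }
    if (length(x) <= 3 * spec$order) {
      stop_bsfc("segment too short to filter (length %d)", length(x))
    }
    bf <- signal::butter(spec$order, spec$band / (fs / 2), type = "pass")
    signal::filtfilt(bf, x - mean(x))
  }
  if (inherits(trace, "bsfc_trace")) {
    out <- trace
    out$signals <- apply(trace$signals, 2, filt1, fs = trace$sample_rate_hz)
    colnames(out$signals) <- colnames(trace$signals)
    out
  } else {
    if (is.null(fs)) stop_bsfc("fs is required for vector input")
    filt1(trace, fs)
  }
}

#' Daily calibration record
#'
#' One record per scattering wavelength per experiment day: the laser
#' power measured at the sample, the (neutral-density-reduced) power used
#' on the spectralon reflectance standard, and the backscatter intensity
#' recorded from the spectralon at that reduced power.
#'
#' @param wavelength_nm one of 405, 488, 633.
#' @param power_sample_mW incident power at the sample, mW.
#' @param power_spectralon_mW reduced incident power at the spectralon,
#'   mW.
#' @param intensity_spectralon spectralon backscatter intensity, signal
#'   units.
#' @return object of class `bsfc_calibration`.
#' @export
calibration_record <- function(wavelength_nm, power_sample_mW,
                               power_spectralon_mW, intensity_spectralon) {
  if (!wavelength_nm %in% c(405, 488, 633)) {
    stop_bsfc("wavelength must be 405, 488 or 633 nm")
  }
  if (power_sample_mW <= 0 || power_spectralon_mW <= 0 ||
      intensity_spectralon <= 0) {
    stop_bsfc("calibration values must all be > 0")
  }
  structure(
    list(wavelength_nm = wavelength_nm,
         power_sample_mW = power_sample_mW,
         power_spectralon_mW = power_spectralon_mW,
         intensity_spectralon = intensity_spectralon),
    class = "bsfc_calibration"
  )
}

#' Daily power normalization factor for a wavelength
#'
#' Norm(lambda) = Intensity_spectralon * Power_sample / Power_spectralon.
#' Dividing a scattering channel by this factor makes traces
#' dimensionless and comparable across days with different illumination
#' powers.
#'
#' @param cal a [calibration_record()].
#' @return scalar normalization factor.
#' @export
#' @examples
#' normalization_factor(calibration_record(405, 2, 0.2, 0.5)) # 5
normalization_factor <- function(cal) {
  stopifnot(inherits(cal, "bsfc_calibration"))
  cal$intensity_spectralon * cal$power_sample_mW / cal$power_spectralon_mW
}

#' Apply daily power normalization to the scattering channels
#'
#' Each scattering channel is divided by its wavelength's normalization
#' factor; fluorescence channels are left untouched.
#'
#' @param trace a `bsfc_trace`.
#' @param factors named numeric factors, names among
#'   `c("S405","S488","S633")` (or `"405"` etc.), all > 0. A data.frame of
#'   calibration records (columns wavelength_nm, power_sample_mW,
#'   power_spectralon_mW, intensity_spectralon) is also accepted.
#' @return normalized trace.
#' @export
apply_normalization <- function(trace, factors) {
  stopifnot(inherits(trace, "bsfc_trace"))
  if (is.data.frame(factors)) {
    f <- vapply(seq_len(nrow(factors)), function(i) {
      normalization_factor(calibration_record(
        factors$wavelength_nm[i], factors$power_sample_mW[i],
        factors$power_spectralon_mW[i], factors$intensity_spectralon[i]))
    }, numeric(1))
    names(f) <- paste0("S", factors$wavelength_nm)
    factors <- f
  }
  names(factors) <- sub("^(\\d)", "S\\1", names(factors))
  sc <- scatter_channels()
  missing <- setdiff(sc, names(factors))
  if (length(missing) > 0) {
    stop_bsfc("missing normalization factor for %s",
              paste(missing, collapse = ", "))
  }
  if (any(factors[sc] <= 0)) stop_bsfc("normalization factors must be > 0")
  out <- trace
  for (ch in sc) out$signals[, ch] <- trace$signals[, ch] / factors[[ch]]
  out
}

#' Cumulative scattering signal
#'
#' Pointwise sum of the three (normalized) scattering channels. Summing
#' co-located pulses adds their amplitudes while independent channel
#' noises add in quadrature, improving the SNR available for peak
#' detection.
#'
#' @param trace a `bsfc_trace` with the three scattering channels.
#' @return numeric vector, same length as the trace.
#' @export
cumulative_scatter <- function(trace) {
  stopifnot(inherits(trace, "bsfc_trace"))
  sc <- scatter_channels()
  if (!all(sc %in% colnames(trace$signals))) {
    stop_bsfc("trace lacks scattering channels")
  }
  rowSums(trace$signals[, sc, drop = FALSE])
}
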