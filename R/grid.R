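#' Channel-to-wavelength mapping for the 288-channel detector
#'
#' The detector reports 288 discrete channels spanning 340--850 nm. Devices
#' ship with a calibration polynomial that is rarely published, so the default
#' grid is linear: channel 0 maps to 340 nm and channel 287 to 850 nm. An
#' explicit 288-value calibration vector overrides the linear default.
#'
#' @param n_channels number of detector channels (288).
#' @param calibration `"linear"` or a strictly increasing numeric vector of
#'   length `n_channels` with values inside \[340, 850\] nm.
#' @return numeric vector of wavelengths in nm, one per channel, with class
#'   `wavelength_grid`.
#' @examples
#' g <- wavelength_grid()
#' g[1]    # 340
#' g[288]  # 850
#' @export
wavelength_grid <- function(n_channels = 288L, calibration = "linear") {
  if (identical(calibration, "linear")) {
    wl <- seq(340, 850, length.out = n_channels)
  } else {
    if (!is.numeric(calibration) || length(calibration) != n_channels)
      stop("calibration must be 'linear' or a numeric vector of length ",
           n_channels, call. = FALSE)
    if (any(diff(calibration) <= 0))
      stop("calibration wavelengths must be strictly increasing", call. = FALSE)
    if (calibration[1] < 340 || calibration[n_channels] > 850)
      stop("calibration wavelengths must lie within [340, 850] nm", call. = FALSE)
    wl <- as.numeric(calibration)
  }
  structure(wl, class = "wavelength_grid")
}

#' Map a detector channel index to its wavelength
#'
#' @param channel 0-based channel index (0..287), scalar or vector.
#' @param grid_spec `"linear"` (the default grid) or an explicit calibration
#'   vector / `wavelength_grid`.
#' @param n_channels number of channels on the detector.
#' @return wavelength(s) in nm.
#' @examples
#' map_channel_to_wavelength(0)    # 340
#' map_channel_to_wavelength(143)  # ~594.08
#' @export
map_channel_to_wavelength <- function(channel, grid_spec = "linear",
                                      n_channels = 288L) {
  grid <- if (inherits(grid_spec, "wavelength_grid")) grid_spec
          else wavelength_grid(n_channels, grid_spec)
  if (any(channel != floor(channel)) || any(channel < 0) ||
      any(channel >= length(grid)))
    stop("channel index out of range 0..", length(grid) - 1L, call. = FALSE)
  unclass(grid)[channel + 1L]
}

#' Nearest detector channel to a target wavelength
#'
#' Published absorption wavelengths (e.g. 586 nm for hemoglobin) rarely fall
#' exactly on the grid; analyses resolve them to the nearest channel.
#'
#' @param wavelength_nm target wavelength(s) in nm.
#' @param grid a `wavelength_grid` (default linear).
#' @return 0-based channel index (vectorised).
#' @export
nearest_channel <- function(wavelength_nm, grid = wavelength_grid()) {
  wl <- unclass(grid)
  vapply(wavelength_nm, function(w) which.min(abs(wl - w)) - 1L, integer(1))
}
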