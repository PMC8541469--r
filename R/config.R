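#' Read scanner, binning and window configuration from YAML
#'
#' Recognized keys (all optional, defaults in parentheses): `n_blocks` (20),
#' `apothem_mm` (165), `block_mm` (`[50, 50, 20]`: width, height, depth),
#' `axial_fov_mm` (60), `transaxial_fov_mm` (330), `energy_resolution_fwhm`
#' (0.10), `acceptance_window_kev` (`[350, 650]`), `min_block_sep` (5),
#' `pixel_pitch_mm` (2), `window_mode` ("TEW"), `lew_upper_kev` (430),
#' `uew_lower_kev` (550).
#'
#' @param path YAML file.
#' @return a list with elements `geometry`, `grid`, `windows`.
#' @export
read_scanner_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  block <- cfg$block_mm %||% c(50, 50, 20)
  geom <- scanner_geometry(
    n_blocks = cfg$n_blocks %||% 20L,
    block_width = block[1], block_height = block[2], block_depth = block[3],
    apothem = cfg$apothem_mm %||% 165,
    axial_fov = cfg$axial_fov_mm %||% 60,
    transaxial_fov = cfg$transaxial_fov_mm %||% 330,
    energy_resolution = cfg$energy_resolution_fwhm %||% 0.10,
    acceptance_window = cfg$acceptance_window_kev %||% c(350, 650),
    min_block_sep = cfg$min_block_sep %||% 5L)
  list(geometry = geom,
       grid = virtual_pixel_grid(geom, cfg$pixel_pitch_mm %||% 2),
       windows = energy_windows(cfg$window_mode %||% "TEW",
                                acceptance = geom$acceptance_window,
                                lew_upper = cfg$lew_upper_kev %||% 430,
                                uew_lower = cfg$uew_lower_kev %||% 550))
}

#' Write a scanner configuration YAML
#' @param geometry a [scanner_geometry()].
#' @param path output file.
#' @param pixel_pitch pitch to record (mm).
#' @param window_mode "TEW" or "DEW".
#' @export
write_scanner_config <- function(geometry, path, pixel_pitch = 2,
                                 window_mode = "TEW") {
  yaml::write_yaml(list(
    n_blocks = geometry$n_blocks,
    apothem_mm = geometry$apothem,
    block_mm = c(geometry$block_width, geometry$block_height,
                 geometry$block_depth),
    axial_fov_mm = geometry$axial_fov,
    transaxial_fov_mm = geometry$transaxial_fov,
    energy_resolution_fwhm = geometry$energy_resolution,
    acceptance_window_kev = geometry$acceptance_window,
    min_block_sep = geometry$min_block_sep,
    pixel_pitch_mm = pixel_pitch,
    window_mode = window_mode), path)
  invisible(path)
}
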