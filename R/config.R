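#' Load an analysis configuration file
#'
#' YAML configuration with the documented key names (`frame_rate_hz`,
#' `pixel_size_um`, `block_size_px`, `search_radius_px`, `min_block_std`,
#' `prominence_frac`, `min_interbeat_s`, `area_amp_frac`,
#' `baseline_percentile`, and the synthetic generator fields). Unknown keys
#' are preserved; command-line flags override file values.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_beatkit("missing_path", paste0("config file does not exist: ", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_beatkit("bad_format", "config file must be a YAML mapping")
  cfg
}
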