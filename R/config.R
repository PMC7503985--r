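# Run configuration: one serializable list of every tunable the pipeline uses,
# overridable from a YAML file. The command-line wrapper under
# inst/cli/ndci.R applies CLI flags on top (precedence CLI > file > defaults).

#' Default run configuration
#'
#' @return Nested list with components `pixel_pitch_um`, `nd` (see
#'   [nd_config()]), `unet` (see [unet_config()]), `train` (see
#'   [unet_train_config()]), `ci` (`level`, `boundary`), `seed`.
#' @export
ndci_defaults <- function() {
  list(
    pixel_pitch_um = hrme_pixel_pitch(),
    nd = unclass(nd_config()),
    unet = list(input_size = 512, base_channels = 32, depth = 5,
                out_channels = 3, batch_norm = TRUE),
    train = unclass(unet_train_config()),
    ci = list(level = 0.90, boundary = 189),
    seed = 1L)
}

# recursive merge: values in `over` win
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML file (if given) and merges it over [ndci_defaults()]. Unknown
#' keys are rejected at the top level.
#'
#' @param path Optional YAML config path.
#' @return Configuration list of class `"ndci_config"`.
#' @export
ndci_config <- function(path = NULL) {
  cfg <- ndci_defaults()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- merge_config(cfg, over)
  }
  if (cfg$ci$level <= 0 || cfg$ci$level >= 1)
    stop("invalid config: ci level must be in (0, 1)")
  if (cfg$pixel_pitch_um <= 0)
    stop("invalid config: pixel_pitch_um must be positive")
  structure(cfg, class = "ndci_config")
}

#' Stable hash of a configuration (for provenance records)
#'
#' @param cfg A configuration list.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  # FNV-1a over the deparsed text; reproducible across sessions
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
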