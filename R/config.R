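# Tunable surface of the pipeline, with YAML overrides.
# Precedence: built-in defaults < config file < command-line flags.

#' Built-in pipeline defaults
#'
#' @return Named list of every tunable surfaced by the pipeline, with units
#'   documented in the functions that consume them.
#' @export
default_config <- function() {
  list(
    sampling_rate = 50,          # Hz
    dumbbell_mass = 4.5,         # kg
    rpe_tolerance = 2,           # Borg units
    reference_channel = "gx",
    min_period = 1,              # s
    prominence_fraction = 0.3,
    smoothing_window = 5,
    alpha = 0.4,
    beta = 0.6,
    gamma = 14,
    normalize_signal = TRUE,
    base_learner = "decision_tree",
    n_rounds = NULL,             # learner-specific default
    tree_max_depth = 3,
    ann_hidden_units = 16,
    ann_epochs = 200,
    seed = 1
  )
}

#' Load a pipeline configuration
#'
#' @param path Optional YAML file of overrides (flat mapping of the
#'   [default_config()] keys).
#' @param overrides Named list applied on top of the file (command-line
#'   flags).
#' @return Merged configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop(sprintf("load_config(): no such config file '%s'", path),
           call. = FALSE)
    }
    from_file <- yaml::read_yaml(path)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown)) {
      stop(sprintf("load_config(): unknown key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    cfg[names(from_file)] <- from_file
  }
  overrides <- overrides[!vapply(overrides, is.null, TRUE)]
  cfg[names(overrides)] <- overrides
  cfg
}

config_objects <- function(cfg) {
  list(
    sampling = sampling_spec(cfg$sampling_rate),
    segmentation = segmentation_config(
      reference_channel = cfg$reference_channel,
      min_period = cfg$min_period,
      prominence_fraction = cfg$prominence_fraction,
      smoothing_window = cfg$smoothing_window),
    params = similarity_params(cfg$alpha, cfg$beta, cfg$gamma),
    model = model_config(base_learner = cfg$base_learner,
                         n_rounds = cfg$n_rounds,
                         tree_max_depth = cfg$tree_max_depth,
                         ann_hidden_units = cfg$ann_hidden_units,
                         ann_epochs = cfg$ann_epochs,
                         seed = cfg$seed)
  )
}
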