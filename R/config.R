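#' Default pipeline configuration
#'
#' A nested list covering the `preprocess`, `patch`, `augment`, `model`,
#' `train` and `eval` namespaces used by the command-line interface.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    preprocess = list(gaussian = list(kernel = 3L, sigma = 1.0),
                      gamma = 1.3, levels = 256L),
    patch = list(window = 64L, step = 16L),
    augment = list(flip = TRUE, rot90 = TRUE, crop_min_frac = 0.8, seed = 1L),
    model = list(in_channels = 1L, stage_channels = c(64L, 128L, 256L),
                 aspp_rates = c(1L, 2L, 3L, 4L), aspp_kernels_per_branch = 128L,
                 dropout_rate = 0.2, l2_coeff = 1e-4, n_supervision = 3L,
                 window = 64L, attention_stage = 2L, aspp_stage = 3L),
    train = list(batch_size = 20L, epochs = 500L, learning_rate = 0.001,
                 optimizer = "adam", seed = 1L, augment = TRUE,
                 loss_mode = "default", val_fraction = 0.1),
    eval = list(threshold = 0.5)
  )
}

#' Load a YAML configuration, rejecting unknown keys
#'
#' Reads a single YAML document and merges it over [default_config()]. Any
#' key absent from the defaults is an error, so typos fail loudly.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return Nested named list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  merge_checked <- function(def, usr, prefix = "") {
    for (nm in names(usr)) {
      if (!nm %in% names(def))
        stop_retseg(sprintf("unknown configuration key '%s%s'", prefix, nm),
                    "retseg_config_error")
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_checked(def[[nm]], usr[[nm]],
                                   paste0(prefix, nm, "."))
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  merge_checked(defaults, user)
}
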