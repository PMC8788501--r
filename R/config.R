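# YAML run configuration.
#
# A run file has four optional sections mapped onto the package's
# constructors:
#   network: {in_channels, num_classes, base_width, input_size, batchnorm}
#   data:    {window: [lo, hi], input_size, split_seed, split_ratio}
#   loss:    {lambda_aux: [1,1,1,1], lambda_final: 1, epsilon: 1e-5}
#   train:   {lr, batch_size, max_epochs, plateau_patience, lr_factor,
#             min_lr, weight_decay, augment, seed}
# Unknown keys are rejected to catch typos early.

default_run_config <- function() {
  list(network = list(in_channels = 1L, num_classes = 2L, base_width = 64L,
                      input_size = 256L, batchnorm = TRUE),
       data = list(window = c(-200, 1200), input_size = 256L,
                   split_seed = 1L, split_ratio = 0.8),
       loss = list(lambda_aux = c(1, 1, 1, 1), lambda_final = 1,
                   epsilon = 1e-5),
       train = list(lr = 1e-3, batch_size = 16L, max_epochs = 100L,
                    plateau_patience = 10L, lr_factor = 0.5, min_lr = 0,
                    weight_decay = 0.01, augment = TRUE, seed = 1L))
}

#' Read a YAML run configuration
#'
#' Loads a run file, fills unspecified keys with the package defaults, and
#' returns ready-to-use configuration objects.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return list with `network` ([vertebox_config()]), `train`
#'   ([train_config()]), `loss_weights` ([loss_weights()]), `loss_eps`, and
#'   the merged `data` section.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- default_run_config()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (sec in names(user)) {
    if (!sec %in% names(defaults))
      vb_stop("unknown configuration section: ", sec)
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      vb_stop("unknown key(s) in section '", sec, "': ",
              paste(bad, collapse = ", "))
  }
  merged <- modifyList(defaults, user)
  net <- merged$network
  tr <- merged$train
  list(network = vertebox_config(net$in_channels, net$num_classes,
                                 net$base_width, net$input_size,
                                 net$batchnorm),
       train = train_config(lr = tr$lr, batch_size = tr$batch_size,
                            max_epochs = tr$max_epochs,
                            plateau_patience = tr$plateau_patience,
                            lr_factor = tr$lr_factor, min_lr = tr$min_lr,
                            weight_decay = tr$weight_decay,
                            augment = tr$augment, seed = tr$seed),
       loss_weights = loss_weights(merged$loss$lambda_aux,
                                   merged$loss$lambda_final),
       loss_eps = merged$loss$epsilon,
       data = merged$data)
}

#' Write phantom slice pairs as PNG files with a JSON-like manifest
#'
#' Saves `image_XXXX.png` / `mask_XXXX.png` pairs plus `manifest.csv`
#' describing each slice, for use outside R.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_phantoms_png <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$pairs)) {
    p <- dataset$pairs[[i]]
    png::writePNG(p$image, file.path(dir, sprintf("image_%04d.png", i)))
    png::writePNG(p$mask + 0, file.path(dir, sprintf("mask_%04d.png", i)))
  }
  write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}
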