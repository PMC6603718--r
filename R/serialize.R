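#' Save and load calibration models as JSON
#'
#' Serialises electrode calibrations (`nikolsky_model`), latent-variable
#' models (`latent_model`) and networks (`network_model`) to a plain JSON
#' document carrying a `model_class` tag, matrices as row-major nested
#' lists, and full numeric precision. `load_model_json()` reconstructs the
#' original object.
#'
#' @param model a supported model object.
#' @param path JSON file path.
#' @return `save_model_json()`: the path, invisibly; `load_model_json()`:
#'   the reconstructed model.
#' @export
save_model_json <- function(model, path) {
  cls <- class(model)[1L]
  if (!cls %in% c("nikolsky_model", "latent_model", "network_model")) {
    stop("unsupported model class: ", cls, call. = FALSE)
  }
  payload <- rapply(unclass(model), function(x) x, how = "replace")
  doc <- list(model_class = cls, payload = payload)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- doc$model_class
  obj <- doc$payload
  if (cls == "nikolsky_model") {
    obj$electrodes <- lapply(obj$electrodes, as.list)
    obj$conc_range <- as.numeric(obj$conc_range)
  } else if (cls == "latent_model") {
    for (f in c("loadings", "scores", "weights", "x_loadings", "rotation")) {
      if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
    }
  } else if (cls == "network_model") {
    obj$weights <- lapply(obj$weights, as.matrix)
    obj$layer_sizes <- as.integer(obj$layer_sizes)
    obj$activations <- as.character(obj$activations)
  } else {
    stop("unsupported model class in file: ", cls, call. = FALSE)
  }
  structure(obj, class = cls)
}
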