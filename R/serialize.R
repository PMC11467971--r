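# Lossless text serialization of fitted spatial-filter models.

model_to_list <- function(model) {
  if (inherits(model, "csp_model")) {
    list(type = "csp_model",
         weights = as.vector(model$weights),
         dim = dim(model$weights),
         colnames = colnames(model$weights),
         eigenvalues = model$eigenvalues,
         n_pairs = model$n_pairs,
         class_order = model$class_order)
  } else if (inherits(model, "fbcsp_model")) {
    list(type = "fbcsp_model",
         per_band_models = lapply(model$per_band_models, model_to_list),
         selected_indices = model$selected_indices,
         k_selected = model$k_selected,
         mi_scores = model$mi_scores,
         bands = lapply(model$bank$bands, unclass),
         class_order = model$class_order)
  } else if (inherits(model, "fbcssp_model")) {
    list(type = "fbcssp_model",
         layer1 = lapply(model$layer1, model_to_list),
         layer2 = model_to_list(model$layer2),
         bands = lapply(model$bank$bands, unclass),
         class_order = model$class_order)
  } else {
    abort("cannot serialize object of class '%s'",
          paste(class(model), collapse = "/"))
  }
}

list_to_model <- function(x) {
  switch(x$type,
    csp_model = {
      w <- matrix(unlist(x$weights), x$dim[[1]], x$dim[[2]])
      if (!is.null(x$colnames)) colnames(w) <- unlist(x$colnames)
      structure(list(weights = w,
                     eigenvalues = unlist(x$eigenvalues),
                     n_pairs = as.integer(x$n_pairs),
                     class_order = unlist(x$class_order)),
                class = "csp_model")
    },
    fbcsp_model = {
      structure(list(
        per_band_models = lapply(x$per_band_models, list_to_model),
        selected_indices = as.integer(unlist(x$selected_indices)),
        k_selected = as.integer(x$k_selected),
        mi_scores = unlist(x$mi_scores),
        bank = rebuild_bank(x$bands),
        class_order = unlist(x$class_order)), class = "fbcsp_model")
    },
    fbcssp_model = {
      structure(list(
        layer1 = lapply(x$layer1, list_to_model),
        layer2 = list_to_model(x$layer2),
        bank = rebuild_bank(x$bands),
        class_order = unlist(x$class_order)), class = "fbcssp_model")
    },
    abort("unknown serialized model type '%s'", x$type))
}

rebuild_bank <- function(bands) {
  filter_bank(lapply(bands, function(b) {
    band_spec(b$low_hz, b$high_hz, order = b$order)
  }))
}

#' Write a fitted model to a JSON file
#'
#' Numeric fields are written with 17 significant digits, so a round trip
#' through [read_model()] reproduces the model to full double precision.
#'
#' @param model A `csp_model`, `fbcsp_model`, or `fbcssp_model`.
#' @param path Output file.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, digits = I(17),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path JSON file.
#' @export
read_model <- function(path) {
  list_to_model(jsonlite::read_json(path, simplifyVector = FALSE))
}
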