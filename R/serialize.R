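# JSON serialization of fitted models.
#
# Schema: {"format_version": 1, "model_type": "lr"|"gnb"|"knn_config",
#          ...all numeric fields of the model...}

#' Write a fitted model to JSON
#'
#' @param model An `lr_model`, `gnb_model`, or `knn_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  type <- if (inherits(model, "lr_model")) "lr"
          else if (inherits(model, "gnb_model")) "gnb"
          else if (inherits(model, "knn_config")) "knn_config"
          else stop("unsupported model class", call. = FALSE)
  payload <- c(list(format_version = 1L, model_type = type),
               unclass(model))
  if (type == "gnb") {
    payload$means <- as.data.frame(payload$means)
    payload$variances <- as.data.frame(payload$variances)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return The reconstructed model object.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format_version) || p$format_version != 1L) {
    stop("unrecognized model file format", call. = FALSE)
  }
  type <- p$model_type
  p$format_version <- NULL
  p$model_type <- NULL
  if (type == "lr") {
    structure(p, class = "lr_model")
  } else if (type == "gnb") {
    p$means <- as.matrix(p$means)
    p$variances <- as.matrix(p$variances)
    rownames(p$means) <- rownames(p$variances) <- c("0", "1")
    p$priors <- stats::setNames(unlist(p$priors), c("0", "1"))
    structure(p, class = "gnb_model")
  } else if (type == "knn_config") {
    knn_config(p$K, p$standardize)
  } else {
    stop(sprintf("unknown model_type '%s'", type), call. = FALSE)
  }
}
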