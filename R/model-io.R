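#' Serialize a fitted classifier as JSON
#'
#' Writes the architecture, weight matrices, feature scaling and training
#' metadata; the file round-trips through [read_progression_net()].
#'
#' @param model A fitted [progression_net()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_progression_net <- function(model, file) {
  stopifnot(inherits(model, "progression_net"))
  obj <- list(
    architecture = list(inputs = length(model$centre), hidden = model$hidden,
                        activation = "tanh", output = "sigmoid"),
    weights = list(W1 = model$weights$W1, b1 = model$weights$b1,
                   W2 = model$weights$W2, b2 = model$weights$b2),
    scaling = list(centre = model$centre, scale = model$scale),
    feature_names = model$feature_names,
    seed = model$seed,
    stop_reason = model$stop_reason,
    trace = model$trace)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(file)
}

#' Read a classifier serialized by [write_progression_net()]
#'
#' @param file JSON path.
#' @return A `progression_net` object usable with [predict()]; the split
#'   indices and fitted values of the original fit are not stored.
#' @export
read_progression_net <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  h <- obj$architecture$hidden
  d <- obj$architecture$inputs
  as_mat <- function(w, nr, nc) {
    if (is.matrix(w)) return(matrix(as.numeric(w), nr, nc))
    matrix(unlist(w), nr, nc, byrow = TRUE)
  }
  structure(list(
    weights = list(W1 = as_mat(obj$weights$W1, h, d),
                   b1 = as.numeric(obj$weights$b1),
                   W2 = as_mat(obj$weights$W2, 1, h),
                   b2 = as.numeric(obj$weights$b2)),
    hidden = h,
    centre = as.numeric(obj$scaling$centre),
    scale = as.numeric(obj$scaling$scale),
    split = NULL, trace = as.data.frame(obj$trace),
    stop_reason = obj$stop_reason, fitted = NULL, y = NULL,
    feature_names = obj$feature_names, seed = obj$seed,
    call = NULL), class = "progression_net")
}
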