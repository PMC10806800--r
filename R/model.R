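# The random-forest SoM classifier: 250 trees, balanced class weights,
# probability output, decision threshold 0.30.

#' Model configuration
#'
#' @param n_estimators Number of trees (default 250).
#' @param decision_threshold Probability threshold tau for calling an atom a
#'   SoM (default 0.30; an atom is positive when `p >= tau`).
#' @param seed Integer seed making training fully reproducible.
#' @param min_node_size Minimal terminal node size (default 1, the classifier
#'   default of the common ensemble libraries).
#' @return A `som_model_config` list.
#' @export
som_model_config <- function(n_estimators = 250L, decision_threshold = 0.30,
                             seed = 1L, min_node_size = 1L) {
  stopifnot(decision_threshold > 0, decision_threshold < 1, n_estimators >= 1)
  structure(list(
    n_estimators = as.integer(n_estimators),
    decision_threshold = decision_threshold,
    seed = as.integer(seed),
    min_node_size = as.integer(min_node_size)
  ), class = "som_model_config")
}

#' Fit the random-forest SoM classifier
#'
#' Trains a probability forest on the atom records' descriptor vectors with
#' class weights inversely proportional to class frequencies (balanced), the
#' package's stand-in for per-bootstrap balanced reweighting. Training is
#' deterministic given the records and the config seed.
#'
#' @param atoms Atom-record tibble with `features` and `is_som`.
#' @param config A [som_model_config()].
#' @return A `som_model` object holding the ensemble, the config snapshot
#'   and a fingerprint (hash) of the training record ids.
#' @export
fit_som_model <- function(atoms, config = som_model_config()) {
  y <- factor(atoms$is_som, levels = c(FALSE, TRUE))
  if (length(unique(atoms$is_som)) < 2) {
    abort("training requires both SoM and non-SoM records")
  }
  cw <- as.numeric(length(y) / (2 * table(y)))
  fit <- ranger::ranger(
    x = atoms$features, y = y,
    num.trees = config$n_estimators,
    probability = TRUE,
    class.weights = cw,
    min.node.size = config$min_node_size,
    seed = config$seed,
    num.threads = 1
  )
  structure(list(
    forest = fit,
    config = config,
    feature_length = ncol(atoms$features),
    n_train = nrow(atoms),
    train_hash = paste(sort(unlist(atoms$atom_refs)), collapse = ";")
  ), class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d trees, %d training atoms, %d features, tau = %.2f\n",
              x$config$n_estimators, x$n_train, x$feature_length,
              x$config$decision_threshold))
  invisible(x)
}

#' Predict per-atom SoM probabilities
#'
#' @param object A `som_model`.
#' @param atoms Atom-record tibble featurized under the training config.
#' @param ... Unused.
#' @return The atom tibble with added columns `probability` (positive-class
#'   probability, mean over trees) and `predicted` (`probability >= tau`).
#' @export
predict.som_model <- function(object, atoms, ...) {
  if (ncol(atoms$features) != object$feature_length) {
    abort(sprintf("feature length %d does not match the model's %d",
                  ncol(atoms$features), object$feature_length))
  }
  p <- predict(object$forest, data = atoms$features, num.threads = 1,
               seed = object$config$seed)$predictions[, "TRUE"]
  out <- atoms
  out$probability <- as.numeric(p)
  out$predicted <- classify_probs(out$probability, object$config$decision_threshold)
  out[, setdiff(names(out), c("features", "fingerprint"))]
}

#' Threshold probabilities into SoM calls
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param tau Decision threshold in (0, 1); the boundary `p == tau` counts
#'   as positive.
#' @return Logical vector.
#' @export
classify_probs <- function(probabilities, tau = 0.30) {
  stopifnot(tau > 0, tau < 1)
  probabilities >= tau
}

#' Rank the atoms of one molecule by predicted probability
#'
#' @param probabilities Per-atom probabilities of a single molecule.
#' @return Integer permutation of atom positions, highest probability first;
#'   ties broken by ascending atom index.
#' @export
rank_atoms <- function(probabilities) {
  order(-probabilities, seq_along(probabilities))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.som_model <- function(x, ...) {
  tibble(n_trees = x$config$n_estimators, n_train = x$n_train,
         n_features = x$feature_length,
         decision_threshold = x$config$decision_threshold,
         oob_error = x$forest$prediction.error, seed = x$config$seed)
}
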