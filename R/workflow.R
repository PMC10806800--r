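# End-to-end experiment harnesses: baseline cross-validation + test
# evaluation, and the cross-validated active-learning benchmark.

#' Split a library into training and test molecules
#'
#' @param library A curated library tibble.
#' @param test_fraction Fraction of molecules held out (default 0.22).
#' @param seed Integer seed.
#' @return List of two library tibbles, `train` and `test`.
#' @export
split_molecules <- function(library, test_fraction = 0.22, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  withr::local_seed(as.integer(seed))
  n_test <- max(1L, round(test_fraction * nrow(library)))
  test_idx <- sort(sample.int(nrow(library), n_test))
  list(train = library[-test_idx, ], test = library[test_idx, ])
}

#' Baseline model: cross-validation plus holdout evaluation
#'
#' Splits the library by molecule, featurizes and atom-deduplicates the
#' training half, runs stratified k-fold cross-validation of the forest,
#' refits on all training atoms and evaluates on the held-out molecules
#' (where complete atom coverage allows the top-2 success rate).
#'
#' @param library A curated library tibble.
#' @param config A [descriptor_config()].
#' @param model_config A [som_model_config()].
#' @param cv_folds Folds for cross-validation (default 10).
#' @param test_fraction Molecule holdout fraction (default 0.22).
#' @param seed Integer seed.
#' @return A `som_baseline` list: `cv` (per-fold metrics tibble),
#'   `cv_summary` (means), `test` (holdout metrics), `model` (the full
#'   training-set fit).
#' @export
run_baseline <- function(library, config = descriptor_config(),
                         model_config = som_model_config(),
                         cv_folds = 10L, test_fraction = 0.22, seed = 1L) {
  split <- split_molecules(library, test_fraction, seed)
  train_atoms <- deduplicate_atoms(featurize_library(split$train, config))
  test_atoms <- featurize_library(split$test, config)
  folds <- stratified_folds(train_atoms, k = cv_folds, seed = seed)
  cv <- map(seq_len(cv_folds), function(f) {
    hold <- folds$record_id[folds$fold == f]
    fit <- fit_som_model(train_atoms[!train_atoms$record_id %in% hold, ], model_config)
    evaluate_predictions(predict(fit, train_atoms[train_atoms$record_id %in% hold, ]))
  }) |> bind_rows() |> mutate(fold = row_number(), .before = 1)
  model <- fit_som_model(train_atoms, model_config)
  test_cov <- setNames(split$test$n_atoms, split$test$mol_id)
  test <- evaluate_predictions(predict(model, test_atoms), n_atoms_per_mol = test_cov)
  structure(list(
    cv = cv,
    cv_summary = summarise(cv, dplyr::across(c("mcc", "auc", "precision",
                                               "recall", "jaccard"), mean)),
    test = test,
    model = model,
    n_train_atoms = nrow(train_atoms),
    n_test_molecules = nrow(split$test)
  ), class = "som_baseline")
}

#' @export
print.som_baseline <- function(x, ...) {
  cat(sprintf("<som_baseline> %d training atoms, %d test molecules\n",
              x$n_train_atoms, x$n_test_molecules))
  cat(sprintf("  CV   MCC %.3f  AUC %.3f\n", x$cv_summary$mcc, x$cv_summary$auc))
  cat(sprintf("  test MCC %.3f  AUC %.3f  top-2 %.0f%%\n",
              x$test$mcc, x$test$auc, 100 * x$test$top2_rate))
  invisible(x)
}

#' @export
glance.som_baseline <- function(x, ...) {
  dplyr::bind_cols(
    setNames(x$cv_summary, paste0("cv_", names(x$cv_summary))),
    setNames(x$test[, c("mcc", "auc", "top2_rate", "jaccard")],
             c("test_mcc", "test_auc", "test_top2_rate", "test_jaccard"))
  )
}

#' Cross-validated active-learning experiment
#'
#' For each fold of the atom-level split (stratified or
#' similarity-clustered) and each repeat seed: one uncertainty-sampling run
#' and one random-selection baseline run over the remaining folds (the
#' active-learning set), evaluated on the held-out fold (the validation
#' set).
#'
#' @param atoms Deduplicated atom-record tibble.
#' @param scheme `"stratified"` or `"similarity_cluster"`.
#' @param k Number of folds (default 5).
#' @param seeds Integer vector of repeat seeds (one AL + one random run per
#'   fold x seed).
#' @param folds_to_run Fold indices to run (default all; a single fold with
#'   several seeds reproduces the initialization-robustness design).
#' @param strategies Selection strategies to run (default both).
#' @param config Template [al_config()]; its strategy/seed are overridden
#'   per run.
#' @param split_seed Seed for the fold assignment.
#' @return Tibble with one row per (fold, seed, strategy) and the run
#'   object in a list-column `run`; unnest `tidy(run)` for curves.
#' @export
run_al_experiment <- function(atoms, scheme = c("stratified", "similarity_cluster"),
                              k = 5L, seeds = 1:5, folds_to_run = seq_len(k),
                              strategies = c("uncertainty", "random"),
                              config = al_config(), split_seed = 1L) {
  scheme <- match.arg(scheme)
  folds <- if (scheme == "stratified") {
    stratified_folds(atoms, k = k, seed = split_seed)
  } else {
    cluster_folds(atoms, k = k)
  }
  grid <- tidyr::expand_grid(fold = folds_to_run, seed = seeds,
                             strategy = strategies)
  grid$run <- pmap(grid, function(fold, seed, strategy) {
    hold <- folds$record_id[folds$fold == fold]
    pool <- atoms[!atoms$record_id %in% hold, ]
    val <- atoms[atoms$record_id %in% hold, ]
    cfg <- config
    cfg$strategy <- strategy
    cfg$seed <- as.integer(seed)
    run_active_learning(pool, val, cfg)
  })
  grid
}

#' Learning curves of an AL experiment, long format
#'
#' @param experiment Result of [run_al_experiment()].
#' @return Tibble: fold, seed, strategy, iteration, frac_data and all
#'   validation metrics (evaluated iterations only).
#' @export
al_learning_curves <- function(experiment) {
  experiment |>
    mutate(history = map(.data$run, ~ .x$history)) |>
    select(-"run") |>
    tidyr::unnest("history") |>
    filter(!is.na(.data$val_mcc)) |>
    select(-"selected")
}

#' Atoms consistently selected across repeats
#'
#' For each strategy/fold, the fraction of the training data at a given
#' pool fraction that was selected in every one of the repeat runs.
#'
#' @param experiment Result of [run_al_experiment()] (several seeds on one
#'   fold).
#' @param at_fraction Pool fraction at which to compare (default 0.25).
#' @return Tibble with fold, strategy, `n_consistent` and
#'   `fraction_of_training`.
#' @export
al_selection_consistency <- function(experiment, at_fraction = 0.25) {
  experiment |>
    group_by(.data$fold, .data$strategy) |>
    summarise(
      {
        sets <- map(.data$run, function(r) {
          h <- r$history
          cut <- which(h$n_train >= at_fraction * r$n_total)[1]
          if (is.na(cut)) cut <- nrow(h)
          sort(unique(c(unlist(h$selected[seq_len(cut)]))))
        })
        common <- Reduce(intersect, sets)
        tibble(n_runs = length(sets),
               n_consistent = length(common),
               fraction_of_training = length(common) /
                 max(1, mean(lengths(sets))))
      },
      .groups = "drop"
    )
}
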