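# Evaluation metrics for imbalanced atom-level classification.

#' Matthews correlation coefficient from confusion counts
#'
#' Standard MCC; returns 0 by convention when any marginal of the confusion
#' matrix is zero. The denominator is computed in log space to avoid
#' overflow on large counts.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  m <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(m == 0)) return(0)
  num <- tp * tn - fp * fn
  if (num == 0) return(0)
  sign(num) * exp(log(abs(num)) - 0.5 * sum(log(m)))
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param probabilities Numeric scores.
#' @param labels Logical (or 0/1) true labels.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_score <- function(probabilities, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Jaccard score of the positive class
#'
#' `tp / (tp + fp + fn)`; 0 when the denominator is 0.
#'
#' @param tp,fp,fn Non-negative confusion counts.
#' @return A value in `[0, 1]`.
#' @export
jaccard_score <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  d <- tp + fp + fn
  if (d == 0) return(0)
  tp / d
}

#' Top-2 success rate over molecules
#'
#' Fraction of molecules for which at least one true SoM appears among the
#' two top-ranked atoms (ranking by predicted probability, ties broken by
#' ascending atom index). Requires complete per-molecule atom coverage;
#' molecules with partial coverage are excluded with a warning, molecules
#' with no annotated SoM are excluded silently.
#'
#' @param predictions Tibble with `mol_id`, `atom_index`, `probability`,
#'   `is_som`.
#' @param n_atoms_per_mol Named integer vector giving the true heavy-atom
#'   count per `mol_id` (for the coverage check); if `NULL`, coverage is
#'   assumed complete.
#' @return Fraction in `[0, 1]`, or `NA` if no molecule qualifies.
#' @export
top2_success_rate <- function(predictions, n_atoms_per_mol = NULL) {
  ok <- TRUE
  res <- predictions |>
    group_by(.data$mol_id) |>
    summarise(
      n_covered = dplyr::n(),
      any_som = any(.data$is_som),
      success = {
        r <- rank_atoms(.data$probability)
        any(.data$is_som[r[seq_len(min(2, length(r)))]])
      },
      .groups = "drop"
    )
  if (!is.null(n_atoms_per_mol)) {
    full <- res$n_covered == n_atoms_per_mol[res$mol_id]
    if (any(!full)) {
      warn(sprintf("excluding %d molecule(s) with partial atom coverage from top-2",
                   sum(!full)))
    }
    res <- res[full, ]
  }
  res <- res[res$any_som, ]
  if (nrow(res) == 0) return(NA_real_)
  mean(res$success)
}

#' Positive label ratio of a record selection
#'
#' @param is_som Logical labels of the selected records.
#' @return Fraction of positives.
#' @export
positive_label_ratio <- function(is_som) {
  if (length(is_som) == 0) abort("empty selection")
  mean(as.logical(is_som))
}

#' Evaluate predictions into a metrics report
#'
#' Computes MCC, ROC AUC, precision, recall, Jaccard score, the predicted
#' and true positive ratios and, when full molecules are covered, the top-2
#' success rate. Precision/recall are 0 (with a warning suppressed into the
#' value) on zero denominators.
#'
#' @param predictions Tibble with `mol_id`, `atom_index`, `is_som`,
#'   `probability`, `predicted` (as returned by [predict.som_model()]).
#' @param n_atoms_per_mol Optional named vector for the top-2 coverage
#'   check; `NA` disables top-2 (the default for atom-subset validation
#'   folds, where molecules are only partially covered).
#' @return One-row tibble: `mcc`, `auc`, `precision`, `recall`, `jaccard`,
#'   `top2_rate`, `positive_label_ratio`, `predicted_positive_ratio`,
#'   `n_atoms`, `n_molecules`.
#' @export
evaluate_predictions <- function(predictions, n_atoms_per_mol = NA) {
  truth <- predictions$is_som
  call <- predictions$predicted
  tp <- sum(truth & call); fp <- sum(!truth & call)
  fn <- sum(truth & !call); tn <- sum(!truth & !call)
  top2 <- if (length(n_atoms_per_mol) == 1 && is.na(n_atoms_per_mol[1])) {
    NA_real_
  } else {
    top2_success_rate(predictions, n_atoms_per_mol)
  }
  tibble(
    mcc = mcc(tp, fp, fn, tn),
    auc = auc_score(predictions$probability, truth),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn),
    jaccard = jaccard_score(tp, fp, fn),
    top2_rate = top2,
    positive_label_ratio = mean(truth),
    predicted_positive_ratio = mean(call),
    n_atoms = nrow(predictions),
    n_molecules = length(unique(predictions$mol_id))
  )
}
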