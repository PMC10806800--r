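# Iterative uncertainty-sampling loop: initialize with one SoM and one
# non-SoM, retrain from scratch each cycle, select the atoms whose predicted
# probability is closest to the decision threshold, grow the training set,
# and track validation metrics.

#' Active-learning configuration
#'
#' @param strategy `"uncertainty"` (distance of the predicted probability
#'   from the decision threshold) or `"random"` (the baseline selector).
#' @param batch_size Number of atoms added per iteration (studied values 1,
#'   5, 10, 25, 100).
#' @param diverse Use diverse mini-batches: shortlist the
#'   `candidate_pool_size` most informative atoms, then pick `batch_size`
#'   k-means cluster representatives (studied pairings 5-of-25 and
#'   10-of-100).
#' @param candidate_pool_size Shortlist size `m` for diverse batches
#'   (required > `batch_size` when `diverse`).
#' @param eval_every Evaluate on the validation set every this many
#'   iterations (the first and last iterations are always evaluated).
#' @param stop_fraction Stop once this fraction of the active-learning set
#'   is in training (default 1 = run to pool exhaustion).
#' @param seed Seed for initialization and all selection randomness.
#' @param model_config A [som_model_config()].
#' @return An `al_config` list.
#' @export
al_config <- function(strategy = c("uncertainty", "random"), batch_size = 1L,
                      diverse = FALSE, candidate_pool_size = NULL,
                      eval_every = 10L, stop_fraction = 1,
                      seed = 1L, model_config = som_model_config()) {
  strategy <- match.arg(strategy)
  batch_size <- as.integer(batch_size)
  stopifnot(batch_size >= 1, eval_every >= 1,
            stop_fraction > 0, stop_fraction <= 1)
  if (diverse) {
    stopifnot(!is.null(candidate_pool_size), candidate_pool_size > batch_size)
  }
  structure(list(
    strategy = strategy, batch_size = batch_size, diverse = isTRUE(diverse),
    candidate_pool_size = if (is.null(candidate_pool_size)) NULL
                          else as.integer(candidate_pool_size),
    eval_every = as.integer(eval_every), stop_fraction = stop_fraction,
    seed = as.integer(seed), model_config = model_config
  ), class = "al_config")
}

#' Initialize the active-learning state
#'
#' The initial training set holds exactly one randomly drawn SoM and one
#' randomly drawn non-SoM; everything else is the pooling set.
#'
#' @param pool Atom-record tibble (the full active-learning set).
#' @param seed Integer seed.
#' @return An `al_state` list with `iteration`, `train_ids`, `pool_ids`.
#' @export
al_initialize <- function(pool, seed = 1L) {
  pos <- pool$record_id[pool$is_som]
  neg <- pool$record_id[!pool$is_som]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("pool must contain at least one SoM and one non-SoM record")
  }
  withr::local_seed(as.integer(seed))
  t1 <- c(pos[sample.int(length(pos), 1)], neg[sample.int(length(neg), 1)])
  structure(list(
    iteration = 1L,
    train_ids = sort(t1),
    pool_ids = sort(setdiff(pool$record_id, t1)),
    n_total = nrow(pool)
  ), class = "al_state")
}

#' Informativeness of a predicted probability
#'
#' Distance of the prediction from the decision threshold; lower is more
#' informative (0 = maximally informative), computed without regard for the
#' label.
#'
#' @param probability Predicted probabilities in `[0, 1]`.
#' @param tau Decision threshold.
#' @return Non-negative scores.
#' @export
informativeness <- function(probability, tau = 0.30) {
  abs(probability - tau)
}

#' Select the next batch of pool atoms
#'
#' The selector never sees labels: it operates on record ids, predicted
#' probabilities and (for diverse batches) descriptor vectors only.
#' Uncertainty sampling takes the `n` atoms with the smallest
#' `|probability - tau|` (ties by ascending record id); the diverse variant
#' shortlists the `m` most informative atoms, clusters their descriptor
#' vectors with k-means (`k = n`, 10 restarts) and returns the candidate
#' nearest each centroid; random selection draws uniformly. If fewer than
#' `n` atoms remain, all are returned.
#'
#' @param pool_ids Record ids of the current pool.
#' @param probability Predicted probability per pool record (unused for
#'   random selection).
#' @param config An [al_config()].
#' @param features Descriptor matrix aligned with `pool_ids` (needed when
#'   `config$diverse`).
#' @return Vector of selected record ids.
#' @export
select_batch <- function(pool_ids, probability, config, features = NULL) {
  if (length(pool_ids) == 0) abort("empty pool")
  n <- config$batch_size
  if (length(pool_ids) <= n) return(sort(pool_ids))
  if (config$strategy == "random") {
    return(sort(pool_ids[sample.int(length(pool_ids), n)]))
  }
  tau <- config$model_config$decision_threshold
  info <- informativeness(probability, tau)
  ord <- order(info, pool_ids)
  if (!config$diverse) {
    return(sort(pool_ids[ord[seq_len(n)]]))
  }
  m <- min(config$candidate_pool_size, length(pool_ids))
  cand <- ord[seq_len(m)]
  if (is.null(features)) abort("diverse selection requires descriptor vectors")
  cand_feat <- features[cand, , drop = FALSE]
  km <- suppressWarnings(kmeans(cand_feat, centers = n, nstart = 10))
  picked <- vapply(seq_len(n), function(cl) {
    members <- which(km$cluster == cl)
    d2 <- rowSums((cand_feat[members, , drop = FALSE] -
                   matrix(km$centers[cl, ], length(members),
                          ncol(cand_feat), byrow = TRUE))^2)
    best <- members[order(d2, pool_ids[cand[members]])][1]
    pool_ids[cand[best]]
  }, numeric(1))
  sort(unique(picked))
}

# Train on T_k, optionally evaluate, select a_k, advance the partition.
# Internal; `run_active_learning()` drives it.
al_step <- function(state, pool, validation, config, evaluate = TRUE,
                    select = TRUE) {
  stopifnot(length(intersect(state$train_ids, state$pool_ids)) == 0,
            length(state$train_ids) + length(state$pool_ids) == state$n_total)
  train <- pool[match(state$train_ids, pool$record_id), ]
  model <- fit_som_model(train, config$model_config)
  metrics <- NULL
  if (evaluate && !is.null(validation)) {
    metrics <- evaluate_predictions(predict(model, validation))
  }
  selected <- integer()
  if (select && length(state$pool_ids) > 0) {
    pool_rows <- pool[match(state$pool_ids, pool$record_id), ]
    prob <- if (config$strategy == "uncertainty") {
      predict(model, pool_rows)$probability
    } else rep(NA_real_, nrow(pool_rows))
    selected <- select_batch(state$pool_ids, prob, config,
                             features = pool_rows$features)
    state$train_ids <- sort(c(state$train_ids, selected))
    state$pool_ids <- sort(setdiff(state$pool_ids, selected))
  }
  state$iteration <- state$iteration + 1L
  list(state = state, model = model, metrics = metrics, selected = selected,
       positive_label_ratio = positive_label_ratio(train$is_som))
}

#' Run the active-learning loop
#'
#' Initializes with one SoM / one non-SoM, then repeats: train the forest
#' from scratch on the current training set, evaluate on the validation
#' set (every `eval_every` iterations), select the next batch from the
#' pool, move it into training. The loop ends when the pool is exhausted
#' (or `stop_fraction` of the active-learning set is in training); the
#' final model is trained on the full accumulated set and always
#' evaluated, so the last history row equals a direct fit on the same
#' records.
#'
#' @param pool Atom-record tibble: the active-learning set.
#' @param validation Atom-record tibble for the learning curve (disjoint
#'   from `pool`), or `NULL` to skip evaluation.
#' @param config An [al_config()].
#' @return A `som_al_run` object; `tidy()` gives the per-iteration history
#'   (iteration, n_train, frac_data, selected ids, positive label ratio and
#'   validation metrics), `glance()` the final row, `autoplot()` the
#'   learning curves.
#' @export
run_active_learning <- function(pool, validation, config = al_config()) {
  stopifnot(length(intersect(pool$record_id,
                             if (is.null(validation)) integer() else validation$record_id)) == 0)
  withr::local_seed(config$seed)
  state <- al_initialize(pool, seed = sample.int(.Machine$integer.max, 1))
  n_total <- state$n_total
  target <- ceiling(config$stop_fraction * n_total)
  history <- list()
  model <- NULL
  repeat {
    k <- state$iteration
    done <- length(state$pool_ids) == 0 || length(state$train_ids) >= target
    evaluate <- (k == 1L) || (k %% config$eval_every == 0L) || done
    res <- al_step(state, pool, validation, config, evaluate = evaluate,
                   select = !done)
    n_train_k <- length(state$train_ids)   # |T_k| before selection
    row <- tibble(
      iteration = k,
      n_train = n_train_k,
      frac_data = n_train_k / n_total,
      n_selected = length(res$selected),
      selected = list(res$selected),
      positive_label_ratio = res$positive_label_ratio
    )
    metr <- res$metrics
    if (is.null(metr)) {
      metr <- tibble(mcc = NA_real_, auc = NA_real_, precision = NA_real_,
                     recall = NA_real_, jaccard = NA_real_, top2_rate = NA_real_,
                     positive_label_ratio = NA_real_,
                     predicted_positive_ratio = NA_real_,
                     n_atoms = NA_integer_, n_molecules = NA_integer_)
    }
    names(metr) <- paste0("val_", names(metr))
    history[[k]] <- dplyr::bind_cols(row, metr)
    state <- res$state
    model <- res$model
    if (done) break
  }
  structure(list(
    history = bind_rows(history),
    final_model = model,
    final_state = state,
    config = config,
    n_total = n_total
  ), class = "som_al_run")
}

#' @export
print.som_al_run <- function(x, ...) {
  cat(sprintf("<som_al_run> %s%s, batch %d: %d iterations, %d/%d atoms used\n",
              x$config$strategy, if (x$config$diverse) " (diverse)" else "",
              x$config$batch_size, nrow(x$history),
              length(x$final_state$train_ids), x$n_total))
  last <- x$history[nrow(x$history), ]
  if (!is.na(last$val_mcc)) {
    cat(sprintf("  final validation MCC %.3f, AUC %.3f\n", last$val_mcc, last$val_auc))
  }
  invisible(x)
}

#' @export
tidy.som_al_run <- function(x, ...) x$history

#' @export
glance.som_al_run <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  dplyr::bind_cols(
    tibble(strategy = x$config$strategy, batch_size = x$config$batch_size,
           diverse = x$config$diverse, n_iterations = nrow(x$history),
           n_total = x$n_total),
    last[, grep("^val_|^frac_data$|^positive_label_ratio$", names(last))]
  )
}
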