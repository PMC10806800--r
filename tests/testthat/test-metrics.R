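# Metric implementations against direct formula evaluation and brute-force
# oracles.

# brute-force AUC: all positive/negative score pairs, ties count half
auc_brute <- function(p, y) {
  pos <- p[y]; neg <- p[!y]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

mcc_brute <- function(tp, fp, fn, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

test_that("MCC matches direct formula evaluation and its conventions", {
  expect_equal(mcc(10, 0, 0, 5), 1.0)
  expect_equal(mcc(0, 5, 5, 0), -1.0)
  expect_equal(mcc(0, 0, 3, 10), 0.0)       # zero-marginal convention
  expect_equal(mcc(3, 1, 2, 10), (3 * 10 - 1 * 2) / sqrt(4 * 5 * 11 * 12))
  withr::with_seed(11, {
    for (i in 1:250) {
      cts <- rpois(4, lambda = sample(c(2, 20, 2000), 4, replace = TRUE))
      expect_equal(mcc(cts[1], cts[2], cts[3], cts[4]), do.call(mcc_brute, as.list(cts)),
                   tolerance = 1e-12)
      # class-swap symmetry
      expect_equal(mcc(cts[1], cts[2], cts[3], cts[4]),
                   mcc(cts[4], cts[3], cts[2], cts[1]))
    }
  })
})

test_that("AUC agrees with the all-pairs oracle and is rank-invariant", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_true(is.na(auc_score(c(0.4, 0.5), c(TRUE, TRUE))))
  withr::with_seed(12, {
    for (i in 1:250) {
      n <- sample(5:60, 1)
      p <- round(runif(n), 2)           # coarse grid forces ties
      y <- runif(n) < 0.3
      if (!any(y) || all(y)) next
      expect_equal(auc_score(p, y), auc_brute(p, y), tolerance = 1e-12)
      # invariance under strictly monotone transforms
      expect_equal(auc_score(qlogis(p * 0.98 + 0.01), y), auc_score(p, y))
    }
    # independent scores: AUC near 1/2
    p <- runif(4000); y <- runif(4000) < 0.2
    expect_equal(auc_score(p, y), 0.5, tolerance = 0.03)
  })
})

test_that("Jaccard score matches its formula with zero-denominator convention", {
  expect_equal(jaccard_score(3, 1, 2), 0.5)
  expect_equal(jaccard_score(7, 0, 0), 1.0)
  expect_equal(jaccard_score(0, 0, 0), 0.0)
  expect_equal(jaccard_score(0, 4, 6), 0.0)
})

test_that("top-2 success rate counts molecules whose two best-ranked atoms hit a SoM", {
  preds <- dplyr::bind_rows(
    tibble::tibble(mol_id = "m1", atom_index = 1:5,
                   probability = c(0.9, 0.1, 0.2, 0.3, 0.4),
                   is_som = c(TRUE, FALSE, FALSE, FALSE, FALSE)),   # rank 1 hit
    tibble::tibble(mol_id = "m2", atom_index = 1:5,
                   probability = c(0.5, 0.4, 0.3, 0.2, 0.1),
                   is_som = c(FALSE, FALSE, TRUE, FALSE, FALSE)),   # SoM ranked 3rd
    tibble::tibble(mol_id = "m3", atom_index = 1:3,
                   probability = c(0.2, 0.8, 0.3),
                   is_som = c(FALSE, FALSE, TRUE))                  # rank 2 hit
  )
  expect_equal(top2_success_rate(preds), 2 / 3)
  # molecules of <= 2 atoms with a SoM always succeed
  tiny <- tibble::tibble(mol_id = "t", atom_index = 1:2,
                         probability = c(0.1, 0.9), is_som = c(TRUE, FALSE))
  expect_equal(top2_success_rate(tiny), 1)
  # partial coverage excluded with a warning
  expect_warning(
    r <- top2_success_rate(preds, n_atoms_per_mol = c(m1 = 5, m2 = 9, m3 = 3)),
    "partial"
  )
  expect_equal(r, 1)  # m2 dropped; m1 and m3 both succeed
  # brute-force cross-check on random configurations
  withr::with_seed(13, {
    for (i in 1:100) {
      n_mol <- sample(2:8, 1)
      preds <- purrr::map_dfr(seq_len(n_mol), function(m) {
        n <- sample(3:12, 1)
        tibble::tibble(mol_id = sprintf("m%02d", m), atom_index = seq_len(n),
                       probability = round(runif(n), 1),
                       is_som = c(TRUE, runif(n - 1) < 0.2)[sample(n)])
      })
      brute <- preds |>
        dplyr::group_by(mol_id) |>
        dplyr::summarise(hit = {
          ord <- order(-probability, atom_index)
          any(is_som[ord[1:2]])
        }) |>
        dplyr::pull(hit) |> mean()
      expect_equal(top2_success_rate(preds), brute)
    }
  })
})

test_that("positive label ratio is the positive fraction and rejects empty input", {
  expect_equal(positive_label_ratio(c(TRUE, FALSE)), 0.5)
  expect_equal(positive_label_ratio(rep(TRUE, 4)), 1)
  expect_equal(positive_label_ratio(c(rep(TRUE, 24), rep(FALSE, 76))), 0.24)
  expect_error(positive_label_ratio(logical()), "empty")
})

test_that("evaluate_predictions assembles a coherent report", {
  withr::with_seed(14, {
    preds <- tibble::tibble(
      mol_id = rep(c("a", "b"), each = 10), atom_index = rep(1:10, 2),
      probability = runif(20), is_som = runif(20) < 0.3
    )
    preds$predicted <- classify_probs(preds$probability, 0.3)
    rep <- evaluate_predictions(preds)
    expect_gte(rep$mcc, -1); expect_lte(rep$mcc, 1)
    expect_equal(rep$n_atoms, 20L)
    expect_equal(rep$n_molecules, 2L)
    expect_true(is.na(rep$top2_rate))
    tp <- sum(preds$is_som & preds$predicted)
    expect_equal(rep$jaccard, jaccard_score(tp, sum(!preds$is_som & preds$predicted),
                                            sum(preds$is_som & !preds$predicted)))
    # independent AUC cross-check
    expect_equal(rep$auc, as.numeric(pROC::auc(pROC::roc(
      preds$is_som, preds$probability, quiet = TRUE, direction = "<"))))
  })
})
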