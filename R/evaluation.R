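#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks; equals
#' the trapezoidal area under the ROC curve, ties included.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), same length.
#' @return The AUC, a single number in \[0, 1\].
#' @examples
#' auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("`scores` and `labels` lengths differ.")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1.")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("AUC needs both classes present.")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated k-fold cross-validation of the full pipeline
#'
#' Known associations are shuffled into `cv_folds` groups per repeat; each
#' group in turn is removed from the matrix, the entire pipeline (all three
#' similarities, fusion, denoising, propagation) is re-run on the masked
#' matrix, and the held-out positives are scored against every pair that is 0
#' in the *original* matrix (training positives never enter the ranking).
#' Fold AUCs are averaged per repeat; the summary is mean and sample standard
#' deviation over repeats. All randomness derives from `params$seed`.
#'
#' @param x Edge data frame or binary association matrix.
#' @param params A [msif_lnp_params()] object (`cv_folds`, `cv_repeats`,
#'   `seed` control the protocol).
#' @param keep_fold_inputs Store each fold's masked training matrix on the
#'   result (for audits of what the similarity stage saw).
#' @return An object of class `msif_lnp_cv` with elements `auc_per_run`,
#'   `auc_mean`, `auc_sd`, `fold_auc` (tibble: repeat, fold, auc, n_test),
#'   `fold_assignments` (tibble: repeat, microbe, disease, fold) and `params`.
#'   [tidy()] returns the per-fold table, [glance()] the one-row summary.
#' @export
msif_lnp_cv <- function(x, params = msif_lnp_params(), keep_fold_inputs = FALSE) {
  A <- validate_association(x)
  check_params_for(params, A)
  pos <- which(A == 1, arr.ind = TRUE)
  npos <- nrow(pos)
  if (npos < params$cv_folds) {
    abort(sprintf("Need at least cv_folds = %d known associations, found %d.",
                  params$cv_folds, npos))
  }
  folds <- params$cv_folds
  repeats <- params$cv_repeats
  assignments <- withr::with_seed(params$seed, {
    lapply(seq_len(repeats), function(r) sample(rep_len(seq_len(folds), npos)))
  })
  fold_rows <- list()
  assign_rows <- list()
  fold_inputs <- if (keep_fold_inputs) list() else NULL
  for (r in seq_len(repeats)) {
    fold_of <- assignments[[r]]
    assign_rows[[r]] <- tibble::tibble(
      repeat_ = r,
      microbe = rownames(A)[pos[, 1L]],
      disease = colnames(A)[pos[, 2L]],
      fold = fold_of
    )
    for (f in seq_len(folds)) {
      test_idx <- pos[fold_of == f, , drop = FALSE]
      A_train <- A
      A_train[test_idx] <- 0
      stopifnot(all(A_train[test_idx] == 0))
      if (keep_fold_inputs) {
        fold_inputs[[length(fold_inputs) + 1L]] <-
          list(repeat_ = r, fold = f, A_train = A_train, test = test_idx)
      }
      fit <- msif_lnp(A_train, params)
      Y <- fit$scores
      test_scores <- Y[test_idx]
      neg_scores <- Y[A == 0]
      auc <- auc_score(c(test_scores, neg_scores),
                       c(rep(1, length(test_scores)), rep(0, length(neg_scores))))
      fold_rows[[length(fold_rows) + 1L]] <- tibble::tibble(
        repeat_ = r, fold = f, auc = auc, n_test = nrow(test_idx)
      )
    }
  }
  fold_auc <- dplyr::bind_rows(fold_rows)
  per_run <- dplyr::summarise(dplyr::group_by(fold_auc, .data$repeat_),
                              auc = mean(.data$auc), .groups = "drop")
  structure(
    list(
      auc_per_run = per_run$auc,
      auc_mean = mean(per_run$auc),
      auc_sd = if (repeats > 1L) stats::sd(per_run$auc) else NA_real_,
      fold_auc = fold_auc,
      fold_assignments = dplyr::bind_rows(assign_rows),
      fold_inputs = fold_inputs,
      params = params,
      n_positives = npos,
      dim = dim(A)
    ),
    class = "msif_lnp_cv"
  )
}

#' @export
print.msif_lnp_cv <- function(x, ...) {
  cat(sprintf("MSIF-LNP cross-validation: %d-fold x %d repeats on %d x %d matrix (%d positives)\n",
              x$params$cv_folds, x$params$cv_repeats, x$dim[1L], x$dim[2L],
              x$n_positives))
  if (is.na(x$auc_sd)) {
    cat(sprintf("  AUC = %.4f (single run)\n", x$auc_mean))
  } else {
    cat(sprintf("  AUC = %.4f +/- %.4f (sd over repeats)\n", x$auc_mean, x$auc_sd))
  }
  invisible(x)
}

#' Parameter-grid sweep
#'
#' Runs [msif_lnp_cv()] at every row of a parameter grid. Each grid point uses
#' the same `seed`, hence identical fold assignments, so differences between
#' grid points reflect the parameters rather than fold noise. The best setting
#' maximizes mean AUC; exact ties go to the earlier (smaller-parameter) row.
#'
#' @param x Edge data frame or binary association matrix.
#' @param grid Data frame whose columns are a subset of the
#'   [msif_lnp_params()] field names (e.g. `theta`, `fusion_iters`).
#' @param params Base parameters for fields not present in `grid`.
#' @return An object of class `msif_lnp_sweep` with a `results` tibble
#'   (grid columns plus `auc_mean`, `auc_sd`) and `best`, the argmax row.
#' @export
msif_lnp_sweep <- function(x, grid, params = msif_lnp_params()) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) abort("`grid` must be a nonempty data frame.")
  grid <- dplyr::arrange(grid, dplyr::across(dplyr::everything()))
  cvs <- purrr::map(seq_len(nrow(grid)), function(i) {
    p <- modify_params(params, as.list(grid[i, , drop = FALSE]))
    msif_lnp_cv(x, p)
  })
  results <- dplyr::mutate(
    tibble::as_tibble(grid),
    auc_mean = purrr::map_dbl(cvs, "auc_mean"),
    auc_sd = purrr::map_dbl(cvs, "auc_sd")
  )
  best <- results[which.max(results$auc_mean), , drop = FALSE]
  structure(
    list(results = results, best = best, cv_results = cvs, params = params),
    class = "msif_lnp_sweep"
  )
}

#' @export
print.msif_lnp_sweep <- function(x, ...) {
  cat(sprintf("MSIF-LNP parameter sweep over %d settings\n", nrow(x$results)))
  cat("  best:\n")
  print(x$best)
  invisible(x)
}
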