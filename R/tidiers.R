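#' Tidy a fitted score matrix into a long tibble
#'
#' @param x A `msif_lnp_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per microbe-disease pair: `microbe`,
#'   `disease`, `score` (final averaged score in \[0, 1\]) and `known`
#'   (whether the pair was a 1 in the input).
#' @export
tidy.msif_lnp_fit <- function(x, ...) {
  tab <- tibble::tibble(
    microbe = rep(rownames(x$scores), times = ncol(x$scores)),
    disease = rep(colnames(x$scores), each = nrow(x$scores)),
    score = as.vector(x$scores),
    known = as.vector(x$associations) == 1
  )
  tab
}

#' One-row summary of a fit
#'
#' @param x A `msif_lnp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: matrix dimensions, association count and density,
#'   the main parameters, and the fraction of negative mass clipped from each
#'   denoised network.
#' @export
glance.msif_lnp_fit <- function(x, ...) {
  A <- x$associations
  tibble::tibble(
    n_microbes = nrow(A),
    n_diseases = ncol(A),
    n_associations = sum(A),
    density = mean(A),
    theta = x$params$theta,
    fusion_iters = x$params$fusion_iters,
    n_neighbors_microbe = x$params$n_neighbors_microbe,
    n_neighbors_disease = x$params$n_neighbors_disease,
    clipped_mass_microbe = x$network_microbe$clipped_mass,
    clipped_mass_disease = x$network_disease$clipped_mass
  )
}

#' Per-fold cross-validation results
#'
#' @param x A `msif_lnp_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per (repeat, fold): `repeat_`, `fold`,
#'   `auc`, `n_test`.
#' @export
tidy.msif_lnp_cv <- function(x, ...) {
  x$fold_auc
}

#' One-row cross-validation summary
#'
#' @param x A `msif_lnp_cv` object.
#' @param ... Unused.
#' @return A one-row tibble: `auc_mean`, `auc_sd` (over repeats), protocol
#'   settings and problem size.
#' @export
glance.msif_lnp_cv <- function(x, ...) {
  tibble::tibble(
    auc_mean = x$auc_mean,
    auc_sd = x$auc_sd,
    cv_folds = x$params$cv_folds,
    cv_repeats = x$params$cv_repeats,
    n_microbes = x$dim[1L],
    n_diseases = x$dim[2L],
    n_positives = x$n_positives,
    seed = x$params$seed
  )
}

#' Sweep results as a tibble
#'
#' @param x A `msif_lnp_sweep` object.
#' @param ... Unused.
#' @return The grid with `auc_mean` and `auc_sd` columns.
#' @export
tidy.msif_lnp_sweep <- function(x, ...) {
  x$results
}

#' One-row sweep summary (the best setting)
#'
#' @param x A `msif_lnp_sweep` object.
#' @param ... Unused.
#' @return The argmax row of the grid.
#' @export
glance.msif_lnp_sweep <- function(x, ...) {
  tibble::as_tibble(x$best)
}
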