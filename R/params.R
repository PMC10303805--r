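#' Model parameters
#'
#' Bundles every tunable of the fusion/propagation pipeline. Defaults are the
#' values selected on the HMDAD-scale benchmark (neighbourhood sizes
#' `n_neighbors_microbe = 5`, `n_neighbors_disease = 26`, `fusion_iters = 2`,
#' `theta = 0.2`); the remaining knobs carry their conventional values
#' (`gip_gamma = 1`, keep half the singular values, 10x10-fold CV).
#'
#' @param n_neighbors_microbe Number of neighbours per microbe used both for
#'   the linear-neighborhood reconstruction and for the neighbour-constraint
#'   kernel on the microbe side. Must satisfy
#'   `n_neighbors_microbe <= n_microbes - 1` for the data it is applied to.
#' @param n_neighbors_disease Same for the disease side.
#' @param fusion_iters Number of cross-iteration fusion steps (0 leaves the
#'   neighbour-constraint kernels untouched).
#' @param theta Propagation probability in (0, 1); labels retain their initial
#'   value at rate `1 - theta` per step.
#' @param gip_gamma Bandwidth multiplier of the Gaussian interaction-profile
#'   kernel.
#' @param svd_keep_fraction Fraction of singular values kept when denoising the
#'   fused network; the rank is `ceiling(svd_keep_fraction * n)`.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param cv_repeats Number of repetitions of the whole fold split.
#' @param seed Integer seed governing all randomness (fold splits).
#'
#' @return An object of class `msif_lnp_params` (a named list).
#' @examples
#' msif_lnp_params(theta = 0.3)
#' @export
msif_lnp_params <- function(n_neighbors_microbe = 5L,
                            n_neighbors_disease = 26L,
                            fusion_iters = 2L,
                            theta = 0.2,
                            gip_gamma = 1,
                            svd_keep_fraction = 0.5,
                            cv_folds = 10L,
                            cv_repeats = 10L,
                            seed = 1L) {
  check_count(n_neighbors_microbe, "n_neighbors_microbe", min = 1L)
  check_count(n_neighbors_disease, "n_neighbors_disease", min = 1L)
  check_count(fusion_iters, "fusion_iters", min = 0L)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    abort("`theta` must be a single number strictly inside (0, 1).")
  }
  if (!is.numeric(gip_gamma) || length(gip_gamma) != 1L || gip_gamma <= 0) {
    abort("`gip_gamma` must be a single positive number.")
  }
  if (!is.numeric(svd_keep_fraction) || length(svd_keep_fraction) != 1L ||
      svd_keep_fraction <= 0 || svd_keep_fraction > 1) {
    abort("`svd_keep_fraction` must lie in (0, 1].")
  }
  check_count(cv_folds, "cv_folds", min = 2L)
  check_count(cv_repeats, "cv_repeats", min = 1L)
  check_count(seed, "seed", min = -.Machine$integer.max)
  structure(
    list(
      n_neighbors_microbe = as.integer(n_neighbors_microbe),
      n_neighbors_disease = as.integer(n_neighbors_disease),
      fusion_iters = as.integer(fusion_iters),
      theta = theta,
      gip_gamma = gip_gamma,
      svd_keep_fraction = svd_keep_fraction,
      cv_folds = as.integer(cv_folds),
      cv_repeats = as.integer(cv_repeats),
      seed = as.integer(seed)
    ),
    class = "msif_lnp_params"
  )
}

check_count <- function(x, name, min) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  invisible(x)
}

# neighbourhood sizes only make sense relative to a concrete matrix
check_params_for <- function(params, A) {
  nm <- nrow(A)
  nd <- ncol(A)
  if (params$n_neighbors_microbe > nm - 1L) {
    abort(sprintf(
      "`n_neighbors_microbe` = %d but only %d microbes are present (need <= %d).",
      params$n_neighbors_microbe, nm, nm - 1L
    ))
  }
  if (params$n_neighbors_disease > nd - 1L) {
    abort(sprintf(
      "`n_neighbors_disease` = %d but only %d diseases are present (need <= %d).",
      params$n_neighbors_disease, nd, nd - 1L
    ))
  }
  invisible(params)
}

#' @export
print.msif_lnp_params <- function(x, ...) {
  cat("MSIF-LNP parameters\n")
  cat(sprintf("  neighbours: %d (microbe), %d (disease)\n",
              x$n_neighbors_microbe, x$n_neighbors_disease))
  cat(sprintf("  fusion iterations: %d   theta: %g   gip gamma: %g\n",
              x$fusion_iters, x$theta, x$gip_gamma))
  cat(sprintf("  svd keep fraction: %g\n", x$svd_keep_fraction))
  cat(sprintf("  CV: %d folds x %d repeats, seed %d\n",
              x$cv_folds, x$cv_repeats, x$seed))
  invisible(x)
}

# merge a named list of overrides (e.g. from YAML or CLI flags) into params
modify_params <- function(params, overrides) {
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  if (length(overrides) == 0L) return(params)
  known <- names(unclass(params))
  bad <- setdiff(names(overrides), known)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown parameter(s): %s", paste(bad, collapse = ", ")))
  }
  args <- utils::modifyList(unclass(params), overrides)
  do.call(msif_lnp_params, args)
}
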