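#' Row-normalize a similarity network into a transition matrix
#'
#' Divides every row with positive sum by that sum; all-zero rows stay zero.
#' The result has spectral radius at most 1, so `theta * K` is a strict
#' contraction for any `theta < 1` and the closed-form propagation is exact.
#'
#' @param K A square nonnegative matrix.
#' @return A (sub)row-stochastic matrix.
#' @export
normalize_transition <- function(K) {
  check_square_nonneg(K)
  rs <- rowSums(K)
  scale <- ifelse(rs > 0, rs, 1)
  K / scale
}

#' Closed-form label propagation
#'
#' Computes the fixed point of the diffusion
#' `H_{m+1} = theta * K %*% H_m + (1 - theta) * H_0`, which is
#' `(1 - theta) * (I - theta K)^{-1} H_0` whenever the Neumann series
#' converges (guaranteed after [normalize_transition()]). The linear system is
#' solved directly; the inverse is never formed.
#'
#' @param K Square transition matrix (n x n).
#' @param H0 Initial label matrix with n rows.
#' @param theta Propagation probability in (0, 1).
#' @return The propagated label matrix, same shape as `H0`.
#' @export
propagate_closed_form <- function(K, H0, theta) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) abort("`K` must be square.")
  H0 <- as.matrix(H0)
  if (nrow(H0) != nrow(K)) abort("`H0` must have as many rows as `K`.")
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    abort("`theta` must lie strictly inside (0, 1).")
  }
  M <- diag(nrow(K)) - theta * K
  H <- tryCatch(
    solve(M, H0),
    error = function(e) {
      abort(paste0(
        "Propagation system (I - theta*K) is numerically singular; ",
        "the spectral radius check rho(theta*K) < 1 failed. ",
        "Row-normalize K with normalize_transition() first."
      ))
    }
  )
  out <- (1 - theta) * H
  dimnames(out) <- dimnames(H0)
  out
}

#' Row-wise min-max normalization
#'
#' Maps each row affinely onto \[0, 1\] via `(y - min) / (max - min)`.
#' Constant rows (max equals min) map to all zeros: they carry no ranking
#' information and zero preserves the \[0, 1\] range contract.
#'
#' @param Y A numeric matrix.
#' @return The row-normalized matrix.
#' @export
minmax_rows <- function(Y) {
  Y <- as.matrix(Y)
  lo <- apply(Y, 1L, min)
  hi <- apply(Y, 1L, max)
  span <- hi - lo
  out <- (Y - lo) / ifelse(span > 0, span, 1)
  out[span == 0, ] <- 0
  dimnames(out) <- dimnames(Y)
  out
}

#' Fit the MSIF-LNP association predictor
#'
#' Runs the full pipeline on a binary microbe-disease association table: the
#' denoised microbe and disease similarity networks are built with
#' [build_network()], row-normalized, and the known associations are diffused
#' over each by closed-form label propagation. Scores are min-max normalized
#' per microbe (microbe side) and per disease (disease side) and the two
#' directions averaged into the final score matrix.
#'
#' @param x An edge data frame with (microbe, disease) columns, or a labeled
#'   0/1 matrix (microbes x diseases).
#' @param params A [msif_lnp_params()] object.
#' @return An object of class `msif_lnp_fit`. Access the final scores with
#'   [tidy()] (a long tibble) or through `$scores` (microbe x disease matrix
#'   with entries in \[0, 1\]).
#' @examples
#' sim <- simulate_associations(nm = 30, nd = 10, seed = 1)
#' fit <- msif_lnp(sim$edges, msif_lnp_params(n_neighbors_disease = 5))
#' dplyr::arrange(tidy(fit), dplyr::desc(score))
#' @export
msif_lnp <- function(x, params = msif_lnp_params()) {
  A <- validate_association(x)
  check_params_for(params, A)
  net_m <- build_network(A, "microbe", params)
  net_d <- build_network(A, "disease", params)
  Km <- normalize_transition(net_m$K)
  Kd <- normalize_transition(net_d$K)
  Ym <- minmax_rows(propagate_closed_form(Km, A, params$theta))
  Yd <- minmax_rows(propagate_closed_form(Kd, t(A), params$theta))
  Y <- (Ym + t(Yd)) / 2
  structure(
    list(
      scores = Y,
      scores_microbe_side = Ym,
      scores_disease_side = Yd,
      network_microbe = net_m,
      network_disease = net_d,
      associations = A,
      params = params
    ),
    class = "msif_lnp_fit"
  )
}

#' @export
print.msif_lnp_fit <- function(x, ...) {
  A <- x$associations
  cat(sprintf("MSIF-LNP fit: %d microbes x %d diseases, %d known associations\n",
              nrow(A), ncol(A), sum(A)))
  cat(sprintf("  theta = %g, fusion iterations = %d, neighbours = (%d, %d)\n",
              x$params$theta, x$params$fusion_iters,
              x$params$n_neighbors_microbe, x$params$n_neighbors_disease))
  top <- head(rank_predictions(x, exclude_known = TRUE), 3L)
  cat("  top novel predictions:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s - %s (%.3f)\n", top$microbe[i], top$disease[i], top$score[i]))
  }
  invisible(x)
}

#' Rank predicted associations
#'
#' Flattens a fitted score matrix into a ranked long table, optionally
#' dropping pairs already known (so the table lists candidate novel
#' associations, the way case studies are read). Ties in score are broken by
#' (microbe, disease) lexicographic order so the ranking is deterministic.
#'
#' @param fit A `msif_lnp_fit` object (or a bare score matrix plus
#'   `known` for exclusion).
#' @param top_n Keep only the first `top_n` rows (optional).
#' @param exclude_known Drop pairs with a known association before ranking.
#' @param known Binary matrix of known pairs; defaults to the fit's own.
#' @return A tibble with columns `microbe`, `disease`, `score`, `rank`.
#' @export
rank_predictions <- function(fit, top_n = NULL, exclude_known = FALSE,
                             known = NULL) {
  if (inherits(fit, "msif_lnp_fit")) {
    Y <- fit$scores
    known <- known %||% fit$associations
  } else {
    Y <- as.matrix(fit)
  }
  if (!is.null(top_n) && (!is.numeric(top_n) || length(top_n) != 1L || top_n <= 0)) {
    abort("`top_n` must be a single positive number.")
  }
  tab <- tibble::tibble(
    microbe = rep(rownames(Y), times = ncol(Y)),
    disease = rep(colnames(Y), each = nrow(Y)),
    score = as.vector(Y)
  )
  if (exclude_known) {
    if (is.null(known)) abort("`exclude_known` requires a `known` matrix.")
    ki <- known[cbind(match(tab$microbe, rownames(known)),
                      match(tab$disease, colnames(known)))]
    tab <- tab[is.na(ki) | ki == 0, ]
  }
  tab <- dplyr::arrange(tab, dplyr::desc(.data$score), .data$microbe, .data$disease)
  tab$rank <- seq_len(nrow(tab))
  if (!is.null(top_n)) tab <- head(tab, as.integer(top_n))
  tab
}

#' Write ranked prediction scores to a TSV file
#'
#' @inheritParams rank_predictions
#' @param path Output path; columns are `microbe`, `disease`, `score`, `rank`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(fit, path, top_n = NULL, exclude_known = FALSE,
                         known = NULL) {
  tab <- rank_predictions(fit, top_n = top_n, exclude_known = exclude_known,
                          known = known)
  tab$score <- sprintf("%.10g", tab$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
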