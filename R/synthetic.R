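#' Simulate a planted-block microbe-disease association matrix
#'
#' Generates a sparse binary bipartite matrix with recoverable structure:
#' microbes and diseases are split into `n_blocks` co-assorted groups (sizes
#' as equal as divisibility allows) and each cell is Bernoulli with
#' probability `p_within` when the two blocks match and `p_between` otherwise.
#' The defaults emulate the shape of curated microbe-disease catalogues
#' (a few hundred cells, overall density of a few percent) while planting
#' neighbourhood coherence the similarity kernels can detect. Rows or columns
#' that come out all-zero are retained: the pipeline's selective
#' normalization must tolerate them.
#'
#' @param nm,nd Numbers of microbes and diseases.
#' @param n_blocks Number of planted co-assorted blocks.
#' @param p_within,p_between Association probabilities inside / outside a
#'   matched block; recoverable structure needs `p_within > p_between`.
#' @param seed Integer seed; the draw is fully deterministic given the seed.
#' @return An object of class `planted_block_sim`: `associations` (labeled 0/1
#'   matrix), `edges` (tibble of the 1-cells), `microbe_block`,
#'   `disease_block` (ground-truth assignments) and `spec` (the arguments).
#' @examples
#' sim <- simulate_associations(nm = 20, nd = 8, seed = 1)
#' sum(sim$associations)
#' @export
simulate_associations <- function(nm = 80L, nd = 20L, n_blocks = 4L,
                                  p_within = 0.35, p_between = 0.02,
                                  seed = 7L) {
  check_count(nm, "nm", min = 1L)
  check_count(nd, "nd", min = 1L)
  check_count(n_blocks, "n_blocks", min = 1L)
  check_count(seed, "seed", min = -.Machine$integer.max)
  for (p in c(p_within, p_between)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      abort("`p_within` and `p_between` must be probabilities in [0, 1].")
    }
  }
  if (n_blocks > min(nm, nd)) {
    abort("`n_blocks` cannot exceed min(nm, nd).")
  }
  microbe_block <- sort(rep_len(seq_len(n_blocks), nm))
  disease_block <- sort(rep_len(seq_len(n_blocks), nd))
  P <- matrix(p_between, nm, nd)
  P[outer(microbe_block, disease_block, `==`)] <- p_within
  A <- withr::with_seed(seed, {
    matrix(rbinom(nm * nd, 1L, as.vector(P)), nm, nd)
  })
  storage.mode(A) <- "double"
  dimnames(A) <- list(sprintf("m%03d", seq_len(nm)), sprintf("d%03d", seq_len(nd)))
  structure(
    list(
      associations = A,
      edges = if (sum(A) > 0) as_edge_list(A) else
        tibble::tibble(microbe = character(), disease = character()),
      microbe_block = stats::setNames(microbe_block, rownames(A)),
      disease_block = stats::setNames(disease_block, colnames(A)),
      spec = list(nm = nm, nd = nd, n_blocks = n_blocks, p_within = p_within,
                  p_between = p_between, seed = seed)
    ),
    class = "planted_block_sim"
  )
}

#' @export
print.planted_block_sim <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Planted-block simulation: %d microbes x %d diseases, %d blocks\n",
              s$nm, s$nd, s$n_blocks))
  cat(sprintf("  p_within = %g, p_between = %g, seed = %d, %d associations (density %.1f%%)\n",
              s$p_within, s$p_between, s$seed, sum(x$associations),
              100 * mean(x$associations)))
  invisible(x)
}

#' Mask a fraction of known associations
#'
#' Sets `floor(fraction * n_positives)` uniformly sampled 1-cells to 0 — the
#' standalone counterpart of one cross-validation fold, handy for recovery
#' experiments.
#'
#' @param A Binary association matrix (or edge data frame).
#' @param fraction Fraction of positives to mask, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train` (the masked matrix) and `held_out` (tibble:
#'   microbe, disease, row, col of the masked cells).
#' @export
mask_positives <- function(A, fraction, seed = 1L) {
  A <- validate_association(A)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly inside (0, 1).")
  }
  check_count(seed, "seed", min = -.Machine$integer.max)
  pos <- which(A == 1, arr.ind = TRUE)
  n_mask <- floor(fraction * nrow(pos))
  if (n_mask == 0L) {
    return(list(train = A,
                held_out = tibble::tibble(microbe = character(),
                                          disease = character(),
                                          row = integer(), col = integer())))
  }
  picked <- withr::with_seed(seed, sample(nrow(pos), n_mask))
  masked <- pos[picked, , drop = FALSE]
  A_train <- A
  A_train[masked] <- 0
  list(
    train = A_train,
    held_out = tibble::tibble(
      microbe = rownames(A)[masked[, 1L]],
      disease = colnames(A)[masked[, 2L]],
      row = as.integer(masked[, 1L]),
      col = as.integer(masked[, 2L])
    )
  )
}
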