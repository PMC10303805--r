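# Association profiles for one entity type: microbes are rows of A, diseases
# are columns (transposed so profiles are always rows).
entity_profiles <- function(A, axis = c("microbe", "disease")) {
  axis <- match.arg(axis)
  if (axis == "microbe") A else t(A)
}

#' Cosine similarity between association profiles
#'
#' Similarity between two entities is the cosine of the angle between their
#' binary association profiles (rows of the matrix for microbes, columns for
#' diseases). Entities with an all-zero profile get similarity 0 to every
#' entity including themselves, so no 0/0 is ever formed; the downstream
#' selective normalization is built to skip the resulting all-zero columns.
#'
#' @param A Binary association matrix (or edge data frame).
#' @param axis `"microbe"` or `"disease"`.
#' @return A symmetric similarity matrix with entity labels, entries in
#'   \[0, 1\].
#' @examples
#' A <- association_matrix(tibble::tibble(m = c("m1", "m2"), d = c("d1", "d2")))
#' cosine_similarity(A, "microbe")
#' @export
cosine_similarity <- function(A, axis = c("microbe", "disease")) {
  A <- validate_association(A)
  P <- entity_profiles(A, axis)
  nrm <- sqrt(rowSums(P^2))
  S <- tcrossprod(P)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, S / denom, 0)
  # guard fp drift on the diagonal of nonzero profiles
  diag(S)[nrm > 0] <- 1
  dimnames(S) <- list(rownames(P), rownames(P))
  S
}

#' Gaussian interaction-profile kernel similarity
#'
#' The GIP kernel scores two entities by a Gaussian of the Euclidean distance
#' between their binary association profiles,
#' `S(i, j) = exp(-gamma_n * ||a_i - a_j||^2)`, with bandwidth
#' `gamma_n = gamma / mean_i(||a_i||^2)` so the kernel width adapts to the
#' overall profile density.
#'
#' @inheritParams cosine_similarity
#' @param gamma Bandwidth multiplier (conventionally 1).
#' @return Symmetric similarity matrix with unit diagonal, entries in (0, 1\].
#' @export
gip_similarity <- function(A, axis = c("microbe", "disease"), gamma = 1) {
  A <- validate_association(A)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    abort("`gamma` must be a single positive number.")
  }
  P <- entity_profiles(A, axis)
  sq <- rowSums(P^2)
  if (mean(sq) == 0) abort("GIP bandwidth undefined: all profiles are zero.")
  gamma_n <- gamma / mean(sq)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  S <- exp(-gamma_n * D2)
  S <- (S + t(S)) / 2
  dimnames(S) <- list(rownames(P), rownames(P))
  S
}

#' Linear-neighborhood similarity
#'
#' For each entity, finds its `k` nearest neighbours by Euclidean distance over
#' association profiles (self excluded; ties at the cut broken by ascending
#' index) and solves the small quadratic program
#' `min || t_i - sum_j w_ij t_j ||^2` subject to `sum_j w_ij = 1`, `w_ij >= 0`
#' over those neighbours. The optimal reconstruction weights form row `i` of
#' the similarity matrix; weights outside the neighbour set are 0. A ridge of
#' `1e-6` is added to the neighbour Gram matrix so duplicated profiles keep the
#' program strictly convex. Entities with an all-zero profile get an all-zero
#' row.
#'
#' @inheritParams cosine_similarity
#' @param k Neighbourhood size, `1 <= k <= n - 1`.
#' @return A row-wise similarity matrix: rows are nonnegative, have at most
#'   `k` nonzeros, zero diagonal, and sum to 1 (or 0 for zero profiles).
#' @export
linear_neighborhood_similarity <- function(A, axis = c("microbe", "disease"),
                                           k) {
  A <- validate_association(A)
  P <- entity_profiles(A, axis)
  n <- nrow(P)
  check_count(k, "k", min = 1L)
  if (k > n - 1L) {
    abort(sprintf("`k` = %d out of range: need 1 <= k <= %d entities minus self.", k, n - 1L))
  }
  W <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  sq <- rowSums(P^2)
  for (i in seq_len(n)) {
    if (sq[i] == 0) next
    d2 <- sq + sq[i] - 2 * drop(P %*% P[i, ])
    d2[i] <- Inf
    nbr <- order(d2, seq_len(n))[seq_len(k)]
    Tn <- P[nbr, , drop = FALSE]
    G <- tcrossprod(Tn)
    diag(G) <- diag(G) + 1e-6
    d <- drop(Tn %*% P[i, ])
    w <- tryCatch(
      solve_simplex_qp(G, d),
      error = function(e) {
        abort(sprintf("Neighborhood QP failed for entity '%s': %s",
                      rownames(P)[i], conditionMessage(e)))
      }
    )
    W[i, nbr] <- w
  }
  W
}

# min w'Gw - 2d'w  s.t.  sum(w) = 1, w >= 0, with G positive definite.
# quadprog solves min 1/2 b'Db - dvec'b, so D = 2G, dvec = 2d.
solve_simplex_qp <- function(G, d) {
  k <- length(d)
  if (k == 1L) return(1)
  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  sol <- quadprog::solve.QP(Dmat = 2 * G, dvec = 2 * d,
                            Amat = Amat, bvec = bvec, meq = 1L)
  w <- pmax(sol$solution, 0)
  w / sum(w)
}
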