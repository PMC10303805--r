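test_that("cosine similarity matches hand-computed values and conventions", {
  A <- matrix(c(1, 1, 0,
                1, 0, 1,
                0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("m", 1:3), paste0("d", 1:3)))
  S <- cosine_similarity(A, "microbe")
  expect_equal(S["m1", "m2"], 0.5) # (1,1,0).(1,0,1) / (sqrt2*sqrt2)
  expect_equal(S["m1", "m1"], 1)
  # zero profile: similarity 0 to everything including itself
  expect_equal(unname(S["m3", ]), c(0, 0, 0))
  expect_equal(S["m3", "m3"], 0)
  expect_identical(S, t(S))

  B <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_equal(cosine_similarity(B, "microbe")["m1", "m2"], 0) # orthogonal
  ident <- association_matrix(tibble::tibble(m = c("a", "b"), d = c("x", "x")))
  expect_equal(cosine_similarity(ident, "microbe")["a", "b"], 1) # identical profiles
})

test_that("GIP kernel matches the hand-evaluated bandwidth formula", {
  A <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("m1", "m2"), c("d1", "d2")))
  S <- gip_similarity(A, "microbe")
  # bandwidth = 1 / mean(profile norms^2) = 1/((1+1)/2) = 1; dist^2 = 2
  expect_equal(S["m1", "m2"], exp(-2), tolerance = 1e-12)
  expect_equal(diag(S), c(m1 = 1, m2 = 1))
  expect_identical(S, t(S))

  # two identical all-zero profiles are maximally similar (zero distance)
  Z <- matrix(c(1, 0, 0,
                0, 0, 0,
                0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("m", 1:3), paste0("d", 1:3)))
  Sz <- gip_similarity(Z, "microbe")
  expect_equal(Sz["m2", "m3"], 1)

  expect_error(gip_similarity(A, "microbe", gamma = -1), "positive")
})

test_that("linear-neighborhood weights satisfy the simplex contract", {
  set.seed(42)
  for (rep in 1:5) {
    A <- random_association(9, 6)
    k <- sample(1:4, 1)
    W <- linear_neighborhood_similarity(A, "microbe", k = k)
    expect_true(all(W >= 0))
    expect_equal(unname(diag(W)), rep(0, nrow(W)))
    nz <- rowSums(A) > 0
    expect_equal(unname(rowSums(W)[nz]), rep(1, sum(nz)), tolerance = 1e-8)
    expect_true(all(rowSums(W > 0) <= k))
    expect_true(all(rowSums(W[!nz, , drop = FALSE]) == 0))
  }
})

test_that("linear-neighborhood weights match hand-derivable cases", {
  # k = 1: the single neighbour takes the whole simplex
  A <- matrix(c(1, 1, 0,
                1, 0, 1,
                0, 1, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("m", 1:3), paste0("d", 1:3)))
  W1 <- linear_neighborhood_similarity(A, "microbe", k = 1)
  expect_equal(unname(rowSums(W1)), rep(1, 3))
  expect_true(all(apply(W1, 1, max) == 1))

  # entity equidistant from two neighbours placed symmetrically: 0.5 / 0.5
  A2 <- matrix(c(1, 1, 0, 0,
                 1, 0, 0, 1,
                 0, 1, 1, 0), 3, 4, byrow = TRUE,
              dimnames = list(paste0("m", 1:3), paste0("d", 1:4)))
  W2 <- linear_neighborhood_similarity(A2, "microbe", k = 2)
  expect_equal(unname(W2[1, 2:3]), c(0.5, 0.5), tolerance = 1e-6)

  # entity whose profile equals one neighbour exactly: near-unit weight there
  A3 <- matrix(c(1, 1, 0, 0,
                 1, 1, 0, 0,
                 0, 0, 1, 1), 3, 4, byrow = TRUE,
              dimnames = list(paste0("m", 1:3), paste0("d", 1:4)))
  W3 <- linear_neighborhood_similarity(A3, "microbe", k = 2)
  expect_gte(W3[1, 2], 1 - 1e-6)

  expect_error(linear_neighborhood_similarity(A, "microbe", k = 3), "out of range")
})

test_that("QP solution matches the exhaustive simplex grid-search oracle", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    nd <- sample(4:8, 1)
    A <- random_association(n, nd, density = 0.4)
    k <- sample(1:3, 1)
    W <- linear_neighborhood_similarity(A, "microbe", k = k)
    P <- A
    sq <- rowSums(P^2)
    for (i in which(sq > 0)) {
      d2 <- sq + sq[i] - 2 * drop(P %*% P[i, ])
      d2[i] <- Inf
      nbr <- order(d2, seq_len(n))[seq_len(k)]
      Tn <- P[nbr, , drop = FALSE]
      G <- tcrossprod(Tn)
      diag(G) <- diag(G) + 1e-6
      d <- drop(Tn %*% P[i, ])
      oracle <- grid_search_simplex(G, d, step = 1e-3)
      w <- W[i, nbr]
      obj <- drop(t(w) %*% G %*% w - 2 * sum(d * w))
      expect_lte(obj, oracle$objective + 1e-3)
    }
  }
})

test_that("similarities are equivariant under simultaneous permutation", {
  # cosine and GIP are elementwise formulas: exactly equivariant on any data
  set.seed(5)
  A <- random_association(8, 6, density = 0.45)
  perm <- sample(nrow(A))
  Ap <- A[perm, , drop = FALSE]
  for (f in list(
    function(x) cosine_similarity(x, "microbe"),
    function(x) gip_similarity(x, "microbe")
  )) {
    expect_equal(unname(f(Ap)), unname(f(A)[perm, perm]), tolerance = 1e-12)
  }

  # top-k selection breaks distance ties by entity index, so the
  # linear-neighborhood map is equivariant whenever selection is unambiguous
  B <- tie_free_association()
  permb <- c(3L, 5L, 1L, 4L, 2L)
  W <- linear_neighborhood_similarity(B, "microbe", k = 2)
  Wp <- linear_neighborhood_similarity(B[permb, , drop = FALSE], "microbe", k = 2)
  expect_equal(unname(Wp), unname(W[permb, permb]), tolerance = 1e-10)
})
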