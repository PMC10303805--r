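test_that("selective column normalization skips all-zero columns", {
  S <- matrix(c(1, 1, 0,
                1, 3, 0,
                2, 0, 0), 3, 3, byrow = TRUE)
  out <- selective_column_normalize(S)
  expect_equal(out[, 1], c(0.25, 0.25, 0.5))
  expect_equal(sum(out[, 2]), 1)
  expect_equal(out[, 3], c(0, 0, 0)) # untouched, no NaN
  expect_false(anyNA(out))

  expect_identical(selective_column_normalize(diag(3)), diag(3))
  expect_error(selective_column_normalize(matrix(c(1, -1, 0, 1), 2, 2)),
               "nonnegative")
})

test_that("neighbour-constraint kernel keeps self plus strongest entries", {
  S <- matrix(c(1, 0.2, 0.1,
                0.2, 1, 0.6,
                0.1, 0.6, 1), 3, 3, byrow = TRUE)
  out <- neighbor_constraint_kernel(S, 2)
  expect_equal(out[2, ], c(0, 0.625, 0.375)) # self (1.0) + strongest other (0.6)

  # n_neighbors = n reduces to plain row normalization
  full <- neighbor_constraint_kernel(S, 3)
  expect_equal(full, S / rowSums(S))

  # n_neighbors = 1 with unit diagonal keeps only self
  expect_equal(neighbor_constraint_kernel(S, 1), diag(3))

  # ties at the cut break toward the smaller column index
  St <- matrix(c(1, 0.5, 0.5,
                 0.5, 1, 0.5,
                 0.5, 0.5, 1), 3, 3, byrow = TRUE)
  tied <- neighbor_constraint_kernel(St, 2)
  expect_equal(tied[1, ], c(1 / 1.5, 0.5 / 1.5, 0))

  # all-zero rows stay all-zero
  Sz <- rbind(c(0, 0), c(1, 1))
  expect_equal(neighbor_constraint_kernel(Sz, 2)[1, ], c(0, 0))

  expect_error(neighbor_constraint_kernel(S, 4), "out of range")
})

test_that("cross-iteration follows the printed update and its fixed points", {
  id3 <- replicate(3, diag(2), simplify = FALSE)
  expect_equal(cross_iterate(id3, id3, 5), id3) # I (2I/2) I = I

  set.seed(1)
  MS <- replicate(3, matrix(runif(4), 2, 2), simplify = FALSE)
  LMS <- replicate(3, matrix(runif(4), 2, 2), simplify = FALSE)
  expect_identical(cross_iterate(MS, LMS, 0), LMS) # x = 0: untouched

  # straight-line oracle: multiply the update out by hand, twice
  cur <- LMS
  for (step in 1:2) {
    nxt <- list(
      MS[[1]] %*% ((cur[[2]] + cur[[3]]) / 2) %*% t(MS[[1]]),
      MS[[2]] %*% ((cur[[1]] + cur[[3]]) / 2) %*% t(MS[[2]]),
      MS[[3]] %*% ((cur[[1]] + cur[[2]]) / 2) %*% t(MS[[3]])
    )
    cur <- nxt
  }
  got <- cross_iterate(MS, LMS, 2)
  expect_equal(got, cur, tolerance = 1e-12)

  # fusion is the entrywise mean of the iterates
  expect_equal(fuse_kernels(MS, LMS, 2), (cur[[1]] + cur[[2]] + cur[[3]]) / 3,
               tolerance = 1e-12)
  expect_equal(fuse_kernels(id3, id3, 3), diag(2)) # mean of equal iterates

  # nonnegativity is preserved at every iterate
  nn <- cross_iterate(MS, LMS, 4)
  expect_true(all(vapply(nn, function(m) all(m >= 0), logical(1))))

  bad <- list(diag(2), diag(2), diag(3))
  expect_error(cross_iterate(bad, id3, 1), "dimensions")
})

test_that("SVD denoising reconstructs exactly at full rank and is Eckart-Young optimal", {
  set.seed(3)
  K <- matrix(runif(16), 4, 4)
  dimnames(K) <- list(paste0("e", 1:4), paste0("e", 1:4))
  full <- svd_denoise(K, keep_fraction = 1)
  expect_lt(norm(full$reconstruction - K, "F"), 1e-8)
  expect_equal(full$rank_kept, 4L)

  r1 <- tcrossprod(runif(5), runif(5))
  dimnames(r1) <- list(paste0("a", 1:5), paste0("a", 1:5))
  expect_lt(norm(svd_denoise(r1, keep_fraction = 0.2)$reconstruction - r1, "F"), 1e-8)

  # rank-2 reconstruction matches the independent eigendecomposition oracle
  half <- svd_denoise(K, keep_fraction = 0.5)
  expect_equal(half$rank_kept, 2L)
  expect_lt(norm(half$reconstruction - best_rank_r_eigen(K, 2), "F"), 1e-6)

  # reconstruction error is nonincreasing in the retained rank
  errs <- vapply(1:4, function(r) {
    norm(svd_denoise(K, keep_fraction = r / 4)$reconstruction - K, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))

  # negative entries of the reconstruction are clipped, and accounted for
  neg <- matrix(c(4, 1, 1, 1, 4, -2, 1, -2, 4), 3, 3)
  den <- svd_denoise(neg, keep_fraction = 2 / 3)
  expect_true(all(den$K >= 0))
  expect_gte(den$clipped_mass, 0)
})

test_that("build_network composes the stages with the documented invariants", {
  sim <- simulate_associations(nm = 30, nd = 12, n_blocks = 3, seed = 2)
  A <- sim$associations
  p <- msif_lnp_params(n_neighbors_microbe = 5, n_neighbors_disease = 5)

  net_m <- build_network(A, "microbe", p)
  net_d <- build_network(A, "disease", p)
  expect_identical(dim(net_m$K), c(30L, 30L))
  expect_identical(dim(net_d$K), c(12L, 12L))

  k <- 5
  for (net in list(net_m, net_d)) {
    for (MS in net$initial_kernels) {
      src_nonzero <- colSums(MS) > 0
      expect_equal(unname(colSums(MS)[src_nonzero]),
                   rep(1, sum(src_nonzero)), tolerance = 1e-8)
    }
    for (LMS in net$neighbor_kernels) {
      rs <- rowSums(LMS)
      expect_true(all(abs(rs[rs > 0] - 1) < 1e-8))
      expect_true(all(rowSums(LMS > 0) <= k))
    }
    expect_true(all(net$K_raw >= 0))
    expect_true(all(net$K >= 0))
  }

  # deterministic: identical inputs give bit-identical networks
  net_m2 <- build_network(A, "microbe", p)
  expect_identical(net_m$K, net_m2$K)
  expect_identical(net_m$singular_values, net_m2$singular_values)

  # planted structure survives fusion: within-block mean above between-block
  simd <- simulate_associations(seed = 7)
  pd <- msif_lnp_params(n_neighbors_disease = 13)
  K <- build_network(simd$associations, "microbe", pd)$K
  bm <- simd$microbe_block
  same <- outer(bm, bm, `==`)
  diag(same) <- NA
  expect_gt(mean(K[same & !is.na(same)]), mean(K[!same & !is.na(same)]))
})

test_that("build_network is permutation-equivariant when selection is unambiguous", {
  A <- tie_free_association()
  p <- msif_lnp_params(n_neighbors_microbe = 2, n_neighbors_disease = 3)
  perm <- c(4L, 1L, 5L, 2L, 3L)
  K <- build_network(A, "microbe", p)$K
  Kp <- build_network(A[perm, , drop = FALSE], "microbe", p)$K
  expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-10)
})
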