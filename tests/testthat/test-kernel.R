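test_that("interaction-profile kernel matches the 2x2 hand computation", {
  A <- diag(2)
  dimnames(A) <- list(c("m1", "m2"), c("d1", "d2"))
  gd <- gip_kernel(A, "diseases")
  # both profiles have norm 1, bandwidth 1, distance^2 = 2
  expect_equal(gd["d1", "d2"], exp(-2))
  expect_equal(diag(unclass(gd)), c(d1 = 1, d2 = 1))
  gr <- gip_kernel(A, "mirnas")
  expect_equal(gr["m1", "m2"], exp(-2))

  # identical profiles are maximally similar
  B <- matrix(c(1, 0, 1, 0), 2, dimnames = list(c("m1", "m2"),
                                                c("d1", "d2")))
  expect_equal(gip_kernel(B, "diseases")["d1", "d2"], 1)

  Z <- matrix(0, 2, 2, dimnames = dimnames(A))
  expect_error(gip_kernel(Z, "diseases"), "bandwidth undefined")
})

test_that("kernel similarity is symmetric, in (0,1], monotone in distance", {
  set.seed(21)
  for (rep in 1:10) {
    A <- random_binary(sample(5:10, 1), sample(5:10, 1))
    for (axis in c("diseases", "mirnas")) {
      K <- gip_kernel(A, axis)
      expect_equal(unclass(K), t(unclass(K)))
      expect_true(all(K > 0 & K <= 1))
      expect_equal(unname(diag(unclass(K))), rep(1, nrow(K)))
    }
  }
  # for binary profiles, squared distance = Hamming distance: similarity
  # strictly decreases as profiles disagree in more positions
  A <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 1))
  dimnames(A) <- list(paste0("m", 1:4), paste0("d", 1:4))
  gr <- gip_kernel(A, "mirnas")
  expect_gt(gr["m1", "m2"], gr["m1", "m3"])
  expect_gt(gr["m1", "m3"], gr["m1", "m4"])
})

test_that("integration averages where defined and falls back to the kernel", {
  nm <- list(c("a", "b"), c("a", "b"))
  gd <- similarity_matrix(matrix(c(1, .4, .4, 1), 2, dimnames = nm), "GD")
  ss <- similarity_matrix(matrix(c(1, .6, .6, 1), 2, dimnames = nm), "SS")
  attr(ss, "has_dag") <- c(a = TRUE, b = TRUE)
  sd <- integrate_disease(ss, gd)
  expect_equal(sd["a", "b"], 0.5)
  # one disease without a DAG: kernel fallback
  attr(ss, "has_dag") <- c(a = TRUE, b = FALSE)
  expect_equal(integrate_disease(ss, gd)["a", "b"], 0.4)
  # no DAGs at all: SD = GD entrywise
  attr(ss, "has_dag") <- c(a = FALSE, b = FALSE)
  expect_equal(unclass(integrate_disease(ss, gd)), unclass(gd),
               ignore_attr = TRUE)

  gr <- similarity_matrix(matrix(c(1, .2, .2, 1), 2, dimnames = nm), "GR")
  ms <- similarity_matrix(matrix(c(1, .8, .8, 1), 2, dimnames = nm), "MS")
  expect_equal(integrate_mirna(ms, gr)["a", "b"], 0.5)
  # miRNA absent from the functional-similarity index: kernel fallback
  ms1 <- similarity_matrix(matrix(1, 1, 1, dimnames = list("a", "a")), "MS")
  expect_equal(integrate_mirna(ms1, gr)["a", "b"], 0.2)
  expect_equal(unclass(integrate_mirna(gr, gr)), unclass(gr),
               ignore_attr = TRUE)
})

test_that("symmetric normalization has the stated fixed points and safety", {
  nm <- list(letters[1:3], letters[1:3])
  ones <- similarity_matrix(matrix(1, 3, 3, dimnames = nm), "SD")
  N <- symmetric_normalize(ones)
  expect_equal(unclass(N), matrix(1 / 3, 3, 3, dimnames = nm),
               ignore_attr = TRUE)
  expect_true(attr(N, "normalized"))

  # identity is a fixed point (unit row sums)
  I <- diag(3); dimnames(I) <- nm
  expect_equal(unclass(symmetric_normalize(similarity_matrix(I, "SD"))),
               I, ignore_attr = TRUE)

  Z <- matrix(c(0, 0, 0, 0, 1, .5, 0, .5, 1), 3, dimnames = nm)
  NZ <- symmetric_normalize(similarity_matrix(Z, "SD"))
  expect_equal(unname(unclass(NZ)[1, ]), c(0, 0, 0))
  expect_false(anyNA(NZ))
})

test_that("normalization is scale-invariant and keeps spectral radius <= 1", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    S <- matrix(runif(k * k), k)
    S <- (S + t(S)) / 2
    dimnames(S) <- list(paste0("x", 1:k), paste0("x", 1:k))
    sm <- similarity_matrix(S, "SD")
    N <- symmetric_normalize(sm)
    # uniform pre-scaling cancels exactly in the normalization
    w <- runif(1, 0.1, 0.9)
    Nw <- symmetric_normalize(similarity_matrix(S * w, "SD"))
    expect_equal(unclass(Nw), unclass(N), tolerance = 1e-12)
    expect_equal(unclass(N), t(unclass(N)))
    expect_lte(max(abs(eigen(unclass(N), only.values = TRUE)$values)),
               1 + 1e-10)
  }
})

test_that("edge weights scale only after normalization and are validated", {
  set.seed(32)
  S <- matrix(runif(16), 4); S <- (S + t(S)) / 2
  dimnames(S) <- list(paste0("x", 1:4), paste0("x", 1:4))
  N <- symmetric_normalize(similarity_matrix(S, "SR"))
  M <- symmetric_normalize(similarity_matrix(S, "SD"))
  w <- apply_edge_weights(N, M, edge_weights(w_mm = 0.5, w_dd = 0.25))
  expect_equal(unclass(w$sr), unclass(N) * 0.5, ignore_attr = TRUE)
  expect_equal(unclass(w$sd), unclass(M) * 0.25, ignore_attr = TRUE)
  expect_true(attr(w$sr, "normalized"))
  # unit weights are a no-op
  w1 <- apply_edge_weights(N, M, edge_weights())
  expect_equal(unclass(w1$sr), unclass(N))
  expect_error(edge_weights(w_mm = 1.5), "\\[0, 1\\]")
  raw <- similarity_matrix(S, "SR")
  expect_error(apply_edge_weights(raw, M), "normalized")
})
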