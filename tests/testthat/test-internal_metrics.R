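# Internal validity indices: hand-derived micro-examples, degenerate
# conventions, invariances, and equivalence with independent oracles.

test_that("silhouette matches hand evaluation on 1-D micro-examples", {
  # duplicate points, perfect separation -> every width 1
  x <- matrix(c(0, 0, 10, 10), ncol = 1,
              dimnames = list(paste0("s", 1:4), "f1"))
  a <- make_assignment(c(1, 1, 2, 2), ids = rownames(x))
  expect_equal(silhouetteScore(x, a), 1)

  # {0,1} vs {10,11}: widths 0.904762, 0.894737, 0.894737, 0.904762
  x2 <- matrix(c(0, 1, 10, 11), ncol = 1,
               dimnames = list(paste0("s", 1:4), "f1"))
  expect_equal(silhouetteScore(x2, a),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)),
               tolerance = 1e-12)

  # coincident points give a = b for every sample; the width is 0 there
  x3 <- matrix(rep(2, 4), ncol = 1,
               dimnames = list(paste0("s", 1:4), "f1"))
  a3 <- make_assignment(c(1, 2, 2, 1), ids = rownames(x3))
  expect_equal(silhouetteScore(x3, a3), 0)
})

test_that("Calinski-Harabasz matches the scatter-trace formula", {
  # {0,1} and {10,11}: tr(B) = 100, tr(W) = 1, CH = 100 * 2 / 1 = 200
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(paste0("s", 1:4), "f1"))
  a <- make_assignment(c(1, 1, 2, 2), ids = rownames(x))
  expect_equal(calinskiHarabasz(x, a), 200, tolerance = 1e-12)

  # every cluster mean equals the global mean -> tr(B) = 0 -> CH = 0
  x2 <- matrix(c(0, 2, -1, 3), ncol = 1,
               dimnames = list(paste0("s", 1:4), "f1"))
  a2 <- make_assignment(c(1, 1, 2, 2), ids = rownames(x2))
  expect_equal(calinskiHarabasz(x2, a2), 0)

  # all clusters point masses -> infinite sentinel with warning
  x3 <- matrix(c(0, 0, 5, 5), ncol = 1,
               dimnames = list(paste0("s", 1:4), "f1"))
  expect_warning(ch <- calinskiHarabasz(x3, a), "point masses")
  expect_identical(ch, Inf)
})

test_that("Dunn's index divides min single-linkage distance by max diameter", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1,
              dimnames = list(paste0("s", 1:4), "f1"))
  a <- make_assignment(c(1, 1, 2, 2), ids = rownames(x))
  expect_equal(dunnIndex(x, a), 9)          # min inter 9, max diam 1
  expect_equal(dunnIndex(x * 7, a), 9)      # ratio is scale-invariant

  # a point duplicated across clusters -> numerator 0 -> D = 0
  x2 <- matrix(c(0, 1, 1, 11), ncol = 1,
               dimnames = list(paste0("s", 1:4), "f1"))
  expect_equal(dunnIndex(x2, a), 0)

  x3 <- matrix(c(0, 5), ncol = 1, dimnames = list(c("s1", "s2"), "f1"))
  a3 <- make_assignment(c(1, 2))
  expect_warning(d <- dunnIndex(x3, a3), "singletons")
  expect_identical(d, Inf)
})

test_that("a single cluster is rejected for every index", {
  x <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  a1 <- make_assignment(c(1, 1, 1))
  expect_error(silhouetteScore(x, a1), "single cluster")
  expect_error(calinskiHarabasz(x, a1), "single cluster")
  expect_error(dunnIndex(x, a1), "single cluster")
})

test_that("indices are invariant to sample permutation and cluster relabeling", {
  set.seed(7)
  for (rep_i in 1:5) {
    inst <- random_instance(n = 30, dims = 3, k = 3)
    x <- inst$x; a <- inst$assign
    perm <- sample(nrow(x))
    xp <- x[perm, , drop = FALSE]
    ap <- make_assignment(clusterLabels(a)[perm], ids = rownames(xp))
    relab <- c(3L, 1L, 2L)
    ar <- make_assignment(relab[clusterLabels(a)], ids = rownames(x))
    for (f in list(silhouetteScore, calinskiHarabasz, dunnIndex)) {
      v <- f(x, a)
      expect_equal(f(xp, ap), v, tolerance = 1e-12)
      expect_equal(f(x, ar), v, tolerance = 1e-12)
    }
  }
})

test_that("moving clusters further apart never decreases any index", {
  set.seed(21)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 4), 10, 2))
  dimnames(x) <- list(sprintf("s%d", 1:20), c("a", "b"))
  a <- make_assignment(rep(1:2, each = 10), ids = rownames(x))
  base <- c(silhouetteScore(x, a), calinskiHarabasz(x, a), dunnIndex(x, a))
  x2 <- x; x2[11:20, ] <- x2[11:20, ] + 5
  moved <- c(silhouetteScore(x2, a), calinskiHarabasz(x2, a), dunnIndex(x2, a))
  expect_true(all(moved >= base))
})

test_that("silhouette and CH match independent oracles on random instances", {
  skip_if_not_installed("cluster")
  set.seed(99)
  for (rep_i in 1:10) {
    k <- sample(2:4, 1)
    inst <- random_instance(n = sample(10:50, 1), dims = sample(1:5, 1), k = k)
    x <- inst$x; a <- inst$assign; lab <- unname(clusterLabels(a))
    sil_ref <- mean(cluster::silhouette(lab, stats::dist(x))[, "sil_width"])
    expect_equal(silhouetteScore(x, a), sil_ref, tolerance = 1e-9)
    expect_equal(calinskiHarabasz(x, a), ch_oracle(x, lab), tolerance = 1e-9)
    expect_equal(dunnIndex(x, a), dunn_oracle(x, lab), tolerance = 1e-9)
  }
})

test_that("representation strategies behave as documented", {
  v1 <- matrix(rnorm(12), 4, 3,
               dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  v2 <- matrix(rnorm(8), 4, 2,
               dimnames = list(paste0("s", 1:4), paste0("cn", 1:2)))
  ds <- OmicsDataset(list(OmicsMatrix(v1, "mrna"),
                          OmicsMatrix(v2, "copy_number")))
  rep <- buildRepresentation(ds)
  expect_identical(dim(rep), c(4L, 5L))
  # canonical kind order puts copy_number first
  expect_identical(colnames(rep), c(paste0("cn", 1:2), paste0("g", 1:3)))

  one <- OmicsDataset(list(OmicsMatrix(v1, "mrna")))
  expect_identical(buildRepresentation(one), v1)

  # per-omics averaging of identical layers equals the single-layer value
  v1b <- v1
  colnames(v1b) <- paste0("h", 1:3)
  ds_same <- OmicsDataset(list(OmicsMatrix(v1, "mrna"),
                               OmicsMatrix(v1b, "mirna")))
  a <- make_assignment(c(1, 1, 2, 2), ids = paste0("s", 1:4))
  per <- internalMetrics(ds_same, a, strategy = "per_omics")
  single <- internalMetrics(one, a, strategy = "concatenate")
  expect_equal(per, single, tolerance = 1e-12)
})
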