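test_that("relationship matrix equals the hand-computed centered crossproduct", {
  calls <- rbind(X1 = c(0L, 2L, 0L, 2L),
                 X2 = c(2L, 0L, 0L, 2L),
                 X3 = c(0L, 2L, 2L, 0L))
  gm <- genotype_matrix(calls, data.frame(id = paste0("s", 1:4), chrom = "c1",
                                          pos = 1:4, ref = "A", alt = "G"))
  p <- colMeans(calls) / 2
  W <- sweep(calls, 2, 2 * p)
  A_hand <- W %*% t(W) / (2 * sum(p * (1 - p)))
  A <- relationship_matrix(gm)
  expect_equal(unclass(A), A_hand, ignore_attr = TRUE)
  # column centering makes the matrix total ~0
  expect_equal(sum(A), 0, tolerance = 1e-10)

  # identical fully homozygous samples: off-diagonal equals the diagonal
  dup <- gm_from_cols(list(c(0L, 0L, 2L), c(2L, 2L, 0L), c(0L, 0L, 2L)))
  Ad <- relationship_matrix(dup)
  expect_equal(Ad[1, 2], Ad[1, 1])
})

test_that("PCA reconstructs the matrix and separates a two-block structure", {
  sim <- default_sim()
  A <- relationship_matrix(sim$geno)
  pc_full <- relationship_pca(A, n_components = nrow(A))
  recon <- pc_full$vectors %*% diag(pc_full$eigenvalues) %*% t(pc_full$vectors)
  expect_lt(max(abs(recon - A)), 1e-8)

  part <- as_partition(sim$passport)
  pc <- relationship_pca(A)
  s1 <- pc$scores[group_samples(part, "L1"), 1]
  s2 <- pc$scores[group_samples(part, "L2"), 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_lte(sum(pc$variance_explained), 1)

  expect_error(relationship_pca(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("Euclidean distances rescale for missing data", {
  gm <- gm_from_cols(list(c(0L, 2L), c(0L, 2L), c(0L, 2L)))
  d <- euclidean_distance(gm)
  expect_equal(as.matrix(d)["X001", "X002"], sqrt(12))

  same <- gm_from_cols(list(c(1L, 1L), c(2L, 2L)))
  expect_equal(as.matrix(euclidean_distance(same))[1, 2], 0)

  # one of three sites missing, remaining diffs (2, 2): sqrt(3/2 * 8)
  calls <- rbind(X1 = c(0L, 0L, 0L), X2 = c(NA, 2L, 2L))
  gmm <- genotype_matrix(calls, data.frame(id = paste0("s", 1:3), chrom = "c1",
                                           pos = 1:3, ref = "A", alt = "G"))
  expect_equal(as.matrix(euclidean_distance(gmm))[1, 2], sqrt(3 / 2 * 8))

  # a pair with no co-observed sites is an error naming the pair
  calls2 <- rbind(X1 = c(0L, NA), X2 = c(NA, 2L), X3 = c(0L, 2L))
  gm2 <- genotype_matrix(calls2, data.frame(id = paste0("s", 1:2), chrom = "c1",
                                            pos = 1:2, ref = "A", alt = "G"))
  expect_error(euclidean_distance(gm2), "X1.*X2")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4 taxa from tree ((A:1,B:2):1,C:3,D:1)
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- D + t(D)
  tr <- nj_tree(D)
  cp <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(cp, D, tolerance = 1e-10)
  target <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(target)), 0,
               ignore_attr = TRUE)

  # 3 taxa: closed-form star lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  len <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(len[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  expect_error(nj_tree(D3[1:2, 1:2]), "at least 3")
})

test_that("tree topology is invariant to input order", {
  set.seed(91)
  true <- ape::unroot(ape::rtree(8))
  D <- ape::cophenetic.phylo(true)
  perm <- sample(rownames(D))
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t1, f)
  expect_s3_class(ape::read.tree(f), "phylo")
})

test_that("PC-geography correlations hit the closed-form anchors", {
  # PC3 is a centered quadratic in rank: orthogonal to the linear longitude
  quad <- (1:10 - 5.5)^2
  scores <- cbind(PC1 = rnorm(10), PC2 = 1:10, PC3 = quad - mean(quad))
  rownames(scores) <- sprintf("S%02d", 1:10)
  pca <- list(scores = scores)
  pass <- data.frame(id = rownames(scores), group = "L1", country = NA,
                     longitude = 1:10,                      # equals PC2
                     latitude = rep(c(1, -1), 5) * 0 + 5,   # constant
                     altitude = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  res <- suppressWarnings(pc_geo_correlation(pca, pass))
  r_lon <- res$r[res$component == 2 & res$variable == "longitude"]
  expect_equal(r_lon, 1)
  # orthogonal construction: PC3 vs longitude
  r3 <- res$r[res$component == 3 & res$variable == "longitude"]
  expect_equal(r3, 0, tolerance = 1e-12)
})
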