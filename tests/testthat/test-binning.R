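test_that("coverage transform is log-unit-norm with zero-row handling", {
  cov <- coverage_matrix(
    matrix(c(99, 0,
             10, 100,
             20, 200,
             0, 0), 4, 2, byrow = TRUE,
           dimnames = list(paste0("c", 1:4), c("s1", "s2"))),
    lengths = rep(1000L, 4)
  )
  m <- transform_coverage(cov, pseudocount = 1)
  expect_equal(unname(m["c1", ]), c(1, 0))          # (log10 100, 0) / norm
  expect_equal(unname(m["c4", ]), c(0, 0))          # all-zero row
  expect_equal(unname(sqrt(rowSums(m[1:3, ]^2))), rep(1, 3))

  # proportional rows land close in direction (the scale factor becomes an
  # additive log offset), and converge as coverage magnitude grows
  m_small <- transform_coverage(cov, pseudocount = 1e-8)
  expect_lt(sum(abs(m_small["c2", ] - m_small["c3", ])), 0.1)
  gap_at <- function(scale) {
    cv <- coverage_matrix(
      rbind(a = scale * c(10, 100), b = scale * c(20, 200)),
      lengths = c(1000L, 1000L)
    )
    m <- transform_coverage(cv, pseudocount = 1e-8)
    sum(abs(m["a", ] - m["b", ]))
  }
  gaps <- vapply(c(1, 100, 10000), gap_at, 0)
  expect_true(all(diff(gaps) < 0))

  bad <- cov
  bad$values[1, 1] <- -1
  expect_error(coverage_matrix(bad$values, bad$length), ">= 0")
})

test_that("3-D projection is a variance-ordered orthogonal projection", {
  set.seed(1)
  # 2-sample input: third coordinate identically zero
  m2 <- matrix(rnorm(40), 20, 2)
  emb2 <- project_3d(m2)
  expect_equal(unname(emb2[, 3]), rep(0, 20))

  # data in a 2-plane embedded in 5 dims: third-axis variance ~ 0
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  planar <- matrix(rnorm(60), 30, 2) %*% t(basis)
  emb_p <- project_3d(planar)
  expect_lt(stats::var(emb_p[, 3]), 1e-20)

  # retained variance <= total variance; axes ordered by variance
  m5 <- matrix(rnorm(200), 40, 5)
  emb5 <- project_3d(m5)
  v <- apply(emb5, 2, stats::var)
  expect_true(all(diff(v) <= 1e-12))
  expect_lte(sum(v), sum(apply(m5, 2, stats::var)) + 1e-12)

  # full-rank 3-column data loses nothing
  m3 <- matrix(rnorm(90), 30, 3)
  expect_equal(sum(apply(project_3d(m3), 2, stats::var)),
               sum(apply(m3, 2, stats::var)))
})

test_that("single-linkage clustering separates distant clouds", {
  set.seed(2)
  cloud <- function(center, n) {
    sweep(matrix(rnorm(3 * n, sd = 0.001), n, 3), 2, center, `+`)
  }
  emb <- rbind(cloud(c(0, 0, 0), 50), cloud(c(0.5, 0, 0), 50))
  rownames(emb) <- paste0("c", 1:100)
  assign <- cluster_contigs(emb, min_bin_size = 10, linkage_dist = 0.05)
  expect_equal(sort(unique(assign$bin_id)), c("bin_001", "bin_002"))
  truth <- setNames(rep(c("gA", "gB"), each = 50), rownames(emb))
  pr <- binning_purity(assign, truth)
  expect_equal(pr$purity, c(1, 1))
  expect_equal(pr$recall, c(1, 1))

  # all points identical -> one bin
  same <- matrix(0, 10, 3, dimnames = list(paste0("x", 1:10), NULL))
  expect_equal(unique(cluster_contigs(same, 5, 0.05)$bin_id), "bin_001")

  # too few points -> all unbinned
  few <- matrix(rnorm(9), 3, 3, dimnames = list(paste0("y", 1:3), NULL))
  expect_equal(unique(cluster_contigs(few, 10, 0.05)$bin_id), "unbinned")
  expect_error(cluster_contigs(few, 0, 0.05), "min_bin_size")
})

test_that("binning purity arithmetic matches hand counts", {
  assign <- data.frame(
    contig_id = paste0("c", 1:40),
    bin_id = rep("bin_001", 40), stringsAsFactors = FALSE
  )
  truth <- setNames(rep(c("gA", "gB"), c(30, 10)), assign$contig_id)
  pr <- binning_purity(assign, truth)
  expect_equal(pr$purity, 0.75)
  expect_equal(pr$top_genome, "gA")
  expect_equal(pr$recall, 1)
  expect_error(binning_purity(assign, truth[-1]), "cover")
})

test_that("zero-noise communities bin perfectly; binning is deterministic", {
  com <- simulate_community(5, 4, contigs_per_genome = 12, noise_sd = 0,
                            seed = 1)
  # the guarantee holds when planted profiles are separated by more than
  # the linkage threshold; check the hypothesis before the conclusion
  expect_gt(min_genome_separation(com), 0.05)
  a1 <- bin_contigs(com$coverage, min_bin_size = 5, linkage_dist = 0.05)
  a2 <- bin_contigs(com$coverage, min_bin_size = 5, linkage_dist = 0.05)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  truth <- setNames(com$contigs$genome_id, com$contigs$contig_id)
  pr <- binning_purity(a1, truth)
  expect_equal(nrow(pr), 5)
  expect_true(all(pr$purity == 1))
  expect_true(all(pr$recall == 1))
})

test_that("purity degrades monotonically (on average) with coverage noise", {
  mean_purity <- function(noise) {
    vals <- vapply(1:4, function(s) {
      com <- simulate_community(6, 3, contigs_per_genome = 10,
                                noise_sd = noise, seed = 100 + s)
      assign <- bin_contigs(com$coverage, min_bin_size = 3,
                            linkage_dist = 0.02)
      truth <- setNames(com$contigs$genome_id, com$contigs$contig_id)
      pr <- binning_purity(assign, truth)
      if (nrow(pr) == 0) return(0)
      mean(pr$purity)
    }, 0)
    mean(vals)
  }
  p <- vapply(c(0, 0.1, 0.8), mean_purity, 0)
  expect_true(all(diff(p) <= 0.05 + 1e-9))  # non-increasing trend
})
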