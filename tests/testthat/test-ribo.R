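ribo_tree <- function() {
  # patristic distances: r1-r2 = 0.02, r1-r3 = 0.06
  ape::read.tree(
    text = "((r1:0.01,r2:0.01):0.02,(r3:0.01,r4:0.01):0.02);")
}

test_that("read filter applies the strict edit-distance rule", {
  expect_true(read_filter(100, 0.90, 9))
  expect_false(read_filter(100, 0.90, 10))  # "less than 10 for 100 bp"
  expect_false(read_filter(100, 0.84, 0))
  expect_true(read_filter(100, 0.85, 0))    # aligned fraction is >=
  # monotone: tightening thresholds never admits a rejected read
  set.seed(1)
  rl <- rep(100L, 50)
  af <- runif(50)
  ed <- sample(0:30, 50, replace = TRUE)
  base <- read_filter(rl, af, ed, 0.85, 0.10)
  expect_true(all(read_filter(rl, af, ed, 0.90, 0.10) <= base))
  expect_true(all(read_filter(rl, af, ed, 0.85, 0.05) <= base))
})

test_that("patristic distance matches a path-sum oracle", {
  tr <- ribo_tree()
  expect_equal(patristic_distance(tr, "r1", "r1"), 0)
  expect_equal(patristic_distance(tr, "r1", "r2"), 0.02)
  expect_equal(patristic_distance(tr, "r1", "r3"), 0.06)
  cherry <- ape::read.tree(text = "(a:0.01,b:0.015);")
  expect_equal(patristic_distance(cherry, "a", "b"), 0.025)
  expect_error(patristic_distance(tr, "r1", "zz"), "unknown")

  set.seed(3)
  big <- random_tree(20)
  pairs <- t(replicate(15, sample(big$tip.label, 2)))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(patristic_distance(big, pairs[i, 1], pairs[i, 2]),
                 oracle_patristic(big, pairs[i, 1], pairs[i, 2]),
                 tolerance = 1e-10)
  }
})

test_that("pair concordance uses the mate-to-mate patristic radius", {
  tr <- ribo_tree()
  pairs <- data.frame(
    pair_id = rep(c("p1", "p2", "p3"), each = 2),
    read_index = rep(1:2, 3),
    ref_id = c("r1", "r1",   # same ref: distance 0
               "r1", "r2",   # 0.02 <= 0.03
               "r1", "r3"),  # 0.06 > 0.03
    read_len = 100L, aligned_frac = 0.95, edit_distance = 1L,
    stringsAsFactors = FALSE
  )
  conc <- pair_concordance(pairs, tr, radius = 0.03)
  expect_equal(conc, c(p1 = TRUE, p2 = TRUE, p3 = FALSE))

  ghost <- pairs
  ghost$ref_id[1] <- "missing_ref"
  expect_warning(conc2 <- pair_concordance(ghost, tr, 0.03), "absent")
  expect_false(conc2[["p1"]])
})

test_that("greedy clustering follows the most-pairs-first rule", {
  # r1: 5 pairs, r2: 3, r3: 1; d(r1,r2) = 0.02 <= radius, r3 farther
  tr <- ribo_tree()
  cl <- greedy_cluster(c(r1 = 5, r2 = 3, r3 = 1), tr, radius = 0.03)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$seed_ref, "r1")
  expect_equal(cl[[1]]$member_refs, c("r1", "r2"))
  expect_equal(cl[[1]]$n_pairs, 8L)
  expect_equal(cl[[2]]$member_refs, "r3")

  # all refs within radius of the top ref: a single cluster
  one <- greedy_cluster(c(r1 = 2, r2 = 1), tr, radius = 0.5)
  expect_length(one, 1)

  # radius 0: one cluster per reference
  split_all <- greedy_cluster(c(r1 = 2, r2 = 2, r3 = 1), tr, radius = 0)
  expect_length(split_all, 3)
  # ties broken by lexicographically smallest id
  expect_equal(split_all[[1]]$seed_ref, "r1")

  # cluster count is non-increasing in the radius
  counts <- c(r1 = 4, r2 = 2, r3 = 2, r4 = 1)
  n_clusters <- vapply(c(0, 0.02, 0.04, 0.1),
                       function(r) length(greedy_cluster(counts, tr, r)), 0L)
  expect_true(all(diff(n_clusters) <= 0))

  expect_error(greedy_cluster(c(zz = 1), tr), "absent")
})

test_that("planted well-separated sources are recovered exactly", {
  set.seed(9)
  for (k in c(2L, 3L, 5L)) {
    # k clades, pendant 0.005, inter-clade separation >> 2 * radius
    tips <- paste0("s", seq_len(k))
    nwk <- paste0("(", paste(sprintf("%s:0.5", tips), collapse = ","), ");")
    tr <- ape::read.tree(text = nwk)
    pairs <- do.call(rbind, lapply(seq_len(k), function(i) {
      p <- simulate_read_pairs(tr, tips[i], 10, placement_sd = 0,
                               seed = 100 + i)
      p$pair_id <- paste0(tips[i], "_", p$pair_id)
      p
    }))
    surv <- filter_pairs(pairs, tr)
    expect_equal(length(unique(surv$pair_id)), 10L * k)
    cl <- cluster_pairs(surv, tr, radius = 0.03)
    expect_length(cl, k)
    expect_setequal(vapply(cl, `[[`, "", "seed_ref"), tips)
    # partition: every surviving pair in exactly one cluster
    all_ids <- unlist(lapply(cl, `[[`, "pair_ids"))
    expect_equal(sort(all_ids), sort(unique(surv$pair_id)))
  }
})

test_that("cluster emission writes interleaved reads and a manifest", {
  tr <- ribo_tree()
  pairs <- rbind(
    simulate_read_pairs(tr, "r1", 8, seed = 1),
    within(simulate_read_pairs(tr, "r3", 1, seed = 2),
           pair_id <- paste0("b_", pair_id))
  )
  surv <- filter_pairs(pairs, tr)
  cl <- cluster_pairs(surv, tr, 0.03)
  reads <- metalineage:::synth_pair_reads(surv, seed = 1)
  dir <- withr::local_tempdir()
  manifest <- emit_clusters(cl, reads, dir)
  expect_equal(nrow(manifest), 2)
  expect_equal(sort(manifest$n_pairs, decreasing = TRUE), c(8, 1))
  fa <- read_fasta(file.path(dir, manifest$file[1]))
  expect_length(fa, 2 * manifest$n_pairs[1])

  # missing reads are an error naming the pair
  expect_error(emit_clusters(cl, reads[-1], withr::local_tempdir()),
               "missing reads")
  # a pair in two clusters violates the partition invariant
  dup <- cl
  dup[[2]]$pair_ids <- c(dup[[2]]$pair_ids, dup[[1]]$pair_ids[1])
  expect_error(emit_clusters(dup, reads, withr::local_tempdir()),
               "more than one cluster")
})

test_that("lineage abundance is the surviving-pair fraction", {
  cl <- structure(list(
    list(seed_ref = "r1", member_refs = "r1",
         pair_ids = sprintf("p%03d", 1:974)),
    list(seed_ref = "r3", member_refs = "r3",
         pair_ids = sprintf("q%03d", 1:26))
  ), class = "recruit_clusters")
  ab <- lineage_abundance(cl, c(r1 = "commonLineage", r3 = "targetLineage"))
  expect_equal(ab[["targetLineage"]], 0.026)
  expect_equal(sum(ab), 1)

  only <- lineage_abundance(cl[1], c(r1 = "commonLineage"))
  expect_equal(unname(only), 1)

  none <- structure(list(), class = "recruit_clusters")
  expect_warning(out <- lineage_abundance(none, c()), "no surviving")
  expect_length(out, 0)
})
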