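test_that("zero-noise coverage exactly reproduces planted abundances", {
  com <- simulate_community(1, 1, contigs_per_genome = 5, noise_sd = 0,
                            seed = 3)
  expected <- com$abundance[1, 1] * com$depth
  expect_equal(unname(com$coverage$values[, 1]), rep(expected, 5))

  com2 <- simulate_community(3, 4, contigs_per_genome = 6, noise_sd = 0,
                             seed = 9)
  for (g in com2$genomes$genome_id) {
    rows <- com2$coverage$values[com2$contigs$genome_id == g, , drop = FALSE]
    expect_equal(rows, matrix(rep(com2$abundance[g, ] * com2$depth,
                                  each = 6), 6,
                              dimnames = dimnames(rows)))
  }
})

test_that("noisy per-genome mean coverage stays near the planted abundance", {
  com <- simulate_community(2, 2, contigs_per_genome = 50, noise_sd = 0.05,
                            seed = 7)
  for (g in com$genomes$genome_id) {
    rows <- com$coverage$values[com$contigs$genome_id == g, , drop = FALSE]
    planted <- com$abundance[g, ] * com$depth
    # mean of log-coverage within 3 sd/sqrt(n) of the planted log-abundance
    expect_true(all(abs(colMeans(log(rows)) - log(planted)) <
                      3 * 0.05 / sqrt(50)))
  }
})

test_that("community generation is deterministic and validates arguments", {
  a <- simulate_community(3, 2, 10, 0.1, seed = 11)
  b <- simulate_community(3, 2, 10, 0.1, seed = 11)
  expect_identical(a, b)
  expect_error(simulate_community(0, 2), "n_genomes")
  expect_error(simulate_community(2, 0), "n_samples")
})

test_that("plant_markers honours the per-genome plan", {
  com <- simulate_community(2, 2, contigs_per_genome = 10, seed = 5)
  hits <- plant_markers(com, present = 105, duplicated = 0, seed = 1)
  for (g in com$genomes$genome_id) {
    counts <- table(hits$marker_id[
      hits$contig_id %in% com$contigs$contig_id[com$contigs$genome_id == g]
    ])
    expect_length(counts, 105)
    expect_true(all(counts == 1))
  }

  hits2 <- plant_markers(com, present = 103, duplicated = 6, seed = 2)
  g1 <- com$contigs$contig_id[com$contigs$genome_id == "g001"]
  counts <- table(hits2$marker_id[hits2$contig_id %in% g1])
  expect_equal(sum(counts == 1), 97)
  expect_equal(sum(counts == 2), 6)
  expect_equal(length(setdiff(default_marker_set(), names(counts))), 2)

  empty <- plant_markers(com, present = 0, seed = 3)
  expect_equal(nrow(empty), 0)
  expect_error(plant_markers(com, present = 5, duplicated = 6),
               "duplicated")
  expect_error(plant_markers(com, present = 200), "present")
})

test_that("congruent gene trees are monophyletic per clade; damage shows", {
  tax <- make_taxonomy(24, n_domains = 2, n_phyla = 4, n_classes = 8)
  gt <- simulate_gene_tree(tax, congruence = 1, seed = 1)
  expect_setequal(gt$tip.label, tax$genome_id)
  for (p in unique(tax$phylum)) {
    expect_true(is_monophyletic(gt, tax$genome_id[tax$phylum == p]))
  }
  # determinism at partial congruence
  a <- simulate_gene_tree(tax, 0.5, seed = 4)
  b <- simulate_gene_tree(tax, 0.5, seed = 4)
  expect_equal(ape::write.tree(a), ape::write.tree(b))
  # swapping two leaves across phyla breaks monophyly of both
  swapped <- gt
  a <- tax$genome_id[tax$phylum == "p01"][1]
  b <- tax$genome_id[tax$phylum == "p02"][1]
  swapped$tip.label[match(c(a, b), gt$tip.label)] <- c(b, a)
  expect_false(is_monophyletic(swapped, tax$genome_id[tax$phylum == "p01"]))
  expect_false(is_monophyletic(swapped, tax$genome_id[tax$phylum == "p02"]))
})

test_that("alignment evolution matches the symmetric-model closed form", {
  # zero branch lengths: identical sequences
  t0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  a0 <- evolve_alignment(t0, 200, seed = 1)
  expect_true(all(a0$seqs[1, ] == a0$seqs[2, ]))
  expect_true(all(a0$seqs[1, ] == a0$seqs[3, ]))

  # two leaves at total path 0.1: mismatch ~ (3/4)(1 - exp(-4*0.1/3))
  t2 <- ape::read.tree(text = "(a:0.04,b:0.06);")
  al <- evolve_alignment(t2, 100000, seed = 2)
  p_hat <- mean(al$seqs[1, ] != al$seqs[2, ])
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.1 / 3))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 100000))

  expect_identical(evolve_alignment(t2, 100, seed = 9)$seqs,
                   evolve_alignment(t2, 100, seed = 9)$seqs)
  t_nolen <- ape::read.tree(text = "(a,b,c);")
  expect_error(evolve_alignment(t_nolen, 10), "branch lengths")
})

test_that("read-pair simulation respects placement and ranges", {
  tree <- ape::read.tree(text = "((r1:0.01,r2:0.01):0.05,(r3:0.01,r4:0.01):0.05);")
  pairs <- simulate_read_pairs(tree, "r1", 20, placement_sd = 0, seed = 1)
  expect_equal(nrow(pairs), 40)
  expect_true(all(pairs$ref_id == "r1"))

  degen <- simulate_read_pairs(tree, "r2", 10,
                               aligned_frac_range = c(0.95, 0.95),
                               edit_ratio_range = c(0.02, 0.02), seed = 2)
  expect_true(all(read_filter(degen$read_len, degen$aligned_frac,
                              degen$edit_distance)))

  expect_equal(nrow(simulate_read_pairs(tree, "r1", 0)), 0)
  expect_error(simulate_read_pairs(tree, "nope", 5), "not in")
})
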