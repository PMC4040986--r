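test_that("masking drops over-gapped and uninformative columns only", {
  m <- rbind(
    g1 = c("A", "A", "-", "A", "-"),
    g2 = c("C", "-", "-", "C", "N"),
    g3 = c("G", "-", "-", "G", "N"),
    g4 = c("T", "-", "T", "T", "N")
  )
  masked <- mask_alignment(m, max_gap_fraction = 0.5)
  # col2 gapped in 3/4 (> 0.5) dropped; col3 gapped in 3/4 dropped;
  # col5 has only ambiguity codes among non-gaps -> dropped;
  # col4 ungapped kept; col1 kept
  expect_equal(ncol(masked), 2)
  expect_equal(attr(masked, "kept"), c(0L, 3L))

  # exactly half gapped is retained ("more than half" is strict)
  half <- rbind(g1 = c("A", "-"), g2 = c("C", "-"),
                g3 = c("G", "G"), g4 = c("T", "T"))
  expect_equal(ncol(mask_alignment(half, 0.5)), 2)

  ungapped <- matrix("A", 3, 4, dimnames = list(paste0("g", 1:3), NULL))
  expect_identical(dim(mask_alignment(ungapped)), c(3L, 4L))

  allgap <- matrix("-", 3, 2, dimnames = list(paste0("g", 1:3), NULL))
  expect_warning(out <- mask_alignment(allgap), "every column")
  expect_equal(ncol(out), 0)
})

test_that("concatenation pads missing genomes and records coordinates", {
  b1 <- matrix("A", 2, 10, dimnames = list(c("g1", "g2"), NULL))
  b2 <- matrix("C", 2, 20, dimnames = list(c("g1", "g3"), NULL))
  sm <- concatenate(list(m1 = b1, m2 = b2), c("g1", "g2", "g3"))
  expect_equal(ncol(sm$seqs), 30)
  expect_equal(sm$map$start, c(0, 10))
  expect_equal(sm$map$end, c(10, 30))
  expect_true(all(sm$seqs["g2", 11:30] == "-"))
  expect_true(all(sm$seqs["g3", 1:10] == "-"))

  expect_error(concatenate(list()), "no blocks")
  expect_error(concatenate(list(m1 = b1, m1 = b1)), "uniquely named")
})

test_that("LogDet distance has the stated closed-form properties", {
  # identical sequences with uniform base composition: distance 0
  s <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  expect_equal(logdet_distance(s, s), 0)

  # consistent under the symmetric model at d = 0.1
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  ests <- vapply(1:10, function(i) {
    al <- evolve_alignment(tr, 20000, seed = i)
    logdet_distance(paste(al$seqs[1, ], collapse = ""),
                    paste(al$seqs[2, ], collapse = ""))
  }, 0)
  expect_lt(abs(mean(ests) - 0.1), 0.01)

  # matches the established paralinear implementation on simulated pairs
  al <- evolve_alignment(tr, 5000, seed = 99)
  d_ref <- ape::dist.dna(ape::as.DNAbin(al$seqs), model = "paralin")
  expect_equal(logdet_distance(paste(al$seqs[1, ], collapse = ""),
                               paste(al$seqs[2, ], collapse = "")),
               as.numeric(d_ref), tolerance = 1e-8)

  # a sequence missing a base entirely saturates
  x <- paste(rep("A", 100), collapse = "")
  y <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  expect_true(is.na(suppressWarnings(logdet_distance(x, y))))
  expect_true(attr(logdet_distance(x, y), "saturated"))

  expect_error(logdet_distance("----", "ACGT"), "no shared")
  expect_error(logdet_distance("ACG", "ACGT"), "equal length")
})

test_that("neighbor joining recovers additive trees exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_equal(ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]], D)

  # 100 random 6-10 leaf trees: topology and path lengths recovered
  set.seed(7)
  for (i in 1:100) {
    gen <- ape::unroot(random_tree(sample(6:10, 1)))
    D_add <- ape::cophenetic.phylo(gen)
    rec <- neighbor_joining(D_add)
    expect_equal(ape::dist.topo(gen, rec), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(
      ape::cophenetic.phylo(rec)[rownames(D_add), colnames(D_add)],
      D_add, tolerance = 1e-8
    )
  }

  asym <- D
  asym[1, 2] <- 99
  expect_error(neighbor_joining(asym), "symmetric")
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("negative NJ branch lengths are clamped to zero", {
  # a near-degenerate matrix that drives an internal branch negative
  D <- matrix(c(0, 2, 2.1, 2.1,
                2, 0, 2.1, 2.1,
                2.1, 2.1, 0, 0.1,
                2.1, 2.1, 0.1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support saturates on a well-resolved fixture", {
  tax <- make_taxonomy(8, 1, 2, 4)
  species <- metalineage:::congruent_tree(tax, 0.1)
  aln <- evolve_alignment(species, 10000, seed = 5)
  sm <- concatenate(list(concat = mask_alignment(aln)),
                    genome_universe = tax$genome_id)
  bs <- bootstrap_support(sm, n_replicates = 30, seed = 5)
  internal <- bs$support[bs$support$size >= 2, ]
  expect_true(all(internal$support >= 90))
  expect_equal(bs$n_skipped, 0)

  # determinism under a fixed seed
  bs2 <- bootstrap_support(sm, n_replicates = 30, seed = 5)
  expect_identical(bs$support, bs2$support)

  # a single replicate yields supports in {0, 100}
  bs1 <- bootstrap_support(sm, n_replicates = 1, seed = 2)
  expect_true(all(bs1$support$support %in% c(0L, 100L)))
})

test_that("monophyly is exact bipartition membership", {
  tr <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,(d:1,e:1):1);")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("d", "e")))
  expect_false(is_monophyletic(tr, c("a", "d")))
  expect_true(is_monophyletic(tr, c("a", "b", "c", "d")))  # leaves minus e
  expect_true(is_monophyletic(tr, "c"))
  expect_error(is_monophyletic(tr, character()), "non-empty")
  expect_error(is_monophyletic(tr, "zz"), "absent")
})

test_that("protein blocks fall back to the mismatch distance", {
  m <- rbind(p1 = strsplit("MKLVITWWMKLVITWW", "")[[1]],
             p2 = strsplit("MKLVITWWMKLVTTWW", "")[[1]],
             p3 = strsplit("MKLV-TWWMKLVITWW", "")[[1]])
  d <- distance_matrix(m, method = "mismatch")
  expect_equal(d["p1", "p2"], 1 / 16)
  expect_equal(d["p1", "p3"], 0)  # gap column excluded
  expect_equal(d, t(d))
})

test_that("mask -> concat -> distance -> NJ round-trips through files", {
  tax <- make_taxonomy(6, 1, 2, 3)
  species <- metalineage:::congruent_tree(tax, 0.1)
  aln <- evolve_alignment(species, 600, seed = 8)
  sm <- concatenate(list(b = mask_alignment(aln)))
  dir <- withr::local_tempdir()
  aln_path <- file.path(dir, "sm.fasta")
  write_alignment(sm, aln_path)
  expect_true(file.exists(paste0(aln_path, ".map.json")))
  back <- read_alignment(aln_path)
  expect_equal(back[rownames(sm$seqs), ], sm$seqs)

  d <- distance_matrix(sm)
  d_path <- file.path(dir, "d.tsv")
  write_distance(d, d_path)
  expect_equal(read_distance(d_path), d, tolerance = 1e-12)

  tr <- neighbor_joining(d)
  tr_path <- file.path(dir, "t.nwk")
  write_newick(tr, tr_path)
  expect_equal(sort(read_newick(tr_path)$tip.label), sort(tr$tip.label))
})
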