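test_that("sampled trees have the right combinatorics and are reproducible", {
  t4 <- sample_tree(4, seed = 1)
  expect_equal(nrow(t4$edge), 5)                      # 2n-3
  expect_equal(length(tree_bipartitions(t4)), 1)      # one internal edge
  t8 <- sample_tree(8, seed = 2)
  expect_equal(nrow(t8$edge), 13)
  expect_identical(write_newick(sample_tree(8, seed = 9)),
                   write_newick(sample_tree(8, seed = 9)))
  expect_false(identical(write_newick(sample_tree(8, seed = 9)),
                         write_newick(sample_tree(8, seed = 10))))
  expect_true(all(sample_tree(10, seed = 3)$edge.length >= 0))
})

test_that("zero coordinate noise gives identical structures up to rigid moves", {
  tr <- sample_tree(5, seed = 4)
  st <- evolve_structures(tr, helix_fold(50), coord_sigma = 0, seed = 5)
  dm <- all_vs_all_matrix(st, align_params())
  expect_lt(max(dm), 1e-6)
})

test_that("Brownian displacement matches its closed-form expectation", {
  # two taxa joined through the root: path length = depth_i + depth_j;
  # compare the empirical per-atom squared deviation against 3 sigma^2 T w
  n <- 40
  base <- helix_fold(n)
  loops <- segment_set(17, 21)
  sigma <- 0.5
  tr <- read_newick("(L1:0.4,L2:0.6,L3:0.2);")
  acc_loop <- acc_rest <- 0
  reps <- 200
  for (r in 1:reps) {
    st <- evolve_structures(tr, base, coord_sigma = sigma, seed = 9000 + r,
                            loop_segments = loops, loop_factor = 4,
                            rigid = FALSE)
    d2 <- rowSums((ca_coords(st[["L1"]]) - ca_coords(st[["L2"]]))^2)
    inloop <- in_segments(loops, 1:n)
    acc_loop <- acc_loop + mean(d2[inloop])
    acc_rest <- acc_rest + mean(d2[!inloop])
  }
  Tpath <- 1.0
  expect_equal(acc_rest / reps, 3 * sigma^2 * Tpath, tolerance = 0.1)
  expect_equal(acc_loop / reps, 3 * sigma^2 * Tpath * 4, tolerance = 0.1)
})

test_that("loop regions diverge more than the rest of the chain", {
  tr <- sample_tree(6, seed = 6)
  st <- evolve_structures(tr, helix_fold(100), coord_sigma = 0.5, seed = 7,
                          loop_segments = segment_set(41, 52), rigid = FALSE)
  d2 <- rowSums((ca_coords(st[[1]]) - ca_coords(st[[2]]))^2)
  inloop <- in_segments(segment_set(41, 52), 1:100)
  expect_gt(mean(sqrt(d2[inloop])), mean(sqrt(d2[!inloop])))
})

test_that("sequence evolution is seeded, rate-0-stable and matches theory", {
  tr <- sample_tree(5, seed = 8)
  root <- paste(rep("ACDEFGHIKL", 25), collapse = "")
  s0 <- evolve_sequences(tr, root, sub_rate = 0, seed = 9)
  expect_true(all(s0 == root))
  s1 <- evolve_sequences(tr, root, sub_rate = 0.3, seed = 10)
  s2 <- evolve_sequences(tr, root, sub_rate = 0.3, seed = 10)
  expect_identical(s1, s2)

  # expected p-distance between two leaves: the 20-state jump chain gives
  # P(diff) = (19/20) (1 - prod_e (20 exp(-r t_e) - 1)/19) over path edges
  tr2 <- read_newick("(L1:0.5,L2:0.7,L3:0.1);")
  rate <- 0.4
  edges <- c(0.5, 0.7)
  expv <- (19 / 20) * (1 - prod((20 * exp(-rate * edges) - 1) / 19))
  L <- 250
  acc <- 0; reps <- 100
  for (r in 1:reps) {
    ss <- evolve_sequences(tr2, paste(rep("A", L), collapse = ""),
                           sub_rate = rate, seed = 4000 + r)
    acc <- acc + mean(strsplit(ss[["L1"]], "")[[1]] != strsplit(ss[["L2"]], "")[[1]])
  }
  expect_equal(acc / reps, expv, tolerance = 0.05)
})

test_that("emitted families round-trip through their files", {
  fam <- sim_family(sim_params(n_taxa = 6, chain_length = 40, seed = 11))
  td <- withr::local_tempdir()
  emit_family(fam, td)
  files <- list.files(td)
  expect_equal(sum(grepl("\\.pdb$", files)), 6)
  expect_true(all(c("sequences.fasta", "true_tree.nwk", "hosts.tsv") %in% files))

  # coordinates round-trip at PDB precision, sequences and tree exactly
  for (lab in names(fam$structures)) {
    s <- read_ca_structure(file.path(td, paste0(lab, ".pdb")))
    expect_lt(max(abs(ca_coords(s) - ca_coords(fam$structures[[lab]]))), 1e-3)
    expect_identical(ca_sequence(s), ca_sequence(fam$structures[[lab]]))
  }
  expect_equal(fasta_as_vector(read_fasta(file.path(td, "sequences.fasta"))),
               fam$sequences)
  tr <- read_newick(path = file.path(td, "true_tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(fam$true_tree$tip.label))
  expect_equal(rf_distance(tr, fam$true_tree), 0)
  expect_equal(read_host_map(file.path(td, "hosts.tsv")), fam$hosts)
})

test_that("terminal indels shorten both sequence and structure coherently", {
  fam <- sim_family(sim_params(n_taxa = 6, chain_length = 60,
                               terminal_indel_max = 8, seed = 12))
  lens_s <- vapply(fam$structures, length, 1L)
  lens_q <- nchar(fam$sequences[names(fam$structures)])
  expect_equal(unname(lens_s), unname(lens_q))
  expect_true(any(lens_s < 60))
  expect_true(all(lens_s >= 52))
})

test_that("hosts derived from true clades are monophyletic on the true tree", {
  fam <- sim_family(sim_params(n_taxa = 8, chain_length = 40, seed = 13))
  rep <- host_monophyly(fam$true_tree, fam$hosts)
  expect_true(all(rep$monophyletic))
  expect_true(all(rep$purity == 1))
})

test_that("doubling coordinate noise roughly doubles structural distances", {
  tr <- sample_tree(5, seed = 14)
  st1 <- evolve_structures(tr, helix_fold(80), coord_sigma = 0.3, seed = 15)
  st2 <- evolve_structures(tr, helix_fold(80), coord_sigma = 0.6, seed = 15)
  d1 <- all_vs_all_matrix(st1, align_params(core_cutoff = Inf))
  d2 <- all_vs_all_matrix(st2, align_params(core_cutoff = Inf))
  ratio <- d2[upper.tri(d2)] / d1[upper.tri(d1)]
  expect_equal(mean(ratio), 2, tolerance = 0.15)
})
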