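test_that("segment specs parse, normalize and render idempotently", {
  s <- parse_segment_spec("34-275,332-609,625-894")
  expect_equal(nrow(s), 3)
  expect_equal(segment_count(s), 790)
  expect_identical(parse_segment_spec(render_segments(s)), s)

  expect_equal(render_segments(parse_segment_spec("10-20,15-30")), "10-30")
  expect_equal(segment_count(parse_segment_spec("5-5")), 1)
  expect_error(parse_segment_spec("20-10"), "start")
  expect_error(parse_segment_spec("a-b"), "parse")
})

test_that("segment subtraction follows interval algebra", {
  a <- parse_segment_spec("34-275")
  expect_equal(render_segments(subtract_segments(a, parse_segment_spec("239-243"))),
               "34-238,244-275")
  expect_equal(nrow(subtract_segments(a, a)), 0)
  expect_identical(subtract_segments(parse_segment_spec("1-10"),
                                     parse_segment_spec("20-30")),
                   parse_segment_spec("1-10"))
})

test_that("modeled-residue accounting matches the capsid bookkeeping", {
  modeled <- parse_segment_spec("34-275,332-609,625-894")
  expect_equal(count_modeled_residues(modeled, parse_segment_spec("239-243")), 785)
  expect_equal(count_modeled_residues(modeled,
               parse_segment_spec("239-243,34-87,625-637")), 718)
  expect_equal(count_modeled_residues(segment_set(), modeled), 0)

  rep <- account_modeled(c("full", "empty"), list(modeled, modeled),
                         list(parse_segment_spec("239-243"),
                              parse_segment_spec("239-243,34-87,625-637")))
  expect_equal(rep$net, c(785, 718))
})

test_that("counting is consistent with brute-force integer enumeration", {
  set.seed(7)
  for (k in 1:25) {
    mk <- function() {
      st <- sort(sample(1:60, 3))
      segment_set(st, st + sample(0:8, 3, replace = TRUE))
    }
    a <- mk(); b <- mk()
    ints <- function(s) if (nrow(s) == 0) integer(0) else
      unlist(Map(seq, s$start, s$end))
    expect_equal(count_modeled_residues(a, b), length(setdiff(ints(a), ints(b))))
    expect_equal(count_modeled_residues(a, b) + segment_count(intersect_segments(a, b)),
                 segment_count(a))
  }
})

test_that("motif location finds all overlapping occurrences in order", {
  expect_equal(motif_locate("ADDF", "DDF"), data.frame(start = 2L, end = 4L))
  expect_equal(motif_locate("AAAA", "AA"),
               data.frame(start = 1:3, end = 2:4))
  expect_equal(nrow(motif_locate("MKV", "DDF")), 0)
  expect_error(motif_locate("MKV", ""), "non-empty")
  # brute-force sliding scan cross-check on random strings
  set.seed(3)
  for (k in 1:10) {
    s <- paste(sample(c("A", "D", "F"), 30, TRUE), collapse = "")
    hits <- motif_locate(s, "AD")
    brute <- which(vapply(1:29, function(i) substr(s, i, i + 1) == "AD", TRUE))
    expect_equal(hits$start, as.integer(brute))
  }
})

test_that("PDB CA extraction honors altloc, missing-CA and ordering contracts", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom(1, "CA", "ALA", 1, 1, 0, 0),
    pdb_atom(2, "CA", "GLY", 2, 2, 0, 0),
    pdb_atom(3, "CA", "SER", 3, 3, 0, 0), "END"), f)
  st <- read_ca_structure(f)
  expect_equal(length(st), 3)
  expect_equal(st$residues$aa, c("A", "G", "S"))

  # altloc: highest occupancy wins; missing-CA residue absent
  writeLines(c(
    pdb_atom(1, "CA", "ALA", 1, 1, 0, 0),
    pdb_atom(2, "CA", "GLY", 2, 2, 0, 0, alt = "A", occ = 0.6),
    pdb_atom(3, "CA", "GLY", 2, 9, 0, 0, alt = "B", occ = 0.4),
    pdb_atom(4, "N",  "SER", 3, 3, 1, 0),
    pdb_atom(5, "CA", "SER", 4, 4, 0, 0), "END"), f)
  st <- suppressWarnings(read_ca_structure(f))
  expect_equal(st$residues$seq_id, c(1L, 2L, 4L))
  expect_equal(st$residues$x[2], 2)  # altloc A kept
  # tie in occupancy -> lexicographically smallest altloc id
  writeLines(c(
    pdb_atom(1, "CA", "ALA", 1, 1, 0, 0),
    pdb_atom(2, "CA", "GLY", 2, 9, 0, 0, alt = "B", occ = 0.5),
    pdb_atom(3, "CA", "GLY", 2, 2, 0, 0, alt = "A", occ = 0.5),
    pdb_atom(4, "CA", "SER", 3, 3, 0, 0), "END"), f)
  st <- suppressWarnings(read_ca_structure(f))
  expect_equal(st$residues$x[2], 2)

  # permuted input comes back strictly ordered
  writeLines(c(
    pdb_atom(1, "CA", "SER", 5, 5, 0, 0),
    pdb_atom(2, "CA", "ALA", 1, 1, 0, 0),
    pdb_atom(3, "CA", "GLY", 3, 3, 0, 0), "END"), f)
  st <- read_ca_structure(f)
  expect_equal(st$residues$seq_id, c(1L, 3L, 5L))

  # unparseable record reports its line number
  writeLines(c(pdb_atom(1, "CA", "ALA", 1, 1, 0, 0),
               "ATOM      2  CA  GLY A  XX       2.0     0.0"), f)
  expect_error(read_ca_structure(f), "line 2")
})

test_that("predicted-model flag controls confidence reading", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom(1, "CA", "ALA", 1, 1, 0, 0, b = 92.5),
               pdb_atom(2, "CA", "GLY", 2, 2, 0, 0, b = 45.1), "END"), f)
  expect_true(all(is.na(read_ca_structure(f)$residues$confidence)))
  st <- read_ca_structure(f, predicted = TRUE)
  expect_equal(st$residues$confidence, c(92.5, 45.1))
})

test_that("FASTA IO round-trips with normalization", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV"), f)
  r <- read_fasta(f)
  expect_equal(r[["a"]]$seq, "MKV")

  recs <- c(a = "MKVLW", b = strrep("ACDEFGHIKL", 13), c = "WYX")
  write_fasta(recs, f)
  expect_equal(fasta_as_vector(read_fasta(f)), recs)
  # wrapped at 60 columns
  expect_true(max(nchar(readLines(f))) <= 60)

  writeLines(c(">lc", "mkv*"), f)
  expect_equal(read_fasta(f)[["lc"]]$seq, "MKV")
  writeLines(c(">a", "MKV", ">a", "MKW"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|read")
})
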