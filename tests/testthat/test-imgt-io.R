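test_that("identity dashes expand against the reference", {
  aln <- parse_alignment(tiny_prot_text(), "prot")
  expect_equal(aln$locus, "A")
  expect_equal(aln$version, "3.59.0")
  expect_equal(aln$reference, "A*01:01")
  expect_equal(ncol(aln$seqs), 10L)
  expect_equal(paste(aln$seqs["A*01:01", ], collapse = ""), "MAVMAPRTLL")
  # variant row: S at position 2, W at the last, reference elsewhere
  expect_equal(paste(aln$seqs["A*02:01", ], collapse = ""), "MSVMAPRTLW")
  expect_false(any(aln$seqs == "-"))
})

test_that("boundary markers become ordered boundary records", {
  aln <- parse_alignment(tiny_gen_text(), "gen")
  expect_equal(aln$boundaries$col, c(3L, 9L))
  expect_equal(aln$boundaries$left, c("U.5", "E.1"))
  expect_equal(aln$boundaries$right, c("E.1", "U.3"))
  expect_true(!is.unsorted(aln$boundaries$col, strictly = TRUE))
  # gDNA numbering skips zero
  expect_equal(aln$positions[1:4], c("-3", "-2", "-1", "1"))
})

test_that("insertion columns get fractional labels", {
  aln <- parse_alignment(tiny_insertion_text(), "prot")
  expect_equal(aln$positions, c("1", "2", "2.1", "3", "4"))
  expect_equal(unname(aln$seqs["A*02:01", 3L]), "W")
  expect_equal(unname(aln$seqs["A*01:01", 3L]), ".")
})

test_that("parse errors name the offending block or allele", {
  bad_label <- sub(" Prot 6", " Prot x6", tiny_prot_text())
  expect_error(parse_alignment(bad_label, "prot"), "block 2")
  dup <- paste(tiny_prot_text(), "", " Prot 1", " A*01:01 MAVMA",
               " A*01:01 -----", sep = "\n")
  expect_error(parse_alignment(dup, "prot"), "duplicate allele")
  wide <- sub("-S---", "-S----", tiny_prot_text())
  expect_error(parse_alignment(wide, "prot"), "A\\*02:01")
})

test_that("late-entering and early-terminating alleles are star-padded", {
  fx <- make_alignment_fixture(21, n_alleles = 6, n_late = 2, n_early = 2)
  aln <- parse_alignment(fx$text, "prot")
  expect_identical(aln, fx$truth)
  alleles <- alignment_alleles(aln)
  late <- alleles[2L]
  lead <- aln$seqs[late, seq_len(which(aln$seqs[late, ] != "*")[1L] - 1L)]
  expect_true(all(lead == "*"))
  expect_false(any(aln$seqs == "-"))
})

test_that("round-trip through the dialect is exact for all alignment types", {
  for (seed in 1:10) {
    for (tp in c("prot", "nuc", "gen")) {
      fx <- make_alignment_fixture(seed, align_type = tp, n_alleles = 5,
                                   block_width = 50 + 7 * seed)
      expect_identical(parse_alignment(fx$text, tp), fx$truth,
                       label = paste("seed", seed, tp))
    }
  }
})

test_that("expansion equals an independent per-character expansion", {
  # single-block text whose expansion can be done by hand, char by char
  set.seed(99)
  ref <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
               collapse = "")
  coded <- paste(ifelse(runif(40) < 0.3,
                        sample(c("A", "C", "G", "T", ".", "*"), 40,
                               replace = TRUE), "-"),
                 collapse = "")
  txt <- paste(c("HLA-B Nucleotide Sequence Alignments",
                 "IPD-IMGT/HLA Release: 3.59.0", "",
                 " cDNA 1",
                 paste(" B*07:02", ref),
                 paste(" B*08:01", coded)), collapse = "\n")
  aln <- parse_alignment(txt, "nuc")
  expect_equal(paste(aln$seqs["B*08:01", ], collapse = ""),
               expand_by_hand(ref, coded))
})

test_that("codon tables derive from nuc tables in frame", {
  fx <- make_alignment_fixture(31, align_type = "nuc", n_insertions = 0,
                               feature_lengths = c(E.1 = 6L, E.2 = 9L))
  cod <- derive_codon_table(fx$truth)
  expect_equal(cod$align_type, "codon")
  expect_equal(cod$positions, as.character(1:5))   # 15 nt = 5 codons
  expect_equal(nchar(cod$seqs[1L, ]), rep(3L, 5L))
  expect_equal(paste(cod$seqs[1L, ], collapse = ""),
               paste(fx$truth$seqs[1L, ], collapse = ""))
  # E.1|E.2 boundary after nt 6 lies in codon column 2
  expect_equal(cod$boundaries$col, 2L)
})

test_that("allele history parses, round-trips and encodes absences", {
  fx <- make_history_fixture(5)
  h <- parse_allele_history(fx$text)
  expect_identical(h, fx$truth)
  expect_identical(parse_allele_history(write_allele_history(h)), h)

  del <- fx$events[fx$events$event == "deletion", ][1L, ]
  i <- match(del$accession, h$table$accession)
  expect_true(is.na(h$table[[h$versions[1L]]][i]))
  expect_false(is.na(h$table[[h$versions[length(h$versions)]]][i]))
})

test_that("history header errors are specific", {
  expect_error(parse_allele_history("foo,3590\nx,y"), "accession column")
  expect_error(parse_allele_history("HLA_ID,35x90\nHLA00001,A*01:01"),
               "release column header")
})

test_that("release strings map to branches and back", {
  expect_equal(release_to_branch("3.59.0"), "3590")
  expect_equal(release_to_branch("Latest"), "Latest")
  expect_equal(branch_to_release("3590"), "3.59.0")
  expect_equal(branch_to_release("1000"), "1.00.0")
  expect_error(release_to_branch("v3.59"), "unrecognised")
})

test_that("inventory lists alignment types with implied codon", {
  d <- withr::local_tempdir()
  writeLines("", file.path(d, "A_prot.txt"))
  writeLines("", file.path(d, "A_nuc.txt"))
  writeLines("", file.path(d, "N_gen.txt"))
  inv <- list_alignment_inventory(d)
  expect_equal(inv$A, c("prot", "nuc", "codon"))
  expect_equal(inv$N, "gen")   # gene fragment: no nuc, no codon
  expect_error(list_alignment_inventory(file.path(d, "nope")),
               "does not exist")
})

test_that("offline fetch without cache fails with fixture-mode guidance", {
  d <- withr::local_tempdir()
  old <- options(timeout = 5)
  withr::defer(options(old))
  expect_error(fetch_release_file("9.99.9", "alignments/ZZ_prot.txt",
                                  cache_dir = d),
               "fixture")
  # a cached file is served without any network access
  dir.create(file.path(d, "3590", "alignments"), recursive = TRUE)
  writeLines("cached text", file.path(d, "3590", "alignments", "X.txt"))
  expect_equal(fetch_release_file("3.59.0", "alignments/X.txt",
                                  cache_dir = d), "cached text")
})
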