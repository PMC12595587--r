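test_that("atlas boundaries carry flanking labels and nuc codons", {
  fx <- make_alignment_fixture(4, locus = "G", align_type = "nuc",
                               feature_lengths = c(E.1 = 6L, E.2 = 9L,
                                                   E.3 = 12L),
                               n_insertions = 0L)
  at <- build_atlas(list(nuc = fx$truth))
  e <- at$entries$nuc
  expect_equal(e$left, c("E.1", "E.2"))
  expect_equal(e$right, c("E.2", "E.3"))
  expect_equal(e$before, c("6", "15"))
  expect_equal(e$after, c("7", "16"))
  # Exon 1 of 6 nt ends in codon ceil(6/3) = 2 (no leader known)
  expect_equal(e$codon, c(2L, 5L))
})

test_that("codon numbering subtracts the leader when a prot table is given", {
  nuc <- make_alignment_fixture(4, locus = "G", align_type = "nuc",
                                feature_lengths = c(E.1 = 6L, E.2 = 9L),
                                n_insertions = 0L)$truth
  prot <- make_alignment_fixture(5, locus = "G", align_type = "prot",
                                 n_positions = 10L, n_insertions = 0L)$truth
  # prot fixture has a 4-residue leader (positions -4..-1)
  at <- build_atlas(list(prot = prot, nuc = nuc))
  expect_equal(at$entries$nuc$codon, 2L - 4L)
})

test_that("degenerate edge boundaries are rejected", {
  fx <- make_alignment_fixture(6, align_type = "gen", n_insertions = 0L)
  broken <- fx$truth
  broken$boundaries$col[1L] <- 0L
  expect_error(build_atlas(list(gen = broken)), "degenerate")
})

test_that("atlas entries serialize to JSON and back", {
  fx <- make_alignment_fixture(7, align_type = "gen")
  at <- build_atlas(list(gen = fx$truth))
  path <- withr::local_tempfile(fileext = ".json")
  atlas_to_json(at, path)
  back <- atlas_from_json(path)
  expect_equal(back$locus, at$locus)
  expect_equal(back$entries$gen$left, at$entries$gen$left)
  expect_equal(back$entries$gen$before, at$entries$gen$before)
})

test_that("gene-body length counts non-indel symbols between the UTRs", {
  fx <- make_alignment_fixture(5, locus = "C", align_type = "gen",
                               feature_lengths = c(U.5 = 10L, E.1 = 10L,
                                                   I.1 = 5L, E.2 = 10L,
                                                   U.3 = 8L),
                               n_insertions = 0L, variant_density = 0)
  gen <- fx$truth
  expect_equal(gene_body_length(gen, gen$reference), 25L)
  # an allele with 3 intron deletions is 3 nt shorter
  mut <- gen
  b <- gen$boundaries
  intron_cols <- (b$col[2L] + 1L):b$col[3L]
  mut$seqs[2L, intron_cols[1:3]] <- "."
  expect_equal(gene_body_length(mut, rownames(mut$seqs)[2L]),
               gene_body_length(gen, gen$reference) - 3L)
  expect_error(gene_body_length(gen, "C*99:99"), "not in")
  noutr <- gen
  noutr$boundaries <- noutr$boundaries[2:3, ]
  expect_error(gene_body_length(noutr, gen$reference), "UTR")
})

test_that("feature lengths between boundaries conserve the ungapped length", {
  for (seed in 1:5) {
    fx <- make_alignment_fixture(seed, align_type = "gen")
    gen <- fx$truth
    cuts <- c(0L, gen$boundaries$col, ncol(gen$seqs))
    for (a in alignment_alleles(gen)) {
      by_feature <- vapply(seq_len(length(cuts) - 1L), function(k) {
        sum(gen$seqs[a, (cuts[k] + 1L):cuts[k + 1L]] != ".")
      }, integer(1))
      expect_equal(sum(by_feature), sum(gen$seqs[a, ] != "."))
    }
  }
})

test_that("the gazetteer populates its fixed 19-category roster", {
  expect_length(gazetteer_categories(), 19L)
  inv <- list(A = c("prot", "nuc", "codon", "gen"), N = "gen",
              DRB1 = c("prot", "nuc", "codon"), MICA = c("prot", "nuc",
                                                         "codon", "gen"))
  g <- build_gazetteer(inv, version = "3.61.0")
  expect_equal(g$prot, c("A", "DRB1", "MICA"))
  expect_equal(g$gen, c("A", "MICA", "N"))
  expect_true("N" %in% g$gene_fragment)
  expect_equal(g$classI, c("A", "MICA", "N"))
  expect_equal(g$classI_hla, c("A", "N"))
  expect_equal(g$nonhla_loci, "MICA")
  expect_equal(g$version, "3.61.0")
  # subset chain and status partition
  expect_true(all(g$prot %in% g$nuc) || all(g$prot %in% g$align))
  expect_true(all(g$align %in% c(g$expressed, g$pseudogene,
                                 g$gene_fragment)))
  expect_error(build_gazetteer(list(ZZ9 = "gen")), "ZZ9")
})

test_that("the chromosomal map merges the ambiguous DRB clusters", {
  g <- build_gazetteer(list(A = "prot"), version = "x")
  expect_true("DRB3/4/5" %in% g$map)
  expect_true("DRB6/7" %in% g$map)
  expect_false(any(c("DRB3", "DRB4", "DRB5", "DRB6", "DRB7") %in% g$map))
  # HLA-R sits on the same insertion variant as HLA-Y
  expect_equal(abs(which(g$map == "R") - which(g$map == "Y")), 1L)
  expect_false(anyDuplicated(g$map) > 0L)
})
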