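test_that("motif specifiers parse both tilde variants and render ASCII", {
  m <- parse_motif("DRB1*25R∼38V~48R~127I")
  expect_equal(m$locus, "DRB1")
  expect_equal(m$positions, c("25", "38", "48", "127"))
  expect_equal(m$residues, c("R", "V", "R", "I"))
  expect_equal(render_motif(m), "DRB1*25R~38V~48R~127I")
  expect_error(parse_motif("DRB1*38V~25R"), "increasing")
  expect_error(parse_motif("DRB1*25RR"), "malformed motif term")
})

test_that("alignment_search reads residues at requested positions", {
  aln <- parse_alignment(tiny_prot_text(), "prot")
  expect_equal(alignment_search(aln, "A*01:01", c(1, 5, 10)), "1M~5A~10L")
  expect_equal(alignment_search(aln, "A*02:01", c(2, 10)), "2S~10W")
  expect_error(alignment_search(aln, "A*01:01", 99), "valid range")
  expect_error(alignment_search(aln, "A*09:01", 1), "not in")
})

test_that("truncated allele input resolves deterministically with a warning", {
  fx <- make_alignment_fixture(9, n_alleles = 8)
  aln <- fx$truth
  rows <- alignment_alleles(aln)
  fam <- format(truncate_allele(rows[1L], 1))
  expanded <- sort(rows[startsWith(rows, paste0(fam, ":"))])
  expect_warning(got <- alignment_search(aln, fam, aln$positions[1L]),
                 "matches")
  expect_equal(got, alignment_search(aln, expanded[1L], aln$positions[1L]))
})

test_that("query_positions counts residues over non-unknown rows", {
  txt <- paste(c("HLA-A Protein Sequence Alignments",
                 "IPD-IMGT/HLA Release: 3.59.0", "",
                 " Prot 1",
                 " A*01:01:01 MAV",
                 " A*01:02:01 -S-",
                 " A*02:01:01 -S-",
                 " A*03:01:01 *--"), collapse = "\n")
  aln <- parse_alignment(txt, "prot")
  qp <- query_positions(aln, c(1, 2))
  expect_equal(attr(qp[["1"]], "denominator"), 3L)  # '*' row excluded
  expect_equal(qp[["1"]]$count[qp[["1"]]$residue == "M"], 3L)
  expect_equal(qp[["2"]]$count[qp[["2"]]$residue == "S"], 2L)
  expect_equal(qp[["2"]]$fraction[qp[["2"]]$residue == "S"], 2 / 4)
  # counts per position sum to rows minus '*' rows
  for (p in names(qp)) {
    stars <- sum(aln$seqs[, match(p, aln$positions)] == "*")
    expect_equal(sum(qp[[p]]$count), nrow(aln$seqs) - stars)
  }
})

test_that("an all-unknown column yields an empty distribution", {
  fx <- make_alignment_fixture(10, n_alleles = 3)
  aln <- fx$truth
  aln$seqs[, 5L] <- "*"
  qp <- query_positions(aln, aln$positions[5L])
  expect_equal(nrow(qp[[1L]]), 0L)
  expect_equal(attr(qp[[1L]], "denominator"), 0L)
})

test_that("motif_match equals a brute-force row scan", {
  for (seed in 1:8) {
    fx <- make_alignment_fixture(seed, n_alleles = 10,
                                 variant_density = 0.25)
    aln <- fx$truth
    set.seed(seed)
    idx <- sort(sample(seq_along(aln$positions), 3))
    res <- aln$seqs[1L, idx]
    motif <- list(locus = aln$locus, positions = aln$positions[idx],
                  residues = res)
    got <- motif_match(motif, aln, truncate_to = 2)
    want <- character(0)   # independent scan over rows
    for (a in alignment_alleles(aln)) {
      ok <- TRUE
      for (k in seq_along(idx)) {
        s <- aln$seqs[a, idx[k]]
        if (s == "*" || s != res[k]) ok <- FALSE
      }
      if (ok) want <- c(want, format(truncate_allele(a, 2)))
    }
    expect_setequal(got, sort(unique(want)))
  }
})

test_that("motif matching is monotone under added terms", {
  fx <- make_alignment_fixture(12, n_alleles = 12, variant_density = 0.3)
  aln <- fx$truth
  m1 <- list(locus = aln$locus, positions = aln$positions[3],
             residues = aln$seqs[1, 3])
  m2 <- list(locus = aln$locus, positions = aln$positions[c(3, 7)],
             residues = aln$seqs[1, c(3, 7)])
  expect_true(all(motif_match(m2, aln) %in% motif_match(m1, aln)))
  # every full-name match reproduces the motif residues exactly
  for (a in motif_match(m2, aln, truncate_to = NA)) {
    expect_equal(alignment_search(aln, a, m2$positions),
                 paste0(m2$positions, m2$residues, collapse = "~"))
  }
})

test_that("motif_match validates residues and unknown never matches", {
  aln <- parse_alignment(tiny_prot_text(), "prot")
  expect_error(motif_match(list(locus = "A", positions = "1",
                                residues = "*"), aln),
               "alphabet")
  fx <- make_alignment_fixture(14, n_alleles = 6, n_late = 2)
  aln2 <- fx$truth
  for (col in c(1L, 5L)) {
    m <- list(locus = aln2$locus, positions = aln2$positions[col],
              residues = aln2$seqs[1L, col])
    for (a in motif_match(m, aln2, truncate_to = NA)) {
      expect_true(aln2$seqs[a, col] != "*")
    }
  }
})

test_that("validate_allele reports hits, misses and ambiguity", {
  fx <- make_alignment_fixture(15, n_alleles = 8)
  aln <- fx$truth
  full <- alignment_alleles(aln)[3L]
  expect_true(validate_allele(aln, full)$valid)
  expect_false(validate_allele(aln, "A*77:77")$valid)
  fam <- format(truncate_allele(full, 1))
  v <- validate_allele(aln, fam)
  expect_true(v$valid)
  expect_true(v$ambiguous)
  expect_equal(v$canonical,
               sort(alignment_alleles(aln)[startsWith(
                 alignment_alleles(aln), paste0(fam, ":"))])[1L])
})

test_that("custom_align assembles ragged multi-locus extracts", {
  fa <- make_alignment_fixture(16, locus = "A", n_alleles = 4)
  fb <- make_alignment_fixture(17, locus = "B", n_alleles = 4)
  tables <- list(A = fa$truth, B = fb$truth)
  requests <- list(list(locus = "A", positions = fa$truth$positions[c(2, 4, 6)]),
                   list(locus = "B", positions = fb$truth$positions[2]))
  alleles <- c(alignment_alleles(fa$truth)[1], alignment_alleles(fb$truth)[1])
  out <- custom_align(tables, requests, alleles)
  expect_equal(dim(out), c(2L, 3L))
  # loop oracle: every cell reproduces alignment_search
  expect_equal(unname(unlist(out[1, ])),
               unname(fa$truth$seqs[1, c(2, 4, 6)]))
  expect_equal(unname(unlist(out[2, ])),
               unname(c(fb$truth$seqs[1, 2], "*", "*")))
  expect_error(custom_align(tables, requests, "DRB1*01:01"), "no request")
})
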