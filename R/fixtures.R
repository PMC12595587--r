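#' @title Seeded synthetic-data generators
#' @description
#' Every input dialect the package reads (IMGT-dialect alignments, the
#' allele-list history CSV, allele-frequency and haplotype-frequency TSVs)
#' can be generated synthetically with known ground truth, so the whole
#' pipeline is testable offline.  All generators are deterministic under
#' their `seed`.
#' @name fixtures
NULL

HK_AA <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
HK_NT <- c("A", "C", "G", "T")

# population sites used by the frequency fixtures; all verified to fall on
# land cells of the packaged synthetic coastline at 1-2 degree resolution
HK_FIXTURE_SITES <- data.frame(
  site = c("iberia", "sahel", "s_africa", "anatolia", "n_india", "e_china",
           "siberia", "se_asia", "c_australia", "amazonia", "andes",
           "patagonia", "great_plains", "yucatan", "quebec", "alaska",
           "c_europe", "urals", "horn", "congo", "mongolia", "deccan"),
  lat = c(40, 15, -29, 39, 27, 30, 60, 15, -25, -5, -15, -45, 40, 19, 50,
          64, 49, 57, 8, -2, 47, 18),
  lon = c(-5, 0, 24, 32, 76, 110, 100, 101, 135, -60, -70, -70, -100, -89,
          -72, -150, 10, 60, 45, 20, 100, 78),
  stringsAsFactors = FALSE)

hk_allele_names <- function(locus, n, fields = 4L) {
  fam <- rep(1:9, each = 12)[seq_len(n)]
  idx <- stats::ave(fam, fam, FUN = seq_along)
  base <- sprintf("%s*%02d:%02d", locus, fam, idx)
  if (fields >= 3L) base <- paste0(base, ":01")
  if (fields >= 4L) base <- paste0(base, ":01")
  base
}

#' Generate an IMGT-dialect alignment fixture
#'
#' Emits block-formatted dialect text together with the independently
#' constructed ground-truth table it encodes.  The fixture exercises every
#' dialect feature: identity dashes, indel and unknown symbols, boundary
#' markers, insertion columns (fractional labels), alleles entering in a
#' later block and alleles terminating early.
#'
#' @param seed integer seed.
#' @param locus locus name.
#' @param align_type `"prot"`, `"nuc"` or `"gen"`.
#' @param n_alleles number of alleles (>= 1).
#' @param n_positions sequence length for `prot` (feature lengths define it
#'   for `nuc`/`gen`).
#' @param feature_lengths named vector of feature lengths for `nuc`/`gen`
#'   fixtures (defaults provided).
#' @param variant_density per-cell substitution probability.
#' @param n_insertions number of insertion columns.
#' @param n_late,n_early number of late-entering / early-terminating
#'   alleles.
#' @param block_width emitted block width (50-100 in the upstream files).
#' @param version release string stamped in the header.
#' @return list with `text` (dialect text) and `truth` (`hla_alignment`).
#' @export
make_alignment_fixture <- function(seed, locus = "A",
                                   align_type = c("prot", "nuc", "gen"),
                                   n_alleles = 8L, n_positions = 60L,
                                   feature_lengths = NULL,
                                   variant_density = 0.08,
                                   n_insertions = 1L, n_late = 1L,
                                   n_early = 1L, block_width = 60L,
                                   version = "3.59.0") {
  align_type <- match.arg(align_type)
  if (n_alleles < 1L) stop("fixture needs at least one allele", call. = FALSE)
  set.seed(seed)

  if (align_type == "gen" && is.null(feature_lengths)) {
    feature_lengths <- c(U.5 = 18L, E.1 = 12L, I.1 = 9L, E.2 = 15L,
                         I.2 = 9L, E.3 = 12L, U.3 = 15L)
  }
  if (align_type == "nuc" && is.null(feature_lengths)) {
    feature_lengths <- c(E.1 = 12L, E.2 = 15L, E.3 = 12L)
  }
  alphabet <- if (align_type == "prot") HK_AA else HK_NT
  if (align_type == "prot") {
    base_n <- n_positions
    first_label <- -4L                       # 4-residue leader peptide
    bounds_base <- integer(0)
  } else {
    base_n <- sum(feature_lengths)
    first_label <- if (align_type == "gen")
      -as.integer(feature_lengths[["U.5"]]) else 1L
    bounds_base <- cumsum(feature_lengths)[-length(feature_lengths)]
  }

  # insertion anchors: strictly inside, away from boundary columns
  avail <- setdiff(2:(base_n - 1L), c(bounds_base, bounds_base + 1L))
  anchors <- sort(sample(avail, min(n_insertions, length(avail))))

  # final column layout: base columns with insertions spliced in after anchors
  is_ins <- logical(0)
  base_id <- integer(0)
  for (b in seq_len(base_n)) {
    is_ins <- c(is_ins, FALSE)
    base_id <- c(base_id, b)
    k <- sum(anchors == b)
    if (k) {
      is_ins <- c(is_ins, rep(TRUE, k))
      base_id <- c(base_id, rep(b, k))
    }
  }
  N <- length(is_ins)
  bounds <- vapply(bounds_base, function(b) max(which(base_id == b)),
                   integer(1))

  ref <- ifelse(is_ins, ".", sample(alphabet, N, replace = TRUE))
  names_all <- hk_allele_names(locus, n_alleles)
  if (n_alleles >= 3L) {
    names_all[n_alleles] <- paste0(names_all[n_alleles], "N")  # null allele
  }
  seqs <- matrix(rep(ref, each = n_alleles), nrow = n_alleles,
                 dimnames = list(names_all, NULL))
  for (i in seq_len(n_alleles)[-1L]) {
    mut <- stats::runif(N) < variant_density
    seqs[i, mut] <- vapply(which(mut), function(j) {
      if (is_ins[j]) sample(alphabet, 1L)
      else sample(setdiff(alphabet, ref[j]), 1L)
    }, character(1))
    # insertion carriers: some alleles hold residues in insertion columns
    carry <- is_ins & stats::runif(N) < 0.5
    seqs[i, carry] <- sample(alphabet, sum(carry), replace = TRUE)
  }
  # late entrants / early terminators (never the reference)
  others <- seq_len(n_alleles)[-1L]
  late <- utils::head(others, n_late)
  early <- utils::tail(others, n_early)
  for (i in late) {
    run <- sample.int(max(1L, N %/% 3L), 1L)
    seqs[i, seq_len(run)] <- "*"
  }
  for (i in early) {
    run <- sample.int(max(1L, N %/% 3L), 1L)
    seqs[i, (N - run + 1L):N] <- "*"
  }

  positions <- hk_position_labels(ref, first_label)
  feats <- hk_boundary_features(length(bounds), align_type)
  truth <- hk_new_alignment(locus, align_type, version, names_all[1L],
                            positions, seqs,
                            cbind(feats, data.frame(col = bounds)))
  list(text = write_alignment(truth, block_width), truth = truth)
}

#' Generate an allele-list history fixture
#'
#' Builds a history with scripted renames (an accession whose name changes
#' between releases), deletions (names that stop appearing in newer
#' releases) and additions (accessions absent from older releases).
#'
#' @param seed integer seed.
#' @param n_accessions number of base accessions.
#' @param releases release strings, newest first.
#' @param n_renames,n_deletions,n_additions scripted event counts.
#' @return list with `text` (CSV), `truth` (`allele_history`) and `events`
#'   (data frame of scripted renames/deletions/additions).
#' @export
make_history_fixture <- function(seed, n_accessions = 12L,
                                 releases = c("3.61.0", "3.59.0", "3.56.0"),
                                 n_renames = 2L, n_deletions = 2L,
                                 n_additions = 2L) {
  set.seed(seed)
  loci <- sample(c("A", "B", "C", "DRB1", "DQB1"), n_accessions,
                 replace = TRUE)
  names0 <- sprintf("%s*%02d:%02d:01", loci,
                    sample(1:40, n_accessions, replace = TRUE),
                    seq_len(n_accessions))
  stopifnot(!anyDuplicated(names0))
  acc <- sprintf("HLA%05d", seq_len(n_accessions))
  nrel <- length(releases)
  tab <- data.frame(accession = acc, stringsAsFactors = FALSE)
  for (v in releases) tab[[v]] <- names0

  events <- list()
  pool <- seq_len(n_accessions)
  take <- function(n) {
    i <- utils::head(pool, n)
    pool <<- setdiff(pool, i)
    i
  }
  for (i in take(n_renames)) {
    new <- sprintf("%s*%02d:%03d", loci[i], sample(1:40, 1L), 100L + i)
    # renamed in every release newer than the oldest
    for (v in releases[-nrel]) tab[[v]][i] <- new
    events[[length(events) + 1L]] <- data.frame(
      accession = acc[i], event = "rename", old = names0[i], new = new)
  }
  for (i in take(n_deletions)) {
    for (v in releases[-nrel]) tab[[v]][i] <- NA_character_
    events[[length(events) + 1L]] <- data.frame(
      accession = acc[i], event = "deletion", old = names0[i],
      new = NA_character_)
  }
  for (i in take(n_additions)) {
    for (v in releases[-1L]) tab[[v]][i] <- NA_character_
    events[[length(events) + 1L]] <- data.frame(
      accession = acc[i], event = "addition", old = NA_character_,
      new = names0[i])
  }
  truth <- structure(list(versions = releases, table = tab,
                          source_version = releases[1L]),
                     class = "allele_history")
  list(text = write_allele_history(truth), truth = truth,
       events = do.call(rbind, events))
}

hk_rdirichlet <- function(n, alpha) {
  x <- stats::rgamma(n, shape = alpha)
  x / sum(x)
}

#' Generate allele-frequency and haplotype-frequency fixtures
#'
#' Per (population, locus) the allele frequencies are Dirichlet-distributed
#' over the locus allele pool; one allele can be planted at a high
#' frequency in one population so map tests have an analytic expectation.
#' The haplotype table mixes two- and three-field allele names and several
#' locus sets across populations, emulating haplotype data pooled from
#' heterogeneous sources.
#'
#' @param seed integer seed.
#' @param loci loci of the allele-frequency table.
#' @param alleles_per_locus pool size per locus.
#' @param n_populations number of populations (max 22).
#' @param concentration Dirichlet concentration parameter.
#' @param migrant_fraction fraction of populations flagged migrant/admixed.
#' @param planted `NULL`, or list with `locus`, `population` (site index)
#'   and `freq`: the first pool allele of `locus` is pinned to `freq` in
#'   that population.
#' @param hap_loci loci used for haplotypes; each population gets one of
#'   the subsets of `hap_loci` of size >= 2 and either two- or three-field
#'   names.
#' @return list with `freq` (`hk_freq_table`), `hap` (`hk_hap_table`) and
#'   `truth` (site table, allele pools, planted spec).
#' @export
make_frequency_fixture <- function(seed, loci = c("A", "C"),
                                   alleles_per_locus = 6L,
                                   n_populations = 8L, concentration = 1,
                                   migrant_fraction = 0.25,
                                   planted = NULL,
                                   hap_loci = c("A", "B", "C", "DRB1")) {
  set.seed(seed)
  stopifnot(n_populations <= nrow(HK_FIXTURE_SITES))
  sites <- HK_FIXTURE_SITES[seq_len(n_populations), ]
  pops <- paste0("pop_", sites$site)
  n_mig <- ceiling(migrant_fraction * n_populations)
  complex <- c(rep("mig", n_mig), rep("ind", n_populations - n_mig))

  pools <- lapply(stats::setNames(loci, loci), function(l)
    hk_allele_names(l, alleles_per_locus, fields = 2L))

  rows <- list()
  for (p in seq_len(n_populations)) {
    for (l in loci) {
      f <- hk_rdirichlet(alleles_per_locus, concentration)
      if (!is.null(planted) && planted$locus == l &&
          planted$population == p) {
        f <- f * (1 - planted$freq) # renormalise the rest
        f[1L] <- planted$freq
      }
      rows[[length(rows) + 1L]] <- data.frame(
        popname = pops[p], latit = sites$lat[p], longit = sites$lon[p],
        locus = l, allele = pools[[l]], frequency = f,
        sample_size = 2L * sample(50:400, 1L), complex = complex[p],
        stringsAsFactors = FALSE)
    }
  }
  freq <- read_frequency_table(do.call(rbind, rows))

  hap_pools <- lapply(stats::setNames(hap_loci, hap_loci), function(l)
    hk_allele_names(l, alleles_per_locus, fields = 2L))
  locus_sets <- list(hap_loci, hap_loci[1:3], hap_loci[c(1, 3)])
  hrows <- list()
  for (p in seq_len(n_populations)) {
    lset <- locus_sets[[1L + (p - 1L) %% length(locus_sets)]]
    three_field <- (p %% 5L) == 0L          # a minority records three fields
    n_hap <- 10L
    haps <- vapply(seq_len(n_hap), function(k) {
      paste(vapply(lset, function(l) {
        a <- sample(hap_pools[[l]], 1L)
        if (three_field) paste0(a, ":01") else a
      }, character(1)), collapse = "~")
    }, character(1))
    haps <- unique(haps)
    f <- hk_rdirichlet(length(haps), concentration) * 0.9
    hrows[[length(hrows) + 1L]] <- data.frame(
      population = pops[p], haplotype = haps, frequency = f,
      sample_size = 2L * sample(50:400, 1L), latit = sites$lat[p],
      longit = sites$lon[p], stringsAsFactors = FALSE)
  }
  hap <- read_haplotype_table(do.call(rbind, hrows))

  list(freq = freq, hap = hap,
       truth = list(sites = cbind(population = pops, sites,
                                  complex = complex),
                    pools = pools, hap_pools = hap_pools,
                    planted = planted))
}

#' Write a complete offline fixture corpus
#'
#' @param seed integer seed.
#' @param dir output directory (created).
#' @return invisibly, the list of written paths.
#' @export
write_fixture_corpus <- function(seed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  i <- 0L
  for (tp in c("prot", "nuc", "gen")) {
    fx <- make_alignment_fixture(seed + i, locus = "A", align_type = tp)
    p <- file.path(dir, paste0("A_", tp, ".txt"))
    writeLines(fx$text, p)
    paths <- c(paths, p)
    i <- i + 1L
  }
  hs <- make_history_fixture(seed + 100L)
  p <- file.path(dir, "Allelelist_history.txt")
  writeLines(hs$text, p)
  paths <- c(paths, p)
  fq <- make_frequency_fixture(seed + 200L)
  p1 <- file.path(dir, "frequencies.tsv")
  p2 <- file.path(dir, "haplotypes.tsv")
  write_frequency_table(fq$freq, p1)
  write_haplotype_table(fq$hap, p2)
  invisible(c(paths, p1, p2))
}
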