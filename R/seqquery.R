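#' @title Positional and motif queries over alignment tables
#' @description
#' Queries work on the expanded positional tables: residues are read at
#' position labels, amino-acid motifs (`DRB1*25R~38V~48R~127I`) are matched
#' against every row, and per-position variant summaries count residues
#' across alleles.  `*` (unknown/unsequenced) never matches a motif term
#' and is excluded from per-position denominators; `.` (indel) is an
#' ordinary matchable symbol.
#' @name seqquery
NULL

#' Parse a motif specifier
#'
#' @param x motif text `locus*pos1res1~pos2res2...`; both ASCII `~` and the
#'   tilde operator U+223C are accepted as separators.
#' @return list with `locus`, `positions` (character labels, strictly
#'   increasing) and `residues`.
#' @export
parse_motif <- function(x) {
  x <- gsub("∼", "~", x)
  m <- regmatches(x, regexec("^(?:HLA-)?([A-Za-z0-9]+)\\*(.+)$", x))[[1]]
  if (length(m) == 0L) stop("malformed motif: '", x, "'", call. = FALSE)
  terms <- strsplit(m[3], "~", fixed = TRUE)[[1]]
  tm <- regmatches(terms, regexec("^(-?[0-9]+(?:\\.[0-9]+)?)([A-Z.])$", terms))
  if (any(lengths(tm) != 3L)) {
    stop("malformed motif term '", terms[lengths(tm) != 3L][1L],
         "' (expected <position><residue>)", call. = FALSE)
  }
  pos <- vapply(tm, `[`, character(1), 2L)
  res <- vapply(tm, `[`, character(1), 3L)
  num <- as.numeric(pos)
  if (is.unsorted(num, strictly = TRUE)) {
    stop("motif positions must be strictly increasing", call. = FALSE)
  }
  list(locus = m[2], positions = pos, residues = res)
}

#' Render a motif specifier
#' @param motif list as returned by [parse_motif()].
#' @return motif text with ASCII `~` separators.
#' @export
render_motif <- function(motif) {
  paste0(motif$locus, "*",
         paste(paste0(motif$positions, motif$residues), collapse = "~"))
}

hk_position_cols <- function(aln, positions) {
  idx <- match(as.character(positions), aln$positions)
  if (anyNA(idx)) {
    stop("position(s) ", paste(positions[is.na(idx)], collapse = ", "),
         " not in the ", aln$locus, " ", aln$align_type,
         " alignment (valid range ", aln$positions[1L], " .. ",
         aln$positions[length(aln$positions)], ")", call. = FALSE)
  }
  idx
}

# resolve a possibly truncated allele name to a row of the table; truncated
# names resolve to the lexicographically first expansion, with a warning
hk_resolve_allele <- function(aln, allele) {
  name <- if (is.character(allele)) allele else format(allele)
  rows <- rownames(aln$seqs)
  if (name %in% rows) return(name)
  k <- allele_field_count(name)
  hits <- sort(rows[truncate_names(rows, k) == name])
  if (length(hits) == 0L) {
    stop("allele ", name, " not in the ", aln$locus, " ", aln$align_type,
         " alignment", call. = FALSE)
  }
  if (length(hits) > 1L) {
    warning("truncated name ", name, " matches ", length(hits),
            " alleles; using ", hits[1L], call. = FALSE)
  }
  hits[1L]
}

#' Read the residues of an allele at chosen positions
#'
#' @param aln an `hla_alignment`.
#' @param allele full or truncated allele name (truncated names resolve to
#'   the lexicographically first matching row, with a warning).
#' @param positions vector of position labels.
#' @return motif-style string of position+residue terms, e.g.
#'   `"25Q~38V~48R~127I"`.
#' @export
alignment_search <- function(aln, allele, positions) {
  row <- hk_resolve_allele(aln, allele)
  idx <- hk_position_cols(aln, positions)
  paste(paste0(as.character(positions), aln$seqs[row, idx]), collapse = "~")
}

#' Summarise residue usage at chosen positions
#'
#' @inheritParams alignment_search
#' @return named list, one entry per position: data frame with `residue`,
#'   `count` and `fraction` (over non-`*` rows), plus attribute
#'   `denominator`.  A column that is entirely `*` yields an empty
#'   distribution with denominator 0.
#' @export
query_positions <- function(aln, positions) {
  idx <- hk_position_cols(aln, positions)
  out <- lapply(seq_along(idx), function(k) {
    col <- aln$seqs[, idx[k]]
    col <- col[col != "*"]
    denom <- length(col)
    tab <- sort(table(col), decreasing = TRUE)
    df <- data.frame(residue = names(tab), count = as.integer(tab),
                     fraction = if (denom) as.integer(tab) / denom else
                       numeric(0),
                     stringsAsFactors = FALSE)
    attr(df, "denominator") <- denom
    df
  })
  names(out) <- as.character(positions)
  out
}

#' Find all alleles carrying a motif
#'
#' @param motif motif text or the list form from [parse_motif()].
#' @param aln an `hla_alignment` for the motif's locus.
#' @param truncate_to truncate matched names to this many fields before
#'   deduplication (expression suffixes are preserved); `NA` keeps full
#'   names.
#' @return sorted character vector of (truncated) allele names.  `*` at a
#'   queried position never matches.
#' @export
motif_match <- function(motif, aln, truncate_to = 2L) {
  if (is.character(motif)) motif <- parse_motif(motif)
  if (motif$locus != aln$locus) {
    stop("motif locus ", motif$locus, " does not match alignment locus ",
         aln$locus, call. = FALSE)
  }
  bad <- !grepl("^[A-Z.]$", motif$residues)
  if (any(bad)) {
    stop("residue symbol '", motif$residues[bad][1L],
         "' is not in the alignment alphabet", call. = FALSE)
  }
  idx <- hk_position_cols(aln, motif$positions)
  hit <- rep(TRUE, nrow(aln$seqs))
  for (k in seq_along(idx)) {
    hit <- hit & aln$seqs[, idx[k]] == motif$residues[k]
  }
  names <- rownames(aln$seqs)[hit]
  if (!is.na(truncate_to)) names <- truncate_names(names, truncate_to)
  sort(unique(names))
}

#' Validate an allele name against an alignment
#'
#' @inheritParams alignment_search
#' @param name full or truncated allele name.
#' @return list with `valid`, `canonical` (full row name or `NA`) and
#'   `ambiguous` (`TRUE` when a truncated name matches several rows).
#' @export
validate_allele <- function(aln, name) {
  rows <- rownames(aln$seqs)
  if (name %in% rows) {
    return(list(valid = TRUE, canonical = name, ambiguous = FALSE))
  }
  parsed <- tryCatch(parse_hla_allele(name), error = function(e) NULL)
  if (is.null(parsed)) {
    return(list(valid = FALSE, canonical = NA_character_, ambiguous = FALSE))
  }
  k <- length(parsed$fields)
  hits <- sort(rows[truncate_names(rows, k) == format(parsed)])
  list(valid = length(hits) > 0L,
       canonical = if (length(hits)) hits[1L] else NA_character_,
       ambiguous = length(hits) > 1L)
}

#' Build a customized multi-locus alignment extract
#'
#' @param tables named list locus -> `hla_alignment`.
#' @param requests list of requests, each a list with `locus` and
#'   `positions`; requests with fewer positions than the widest request are
#'   padded with `*` cells.
#' @param alleles character vector of allele names; each pairs with the
#'   request for its own locus.
#' @return data frame, one row per allele, one column per requested
#'   position slot; cells hold residues, `*` where no position was
#'   requested for that slot.
#' @export
custom_align <- function(tables, requests, alleles) {
  req_loci <- vapply(requests, `[[`, character(1), "locus")
  widths <- vapply(requests, function(r) length(r$positions), integer(1))
  wmax <- max(widths)
  rows <- lapply(alleles, function(a) {
    locus <- parse_hla_allele(a)$locus
    r <- match(locus, req_loci)
    if (is.na(r)) {
      stop("no request for locus ", locus, " (allele ", a, ")", call. = FALSE)
    }
    aln <- tables[[locus]]
    if (is.null(aln)) {
      stop("no alignment available for locus ", locus, call. = FALSE)
    }
    pos <- requests[[r]]$positions
    row <- hk_resolve_allele(aln, a)
    cells <- aln$seqs[row, hk_position_cols(aln, pos)]
    c(cells, rep("*", wmax - length(cells)))
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- paste0("p", seq_len(wmax))
  rownames(out) <- alleles
  out
}
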