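#' @title IMGT-dialect alignment tables
#' @description
#' The IMGT alignment dialect distributed in the `alignments/` directory of
#' the ANHIG/IMGTHLA repository presents one multiple sequence alignment per
#' locus and alignment type (`prot`, `nuc`, `gen`) in blocks of 50-100
#' positions.  Within a block the first sequence is the reference; in every
#' other row `-` means identity to the reference, `.` an indel, `*` unknown
#' or unsequenced residue, and `|` marks a gene-feature boundary.
#' `parse_alignment()` flattens the blocks into a table with one row per
#' allele and one column per aligned position, fully expanded (no identity
#' dashes), with boundary markers lifted into metadata.
#' @name hla_alignment
NULL

HK_TYPE_WORDS <- c(prot = "Protein", nuc = "cDNA", gen = "Genomic",
                   codon = "Codon")
HK_LABEL_KEYWORDS <- c(prot = "Prot", nuc = "cDNA", gen = "gDNA",
                       codon = "Pos.")

# next position label, skipping 0 (protein numbering has ... -2, -1, 1, 2 ...)
hk_next_pos <- function(p) if (p == -1L) 1L else p + 1L

# Synthesize the full column-label vector from the expanded reference row and
# the first block's anchor label.  Insertion columns (reference holds ".")
# get fractional labels n.1, n.2, ... after the preceding integer position n.
hk_position_labels <- function(ref_syms, first_label) {
  n <- length(ref_syms)
  labels <- character(n)
  cur <- NA_integer_
  ins <- 0L
  for (i in seq_len(n)) {
    if (ref_syms[i] == ".") {
      if (is.na(cur)) {
        stop("alignment cannot begin with an insertion column", call. = FALSE)
      }
      ins <- ins + 1L
      labels[i] <- paste0(cur, ".", ins)
    } else {
      cur <- if (is.na(cur)) as.integer(first_label) else hk_next_pos(cur)
      ins <- 0L
      labels[i] <- as.character(cur)
    }
  }
  labels
}

# Feature names flanking the k-th boundary marker given the alignment type.
# gen alignments span 5'UTR | E.1 | I.1 | ... | E.n | 3'UTR; nuc alignments
# contain only spliced exons; prot/codon markers (rare) separate exons.
hk_boundary_features <- function(n_boundaries, align_type) {
  if (n_boundaries == 0L) {
    return(data.frame(left = character(0), right = character(0)))
  }
  if (align_type == "gen") {
    n_feat <- n_boundaries + 1L
    mid <- n_feat - 2L                      # features between the UTRs
    inner <- character(0)
    if (mid > 0L) {
      inner <- ifelse(seq_len(mid) %% 2L == 1L,
                      paste0("E.", (seq_len(mid) + 1L) %/% 2L),
                      paste0("I.", seq_len(mid) %/% 2L))
    }
    feats <- c("U.5", inner, "U.3")
  } else {
    feats <- paste0("E.", seq_len(n_boundaries + 1L))
  }
  data.frame(left = feats[-length(feats)], right = feats[-1L],
             stringsAsFactors = FALSE)
}

hk_new_alignment <- function(locus, align_type, version, reference,
                             positions, seqs, boundaries) {
  stopifnot(is.matrix(seqs), ncol(seqs) == length(positions))
  if (anyDuplicated(positions)) stop("duplicate position labels", call. = FALSE)
  attr(boundaries, "row.names") <- seq_len(nrow(boundaries))
  structure(list(locus = locus, align_type = align_type, version = version,
                 reference = reference, positions = positions, seqs = seqs,
                 boundaries = boundaries),
            class = "hla_alignment")
}

#' @export
print.hla_alignment <- function(x, ...) {
  cat(sprintf("<hla_alignment> %s %s (release %s): %d alleles x %d positions, %d boundaries\n",
              x$locus, x$align_type, x$version, nrow(x$seqs),
              ncol(x$seqs), nrow(x$boundaries)))
  invisible(x)
}

#' Alleles of an alignment table
#' @param aln an `hla_alignment`.
#' @return character vector of full allele names (reference first).
#' @export
alignment_alleles <- function(aln) rownames(aln$seqs)

HK_ALLELE_LINE_RE <- "^\\s*((?:HLA-)?[A-Za-z0-9]+\\*[0-9:]+[NLSCAQ]?)\\s+(\\S.*)$"
HK_LABEL_LINE_RE <- "^\\s*(Prot|cDNA|gDNA|Pos\\.)\\s+(-?[0-9]+)\\s*$"

#' Parse IMGT-dialect alignment text into a positional table
#'
#' @param text character scalar (entire file) or character vector of lines.
#' @param align_type one of `"prot"`, `"nuc"`, `"gen"` (codon tables are
#'   derived from nuc tables with [derive_codon_table()], not parsed).
#' @return An `hla_alignment`: list with `locus`, `align_type`, `version`,
#'   `reference` (full name of the first sequence), `positions` (ordered
#'   column labels; negative for pre-mature-protein positions, fractional
#'   `n.k` for insertion columns), `seqs` (character matrix, one row per
#'   allele, fully expanded), and `boundaries` (data frame `left`, `right`,
#'   `col`: the feature labels flanking each `|` marker and the index of the
#'   last column before it).
#'
#' Alleles that enter the alignment only in a later block are left-padded
#' with `*`; alleles whose sequence ends before the final block are
#' right-padded with `*`.
#' @export
parse_alignment <- function(text, align_type = c("prot", "nuc", "gen")) {
  align_type <- match.arg(align_type)
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)

  ## ---- header: locus and release version ------------------------------
  locus <- NA_character_
  version <- NA_character_
  for (ln in utils::head(lines, 25L)) {
    if (is.na(locus)) {
      m <- regmatches(ln, regexec(
        "^(?:# *file: *)?(?:HLA-)?([A-Za-z0-9]+)(?:_(?:prot|nuc|gen)\\.txt| (?:Protein|cDNA|Nucleotide|Genomic|Codon) Sequence Alignments)",
        ln))[[1]]
      if (length(m)) locus <- m[2]
    }
    if (is.na(version)) {
      m <- regmatches(ln, regexec(
        "(?:Release:?|IPD-IMGT/HLA)\\s+([0-9]+\\.[0-9]+\\.[0-9]+|Latest)", ln))[[1]]
      if (length(m)) version <- m[2]
    }
  }
  if (is.na(locus)) {
    stop("alignment header does not name a locus", call. = FALSE)
  }
  if (is.na(version)) version <- "unknown"

  ## ---- split into blocks ----------------------------------------------
  is_label <- grepl(HK_LABEL_LINE_RE, lines)
  looks_label <- grepl("^\\s*(Prot|cDNA|gDNA|Pos\\.)\\s", lines) & !is_label
  if (any(looks_label)) {
    stop("malformed position-label line in block ",
         sum(is_label[seq_len(which(looks_label)[1])]) + 1L,
         ": '", trimws(lines[which(looks_label)[1]]), "'", call. = FALSE)
  }
  starts <- which(is_label)
  if (length(starts) == 0L) stop("no alignment blocks found", call. = FALSE)

  block_label <- integer(length(starts))
  block_rows <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block_label[b] <- as.integer(
      sub(HK_LABEL_LINE_RE, "\\2", lines[starts[b]]))
    end <- if (b < length(starts)) starts[b + 1L] - 1L else length(lines)
    body <- lines[(starts[b] + 1L):end]
    body <- body[nzchar(trimws(body))]
    body <- body[!grepl("^[ |]*$", body)]           # column rulers
    hit <- regmatches(body, regexec(HK_ALLELE_LINE_RE, body))
    keep <- lengths(hit) == 3L
    names_b <- vapply(hit[keep], `[`, character(1), 2L)
    seqs_b <- gsub("[[:space:]]", "", vapply(hit[keep], `[`, character(1), 3L))
    if (anyDuplicated(names_b)) {
      stop("duplicate allele name '", names_b[duplicated(names_b)][1],
           "' in block ", b, call. = FALSE)
    }
    bad <- grepl("[^A-Z.*|-]", seqs_b)
    if (any(bad)) {
      stop("illegal symbol in sequence for ", names_b[bad][1],
           " in block ", b, call. = FALSE)
    }
    block_rows[[b]] <- list(names = names_b, seqs = seqs_b)
  }
  ref_name <- block_rows[[1L]]$names[1L]

  ## ---- concatenate blocks, tracking boundary markers -------------------
  n_blocks <- length(starts)
  widths <- integer(n_blocks)
  boundary_cols <- integer(0)
  chunks <- list()        # per allele: accumulated symbols
  ended <- character(0)   # alleles whose sequence terminated early
  offset <- 0L
  for (b in seq_len(n_blocks)) {
    br <- block_rows[[b]]
    i_ref <- match(ref_name, br$names)
    if (is.na(i_ref)) {
      stop("reference allele ", ref_name, " missing from block ", b,
           call. = FALSE)
    }
    ref_seq <- br$seqs[i_ref]
    w <- nchar(gsub("|", "", ref_seq, fixed = TRUE))
    widths[b] <- w
    # boundary markers are taken from the reference row
    sym <- strsplit(ref_seq, "")[[1]]
    pos <- 0L
    for (s in sym) {
      if (s == "|") boundary_cols <- c(boundary_cols, offset + pos)
      else pos <- pos + 1L
    }
    for (j in seq_along(br$names)) {
      nm <- br$names[j]
      sq <- gsub("|", "", br$seqs[j], fixed = TRUE)
      nw <- nchar(sq)
      if (nw > w) {
        stop("sequence for ", nm, " in block ", b, " has ", nw,
             " symbols; block width is ", w, call. = FALSE)
      }
      if (nm %in% ended) {
        stop("sequence for ", nm, " reappears in block ", b,
             " after terminating early", call. = FALSE)
      }
      if (nw < w) {
        sq <- paste0(sq, strrep("*", w - nw))
        ended <- c(ended, nm)
      }
      if (is.null(chunks[[nm]])) {
        chunks[[nm]] <- if (offset > 0L) strrep("*", offset) else ""
      }
      chunks[[nm]] <- paste0(chunks[[nm]], sq)
    }
    # alleles present earlier but absent from this block: pad with '*'
    absent <- setdiff(names(chunks), br$names)
    for (nm in absent) chunks[[nm]] <- paste0(chunks[[nm]], strrep("*", w))
    offset <- offset + w
  }
  total <- offset

  alleles <- names(chunks)
  alleles <- c(ref_name, setdiff(alleles, ref_name))
  seqs <- matrix("", nrow = length(alleles), ncol = total,
                 dimnames = list(alleles, NULL))
  for (nm in alleles) {
    v <- strsplit(chunks[[nm]], "")[[1]]
    stopifnot(length(v) == total)
    seqs[nm, ] <- v
  }

  ## ---- expand identity dashes against the reference --------------------
  ref_row <- seqs[ref_name, ]
  if (any(ref_row == "-")) {
    stop("reference row for ", ref_name, " contains identity dashes",
         call. = FALSE)
  }
  for (nm in alleles[-1L]) {
    hit <- seqs[nm, ] == "-"
    if (any(hit)) seqs[nm, hit] <- ref_row[hit]
  }

  positions <- hk_position_labels(ref_row, block_label[1L])

  # block anchor labels must agree with the synthesized labels
  off <- cumsum(c(0L, widths[-n_blocks]))
  for (b in seq_len(n_blocks)) {
    expect <- as.integer(sub("\\..*$", "", positions[off[b] + 1L]))
    if (expect != block_label[b]) {
      stop("block ", b, ": position label ", block_label[b],
           " does not match alignment position ", expect, call. = FALSE)
    }
  }

  feats <- hk_boundary_features(length(boundary_cols), align_type)
  boundaries <- cbind(feats, data.frame(col = boundary_cols))

  hk_new_alignment(locus, align_type, version, ref_name,
                   positions, seqs, boundaries)
}

#' Serialize an alignment table back to the IMGT block dialect
#'
#' Inverse of [parse_alignment()]: the emitted text reparses to an identical
#' table.  Non-reference rows are re-encoded with identity dashes; leading
#' and trailing all-`*` regions of a row are realised by omitting that
#' allele's line from the corresponding blocks.
#'
#' @param aln an `hla_alignment`.
#' @param block_width number of alignment columns per block (50-100 in the
#'   upstream files).
#' @return character scalar of dialect text.
#' @export
write_alignment <- function(aln, block_width = 60L) {
  stopifnot(inherits(aln, "hla_alignment"))
  n <- ncol(aln$seqs)
  alleles <- rownames(aln$seqs)
  ref_row <- aln$seqs[aln$reference, ]

  first_live <- vapply(alleles, function(a) {
    i <- which(aln$seqs[a, ] != "*"); if (length(i)) min(i) else 1L
  }, integer(1))
  last_live <- vapply(alleles, function(a) {
    i <- which(aln$seqs[a, ] != "*"); if (length(i)) max(i) else n
  }, integer(1))

  keyword <- HK_LABEL_KEYWORDS[[aln$align_type]]
  out <- c(
    paste0("HLA-", aln$locus, " ", HK_TYPE_WORDS[[aln$align_type]],
           " Sequence Alignments"),
    paste0("IPD-IMGT/HLA Release: ", aln$version),
    "")
  name_w <- max(nchar(alleles)) + 1L

  emit_row <- function(syms, cols) {
    toks <- character(0)
    count <- 0L
    for (k in seq_along(cols)) {
      if (count > 0L && count %% 10L == 0L) toks <- c(toks, " ")
      toks <- c(toks, syms[k])
      count <- count + 1L
      if (cols[k] %in% aln$boundaries$col) toks <- c(toks, "|")
    }
    paste(toks, collapse = "")
  }

  starts <- seq(1L, n, by = block_width)
  for (s in starts) {
    e <- min(s + block_width - 1L, n)
    cols <- s:e
    anchor <- sub("\\..*$", "", aln$positions[s])
    out <- c(out, paste0(" ", keyword, " ", anchor))
    for (a in alleles) {
      # skip blocks wholly inside this allele's leading/trailing padding
      if (a != aln$reference &&
          (e < first_live[[a]] || s > last_live[[a]])) next
      syms <- aln$seqs[a, cols]
      if (a != aln$reference) {
        ident <- syms == ref_row[cols] & grepl("[A-Z]", ref_row[cols])
        syms[ident] <- "-"
        # trailing early-termination padding inside the block is dropped
        if (e > last_live[[a]]) {
          keep <- cols <= last_live[[a]]
          syms <- syms[keep]
          line_cols <- cols[keep]
        } else line_cols <- cols
      } else line_cols <- cols
      out <- c(out, sprintf(" %-*s %s", name_w, a, emit_row(syms, line_cols)))
    }
    out <- c(out, "")
  }
  paste(out, collapse = "\n")
}

#' Write an alignment table as TSV (alleles x positions)
#' @param aln an `hla_alignment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(aln, path) {
  df <- as.data.frame(aln$seqs, stringsAsFactors = FALSE)
  colnames(df) <- aln$positions
  df <- cbind(allele = rownames(aln$seqs), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a codon alignment from a nucleotide alignment
#'
#' The upstream repository encodes coding-nucleotide and codon alignments in
#' one `_nuc.txt` file; codon tables are therefore derived, not parsed.  The
#' reading frame starts at the first column (the Exon-1 start of a spliced
#' cDNA alignment).  Each codon becomes one column whose cell holds the
#' three constituent nucleotide symbols; insertion columns are attached to
#' the codon of the preceding in-frame position.
#'
#' @param nuc an `hla_alignment` with `align_type == "nuc"`.
#' @return An `hla_alignment` with `align_type == "codon"` and integer codon
#'   labels.
#' @export
derive_codon_table <- function(nuc) {
  stopifnot(inherits(nuc, "hla_alignment"), nuc$align_type == "nuc")
  anchor <- as.integer(sub("\\..*$", "", nuc$positions))
  codon <- (anchor + 2L) %/% 3L          # ceil(pos/3) for positive positions
  groups <- split(seq_along(codon), codon)
  labels <- as.character(sort(unique(codon)))
  groups <- groups[labels]
  seqs <- matrix("", nrow = nrow(nuc$seqs), ncol = length(groups),
                 dimnames = list(rownames(nuc$seqs), NULL))
  for (g in seq_along(groups)) {
    cols <- groups[[g]]
    seqs[, g] <- apply(nuc$seqs[, cols, drop = FALSE], 1L, paste, collapse = "")
  }
  boundaries <- nuc$boundaries
  if (nrow(boundaries)) {
    boundaries$col <- match(as.character(codon[boundaries$col]), labels)
  }
  hk_new_alignment(nuc$locus, "codon", nuc$version, nuc$reference,
                   labels, seqs, boundaries)
}
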