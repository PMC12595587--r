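#' @title Gene-feature atlases
#' @description
#' An atlas records, for every alignment of a locus, where each gene-feature
#' boundary falls: the feature labels on either side, the position labels of
#' the flanking columns, and (for nucleotide alignments) the codon spanning
#' the boundary.  Codons are numbered on the mature protein: when a protein
#' alignment is supplied its leader-peptide length (the number of negative
#' position labels) is subtracted from the raw cDNA codon index.
#' @name hla_atlas
NULL

#' Build the atlas entry for one locus
#'
#' @param tables named list of `hla_alignment` objects for a single locus;
#'   names are alignment types (`prot`, `nuc`, `codon`, `gen`).
#' @param version release string; defaults to the first table's version.
#' @return An object of class `hla_atlas_entry`: list with `locus`,
#'   `version`, and one data frame per alignment type with columns `left`,
#'   `right` (flanking feature labels), `before`, `after` (position labels
#'   of the flanking columns) and `codon` (`NA` outside nuc alignments).
#' @export
build_atlas <- function(tables, version = NULL) {
  stopifnot(length(tables) > 0L)
  locus <- unique(vapply(tables, `[[`, character(1), "locus"))
  if (length(locus) != 1L) {
    stop("build_atlas() takes the alignments of a single locus", call. = FALSE)
  }
  if (is.null(version)) version <- tables[[1L]]$version

  leader <- 0L
  if (!is.null(tables$prot)) {
    leader <- sum(grepl("^-", tables$prot$positions))
  }

  entries <- lapply(names(tables), function(tp) {
    aln <- tables[[tp]]
    b <- aln$boundaries
    if (nrow(b) == 0L) {
      return(data.frame(left = character(0), right = character(0),
                        before = character(0), after = character(0),
                        codon = integer(0)))
    }
    if (any(b$col < 1L | b$col >= ncol(aln$seqs))) {
      stop("degenerate boundary marker at the edge of the ", aln$locus, " ",
           tp, " alignment", call. = FALSE)
    }
    out <- data.frame(left = b$left, right = b$right,
                      before = aln$positions[b$col],
                      after = aln$positions[b$col + 1L],
                      codon = NA_integer_, stringsAsFactors = FALSE)
    if (tp == "nuc") {
      cdna <- as.integer(sub("\\..*$", "", out$before))
      out$codon <- (cdna + 2L) %/% 3L - leader
    }
    out
  })
  names(entries) <- names(tables)
  structure(list(locus = locus, version = version, entries = entries),
            class = "hla_atlas_entry")
}

#' @export
print.hla_atlas_entry <- function(x, ...) {
  cat(sprintf("<hla_atlas_entry> %s (release %s): %s\n", x$locus, x$version,
              paste(sprintf("%s[%d]", names(x$entries),
                            vapply(x$entries, nrow, integer(1))),
                    collapse = " ")))
  invisible(x)
}

#' Serialize an atlas entry to JSON
#' @param entry an `hla_atlas_entry`.
#' @param path optional output path; when `NULL` the JSON text is returned.
#' @return JSON text or `path`, invisibly when written.
#' @export
atlas_to_json <- function(entry, path = NULL) {
  txt <- jsonlite::toJSON(unclass(entry), dataframe = "rows", na = "null",
                          auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read an atlas entry from JSON
#' @param path JSON path or JSON text.
#' @return an `hla_atlas_entry`.
#' @export
atlas_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  x$entries <- lapply(x$entries, function(df) {
    if (length(df) == 0L) {
      data.frame(left = character(0), right = character(0),
                 before = character(0), after = character(0),
                 codon = integer(0))
    } else as.data.frame(df)
  })
  structure(x, class = "hla_atlas_entry")
}

#' Gene-body length of an allele
#'
#' The gene body is the contiguous sequence of all exons and introns: the
#' region of a genomic alignment between the 5'UTR/Exon-1 boundary and the
#' last-exon/3'UTR boundary.  The length counts every non-indel symbol of
#' the allele's row in that region.
#'
#' @param gen an `hla_alignment` with `align_type == "gen"`.
#' @param allele full allele name (row of `gen`).
#' @return integer nucleotide count.
#' @export
gene_body_length <- function(gen, allele) {
  stopifnot(inherits(gen, "hla_alignment"), gen$align_type == "gen")
  if (is.character(allele) && !allele %in% rownames(gen$seqs)) {
    stop("allele ", allele, " not in the ", gen$locus, " genomic alignment",
         call. = FALSE)
  }
  b <- gen$boundaries
  i5 <- which(b$left == "U.5")
  i3 <- which(b$right == "U.3")
  if (length(i5) != 1L || length(i3) != 1L) {
    stop("missing UTR boundaries in the ", gen$locus, " genomic alignment",
         call. = FALSE)
  }
  cols <- (b$col[i5] + 1L):b$col[i3]
  sum(gen$seqs[allele, cols] != ".")
}
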