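#' @title Feature nomenclature for pseudogenes and gene fragments
#' @description
#' Expressed genes decompose into UTRs, exons and introns, but pseudogenes
#' and gene fragments need not.  Comparing a fragment's genomic alignment to
#' an expressed reference gene, each fragment feature is classified as a
#' standard feature (it covers exactly one full reference feature), a
#' *segment* (S: a proper subset of one reference feature), a *join* (J:
#' contiguous sequence crossing one or more reference boundaries), a
#' *hybrid* (H: a mix of reference-aligned and novel sequence) or *novel*
#' (N: nothing aligns).  Standard features inherit the reference feature's
#' number; H/J/N/S features are numbered by order of appearance 5' to 3'.
#' @name fragment_features
NULL

hk_feature_word <- function(label) {
  if (label == "U.5") return("the 5' UTR")
  if (label == "U.3") return("the 3' UTR")
  n <- sub("^[EI]\\.", "", label)
  if (startsWith(label, "E.")) paste("Exon", n) else paste("Intron", n)
}

# per-column feature label for an alignment with boundary metadata
hk_column_features <- function(aln) {
  n <- ncol(aln$seqs)
  b <- aln$boundaries
  if (nrow(b) == 0L) return(rep(NA_character_, n))
  labels <- c(b$left, b$right[nrow(b)])
  idx <- findInterval(seq_len(n) - 0.5, b$col) + 1L
  labels[idx]
}

#' Classify the gene features of a fragment against a reference gene
#'
#' @param fragment_gen genomic `hla_alignment` of the pseudogene or gene
#'   fragment; its own boundary markers partition it into features, and its
#'   first row is the sequence classified.
#' @param reference_gen genomic `hla_alignment` of the expressed reference
#'   gene (HLA-C for class I fragments; DPA1/DPB1 for the DP pseudogenes).
#' @param pairing integer vector, one entry per `fragment_gen` column:
#'   index of the corresponding `reference_gen` column, or `NA` for novel
#'   (unaligned) sequence.  Must be monotonic over non-`NA` entries.  When
#'   `NULL`, columns are paired by shared position labels, which is exact
#'   when the fragment was lifted from the reference's own alignment file.
#' @return An object of class `hla_featureset`: list with `gene`,
#'   `reference_gene`, `features` (ordered labels), `annotation` (named
#'   character, one free-text entry per non-standard feature) and `version`.
#' @export
classify_fragment_features <- function(fragment_gen, reference_gen,
                                       pairing = NULL) {
  stopifnot(inherits(fragment_gen, "hla_alignment"),
            inherits(reference_gen, "hla_alignment"))
  nf <- ncol(fragment_gen$seqs)
  if (is.null(pairing)) {
    pairing <- match(fragment_gen$positions, reference_gen$positions)
  }
  stopifnot(length(pairing) == nf)
  nn <- pairing[!is.na(pairing)]
  if (is.unsorted(nn, strictly = TRUE)) {
    stop("column pairing is not monotonic", call. = FALSE)
  }

  ref_feat <- hk_column_features(reference_gen)
  ref_row <- reference_gen$seqs[reference_gen$reference, ]
  # reference feature -> set of sequence-bearing reference columns
  ref_sets <- split(which(ref_row != "."), ref_feat[ref_row != "."])

  frag_row <- fragment_gen$seqs[1L, ]
  frag_feat_id <- {
    b <- fragment_gen$boundaries
    findInterval(seq_len(nf) - 0.5, if (nrow(b)) b$col else integer(0)) + 1L
  }

  features <- character(0)
  annotation <- list()
  counters <- c(H = 0L, J = 0L, N = 0L, S = 0L)

  for (fid in sort(unique(frag_feat_id))) {
    cols <- which(frag_feat_id == fid & frag_row != ".")
    if (length(cols) == 0L) next
    mapped <- pairing[cols]
    aligned <- cols[!is.na(mapped)]
    novel <- cols[is.na(mapped)]
    A <- pairing[aligned]
    touched <- unique(ref_feat[A])

    # run structure (novel / per-reference-feature runs), for annotations
    runs <- rle(ifelse(is.na(mapped), "novel", ref_feat[pairing[cols]]))
    describe <- paste(vapply(seq_along(runs$lengths), function(k) {
      what <- runs$values[k]
      len <- runs$lengths[k]
      if (what == "novel") {
        paste0(len, " nucleotides of novel sequence")
      } else if (len == length(ref_sets[[what]])) {
        paste0("all of ", hk_feature_word(what), " (", len, " nt)")
      } else {
        paste0(len, " nucleotides of ", hk_feature_word(what))
      }
    }, character(1)), collapse = " followed by ")

    if (length(aligned) == 0L) {
      counters["N"] <- counters["N"] + 1L
      lab <- paste0("N.", counters["N"])
      annotation[[lab]] <- paste0(lab, " is ", describe, ".")
    } else if (length(novel) > 0L) {
      counters["H"] <- counters["H"] + 1L
      lab <- paste0("H.", counters["H"])
      annotation[[lab]] <- paste0(lab, " is ", describe, ".")
    } else if (length(touched) >= 2L) {
      counters["J"] <- counters["J"] + 1L
      lab <- paste0("J.", counters["J"])
      annotation[[lab]] <- paste0(lab, " is ", describe, ".")
    } else if (setequal(A, ref_sets[[touched]])) {
      lab <- touched                       # standard feature, full coverage
    } else {
      counters["S"] <- counters["S"] + 1L
      lab <- paste0("S.", counters["S"])
      annotation[[lab]] <- paste0(lab, " is ", describe, ".")
    }
    features <- c(features, lab)
  }

  structure(list(gene = fragment_gen$locus,
                 reference_gene = reference_gen$locus,
                 features = features,
                 annotation = annotation,
                 version = fragment_gen$version),
            class = "hla_featureset")
}

#' @export
print.hla_featureset <- function(x, ...) {
  cat(sprintf("<hla_featureset> %s vs %s (release %s): %s\n", x$gene,
              x$reference_gene, x$version, paste(x$features, collapse = ", ")))
  for (a in x$annotation) cat("  ", a, "\n", sep = "")
  invisible(x)
}

#' Serialize a feature set to JSON
#' @param fs an `hla_featureset`.
#' @param path optional output path.
#' @return JSON text, or `path` invisibly when written.
#' @export
featureset_to_json <- function(fs, path = NULL) {
  txt <- jsonlite::toJSON(unclass(fs), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}
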