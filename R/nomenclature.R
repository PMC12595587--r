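#' @title Allele-name validation and cross-release translation
#' @description
#' The allele-list history keys every allele by a stable accession, so a
#' name valid in one release can be carried to any other release through its
#' accession: look the name up in the source release column, then read the
#' same accession's entry in the target column.  A missing entry means the
#' allele was deleted (or not yet named) in the target release.
#' @name nomenclature
NULL

# strip an optional HLA- prefix for history lookups; history stores bare names
hk_bare_name <- function(name) sub("^HLA-", "", name)

#' Verify an allele name against a specific release
#'
#' @param name allele name (string or `hla_allele`).
#' @param release release string.
#' @param history an `allele_history`.
#' @return list with `valid` (logical) and `accession` (string or `NA`).
#'   Unparseable names raise an error rather than returning invalid.
#' @export
verify_allele <- function(name, release, history) {
  if (is.character(name)) name <- parse_hla_allele(name)
  release <- hk_check_release(history, release)
  bare <- hk_bare_name(format(name))
  col <- history$table[[release]]
  i <- which(!is.na(col) & col == bare)
  list(valid = length(i) > 0L,
       accession = if (length(i)) history$table$accession[i[1L]] else NA_character_)
}

#' Query the allele names of a release
#'
#' @param history an `allele_history`.
#' @param release release string.
#' @param pattern a locus name, allele-name prefix, or substring.
#' @param count_only return the number of matches instead of the names.
#' @return sorted character vector of matching names, or an integer count.
#' @export
query_release <- function(history, release, pattern, count_only = FALSE) {
  release <- hk_check_release(history, release)
  col <- history$table[[release]]
  col <- col[!is.na(col)]
  hits <- col[startsWith(col, pattern) | startsWith(col, paste0(pattern, "*")) |
                grepl(pattern, col, fixed = TRUE)]
  hits <- sort(unique(hits))
  if (count_only) length(hits) else hits
}

#' Translate an allele name between releases
#'
#' A full name is looked up in `from_release` and the accession's name in
#' `to_release` is returned (`NA` if the accession has no entry there, i.e.
#' the allele was deleted or did not yet exist).  A truncated (1-3 field)
#' name absent from `from_release` is expanded to all full names it
#' truncates to, each is translated and re-truncated, and the unique result
#' is returned; differing results raise an ambiguity error.
#'
#' @inheritParams verify_allele
#' @param from_release,to_release release strings.
#' @return translated name (character) or `NA_character_` when the allele
#'   has no name in `to_release`.
#' @export
translate_allele <- function(name, from_release, to_release, history) {
  if (is.character(name)) name <- parse_hla_allele(name)
  from_release <- hk_check_release(history, from_release)
  to_release <- hk_check_release(history, to_release)
  bare <- hk_bare_name(format(name))
  from_col <- history$table[[from_release]]
  i <- which(!is.na(from_col) & from_col == bare)
  if (length(i)) {
    out <- history$table[[to_release]][i[1L]]
    return(if (is.na(out)) NA_character_ else paste0(name$prefix, out))
  }
  # truncated-name path
  k <- length(name$fields)
  if (k < 4L) {
    cand <- which(!is.na(from_col) &
                    startsWith(from_col, paste0(name$locus, "*")))
    cand <- cand[vapply(from_col[cand], function(n) {
      format(truncate_allele(parse_hla_allele(n), k)) == bare
    }, logical(1))]
    if (length(cand)) {
      outs <- history$table[[to_release]][cand]
      outs <- outs[!is.na(outs)]
      if (length(outs) == 0L) return(NA_character_)
      trunc <- unique(truncate_names(outs, k))
      if (length(trunc) > 1L) {
        stop("truncated name ", bare, " is ambiguous in ", to_release, ": ",
             paste(utils::head(trunc, 5L), collapse = ", "), call. = FALSE)
      }
      return(paste0(name$prefix, trunc))
    }
  }
  stop("allele ", format(name), " is not valid in release ", from_release,
       call. = FALSE)
}

#' Translate a genotype dataset between releases
#'
#' The tabular genotype dialect has a `subject` column followed by paired
#' per-locus columns `<locus>_1`, `<locus>_2`; untyped cells are blank.
#'
#' @param tab data frame in the genotype dialect (or path to a TSV/CSV file).
#' @inheritParams translate_allele
#' @return list with `table` (translated data frame; untranslatable cells
#'   keep their input value) and `report` (data frame per locus:
#'   `translated`, `unchanged`, `untranslatable` cell counts), plus a
#'   `flagged` data frame locating every untranslatable cell.
#' @export
translate_dataset <- function(tab, from_release, to_release, history) {
  if (is.character(tab)) {
    sep <- if (grepl("\\.csv$", tab)) "," else "\t"
    tab <- utils::read.table(tab, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character")
  }
  if (!is.data.frame(tab) || names(tab)[1L] != "subject" ||
      !all(grepl("^[A-Za-z0-9]+_[12]$", names(tab)[-1L]))) {
    stop("malformed genotype table: expected columns subject, <locus>_1, ",
         "<locus>_2, ...", call. = FALSE)
  }
  loci <- unique(sub("_[12]$", "", names(tab)[-1L]))
  report <- data.frame(locus = loci, translated = 0L, unchanged = 0L,
                       untranslatable = 0L, stringsAsFactors = FALSE)
  flagged <- list()
  out <- tab
  for (col in names(tab)[-1L]) {
    locus <- sub("_[12]$", "", col)
    r <- match(locus, report$locus)
    for (i in seq_len(nrow(tab))) {
      cell <- tab[[col]][i]
      if (is.na(cell) || !nzchar(cell)) next
      new <- tryCatch(translate_allele(cell, from_release, to_release, history),
                      error = function(e) e)
      if (inherits(new, "error") || is.na(new)) {
        report$untranslatable[r] <- report$untranslatable[r] + 1L
        flagged[[length(flagged) + 1L]] <-
          data.frame(subject = tab$subject[i], column = col, allele = cell,
                     stringsAsFactors = FALSE)
      } else if (identical(new, cell)) {
        report$unchanged[r] <- report$unchanged[r] + 1L
      } else {
        out[[col]][i] <- new
        report$translated[r] <- report$translated[r] + 1L
      }
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(subject = character(0), column = character(0),
               allele = character(0), stringsAsFactors = FALSE)
  list(table = out, report = report, flagged = flagged)
}
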