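#' @title Allele-list history across database releases
#' @description
#' `Allelelist_history.txt` records, for every allele accession (e.g.
#' `HLA00001`), the allele name current in each quarterly IPD-IMGT/HLA
#' release.  Renamed alleles carry different names in different release
#' columns under the same accession; deleted alleles simply stop appearing.
#' @name allele_history
NULL

#' Convert between release strings and repository branch names
#'
#' Each IPD-IMGT/HLA release maps to one repository branch whose name is the
#' release with the dots deleted (`"3.59.0"` -> `"3590"`); `"Latest"` is
#' accepted verbatim.  Unrecognised patterns fail loudly rather than
#' guessing.
#' @param release release string such as `"3.59.0"` or `"Latest"`.
#' @return branch name.
#' @export
release_to_branch <- function(release) {
  if (identical(release, "Latest")) return("Latest")
  if (!grepl("^[0-9]+\\.[0-9]{2}\\.[0-9]$", release)) {
    stop("unrecognised release string '", release,
         "' (expected e.g. \"3.59.0\" or \"Latest\")", call. = FALSE)
  }
  gsub(".", "", release, fixed = TRUE)
}

#' @rdname release_to_branch
#' @param branch branch name such as `"3590"`.
#' @export
branch_to_release <- function(branch) {
  if (identical(branch, "Latest")) return("Latest")
  m <- regmatches(branch, regexec("^([0-9]+)([0-9]{2})([0-9])$", branch))[[1]]
  if (length(m) == 0L) {
    stop("unrecognised release column header '", branch, "'", call. = FALSE)
  }
  paste(m[2], m[3], m[4], sep = ".")
}

hk_normalise_release <- function(x) {
  if (grepl("^[0-9]+\\.[0-9]{2}\\.[0-9]$", x) || identical(x, "Latest")) x
  else branch_to_release(x)
}

#' Parse an allele-list history file
#'
#' @param text character scalar or vector of lines: comma-separated, comment
#'   lines starting with `#`, an accession column (`HLA_ID`) and one column
#'   per release (headers either branch-style `3590` or dotted `3.59.0`).
#' @return An `allele_history`: list with `versions` (dotted release
#'   strings, file order), `table` (data frame: `accession` plus one
#'   character column per release, `NA` where the accession is absent from
#'   that release) and `source_version` (the newest release column).
#' @export
parse_allele_history <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty history file", call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1]]
  if (!header[1L] %in% c("HLA_ID", "Accession", "accession")) {
    stop("history file is missing the accession column (first header is '",
         header[1L], "')", call. = FALSE)
  }
  versions <- vapply(header[-1L], hk_normalise_release, character(1),
                     USE.NAMES = FALSE)
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  ncols <- length(header)
  cells <- vapply(body, function(x) {
    length(x) <- ncols
    x
  }, character(ncols))
  cells <- t(cells)
  cells[!nzchar(cells) | is.na(cells)] <- NA_character_
  tab <- data.frame(accession = cells[, 1L], stringsAsFactors = FALSE)
  for (j in seq_along(versions)) tab[[versions[j]]] <- cells[, j + 1L]
  for (v in versions) {
    present <- !is.na(tab[[v]])
    # every present name must parse; fail on the first offender
    bad <- which(present &
                   !grepl("^[A-Za-z0-9]+\\*[0-9:]+[NLSCAQ]?$", tab[[v]]))
    if (length(bad)) {
      stop("unparseable allele name '", tab[[v]][bad[1L]], "' in release ", v,
           call. = FALSE)
    }
  }
  structure(list(versions = versions, table = tab,
                 source_version = versions[1L]),
            class = "allele_history")
}

#' @export
print.allele_history <- function(x, ...) {
  cat(sprintf("<allele_history> %d accessions x %d releases (%s .. %s)\n",
              nrow(x$table), length(x$versions),
              x$versions[length(x$versions)], x$versions[1L]))
  invisible(x)
}

#' Serialize an allele history back to CSV
#' @param history an `allele_history`.
#' @param branch_headers emit branch-style (`3590`) release headers, as the
#'   upstream file does, instead of dotted ones.
#' @return character scalar of CSV text.
#' @export
write_allele_history <- function(history, branch_headers = TRUE) {
  stopifnot(inherits(history, "allele_history"))
  heads <- if (branch_headers) {
    vapply(history$versions, release_to_branch, character(1))
  } else history$versions
  tab <- history$table
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    vals <- unlist(tab[i, c("accession", history$versions)], use.names = FALSE)
    vals[is.na(vals)] <- ""
    paste(vals, collapse = ",")
  }, character(1))
  paste(c(paste(c("HLA_ID", heads), collapse = ","), rows, ""),
        collapse = "\n")
}

hk_check_release <- function(history, release) {
  release <- hk_normalise_release(release)
  if (!release %in% history$versions) {
    stop("release ", release, " not in history; available: ",
         paste(history$versions, collapse = ", "), call. = FALSE)
  }
  release
}
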