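#' Parse an HLA allele name
#'
#' Splits an allele name written in current WHO nomenclature
#' (`locus*field1:field2[:field3[:field4]][suffix]`) into its components.
#' The optional `HLA-` prefix is preserved and re-emitted on rendering, as is
#' the single-character expression suffix (`N`, `L`, `S`, `C`, `A` or `Q`)
#' that marks null, low, secreted, cell-surface, aberrant or questionable
#' expression.
#'
#' @param x character scalar, e.g. `"B*13:07N"` or `"HLA-DRB1*07:01:01:01"`.
#' @return An object of class `hla_allele` with elements `locus`, `fields`
#'   (character vector of 1-4 numeric field strings), `suffix` (`""` when
#'   absent), `prefix` (`"HLA-"` or `""`) and `raw` (the input).
#' @examples
#' a <- parse_hla_allele("B*13:07:01N")
#' format(truncate_allele(a, 2))  # "B*13:07N"
#' @export
parse_hla_allele <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  m <- regmatches(x, regexec(
    "^(HLA-)?([A-Za-z0-9]+)\\*([0-9:]+)([NLSCAQ])?$", x))[[1]]
  if (length(m) == 0L) {
    stop("not a parseable HLA allele name: '", x, "'", call. = FALSE)
  }
  fields <- strsplit(m[4], ":", fixed = TRUE)[[1]]
  if (length(fields) < 1L || length(fields) > 4L || any(fields == "")) {
    stop("allele name '", x, "' must have 1-4 non-empty colon-separated fields",
         call. = FALSE)
  }
  structure(
    list(prefix = m[2], locus = m[3], fields = fields, suffix = m[5], raw = x),
    class = "hla_allele")
}

#' @export
format.hla_allele <- function(x, ...) {
  paste0(x$prefix, x$locus, "*", paste(x$fields, collapse = ":"), x$suffix)
}

#' @export
print.hla_allele <- function(x, ...) {
  cat("<hla_allele> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.hla_allele <- function(x, ...) format(x)

#' Truncate an allele name to fewer fields
#'
#' Truncation preserves the expression suffix: `B*13:07:01N` truncated to two
#' fields is `B*13:07N`, matching the convention used when frequency-table
#' allele names are extended with their expression variants.
#'
#' @param x an `hla_allele` or character scalar.
#' @param k number of fields to keep (1-4).
#' @return An `hla_allele` with at most `k` fields.
#' @export
truncate_allele <- function(x, k) {
  if (is.character(x)) x <- parse_hla_allele(x)
  stopifnot(inherits(x, "hla_allele"), k >= 1L, k <= 4L)
  if (length(x$fields) <= k) return(x)
  out <- x
  out$fields <- x$fields[seq_len(k)]
  out$raw <- format(out)
  out
}

#' Number of fields in an allele name
#' @param x an `hla_allele` or character scalar.
#' @return integer field count.
#' @export
allele_field_count <- function(x) {
  if (is.character(x)) x <- parse_hla_allele(x)
  length(x$fields)
}

# vectorised truncation of rendered names; used throughout seqquery/freqmap
truncate_names <- function(names, k) {
  vapply(names, function(n) format(truncate_allele(parse_hla_allele(n), k)),
         character(1), USE.NAMES = FALSE)
}

field_counts <- function(names) {
  vapply(names, allele_field_count, integer(1), USE.NAMES = FALSE)
}
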