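#' @title GL Strings and GL String Codes
#' @description
#' A Genotype List (GL) String encodes multi-locus HLA typing results in one
#' delimited string: `^` separates genes, `|` alternative genotypes, `~`
#' haplotype members, `+` the two alleles of a genotype, and `/` ambiguous
#' alternative alleles.  A GL String Code prefixes a GL String with a
#' namespace and the nomenclature release under which the names were
#' assigned: `hla#3.01.0#HLA-A*01:01+HLA-A*02:01`.
#' @name glstring
NULL

HK_GL_DELIMS <- c("^", "|", "~", "+", "/")

#' Tokenize / reassemble a GL String
#'
#' `parse_glstring()` splits a GL String into alternating allele and
#' delimiter tokens, validating every allele leaf; `render_glstring()` is
#' its exact inverse.
#'
#' @param x GL String text.
#' @return An object of class `glstring`: list with `tokens` (character
#'   vector of leaves and delimiters) and `is_delim` (logical mask).
#' @export
parse_glstring <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- regmatches(x, gregexpr("[\\^|~+/]|[^\\^|~+/]+", x))[[1]]
  is_delim <- toks %in% HK_GL_DELIMS
  if (length(toks) == 0L || is_delim[1L] || is_delim[length(toks)] ||
      any(is_delim[-1L] & is_delim[-length(toks)])) {
    stop("malformed GL String: '", x, "'", call. = FALSE)
  }
  for (leaf in toks[!is_delim]) parse_hla_allele(leaf)
  structure(list(tokens = toks, is_delim = is_delim), class = "glstring")
}

#' @rdname parse_glstring
#' @param gl a `glstring`.
#' @export
render_glstring <- function(gl) paste(gl$tokens, collapse = "")

#' @export
print.glstring <- function(x, ...) {
  cat("<glstring> ", render_glstring(x), "\n", sep = "")
  invisible(x)
}

#' Parse / render a GL String Code
#'
#' @param x GL String Code text `namespace#version#glstring`.
#' @return An object of class `glstring_code`: list with `namespace`
#'   (opaque text), `version` (release string) and `glstring`.
#' @export
parse_glstring_code <- function(x) {
  parts <- strsplit(x, "#", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("malformed GL String Code (expected namespace#version#glstring): '",
         x, "'", call. = FALSE)
  }
  structure(list(namespace = parts[1L], version = parts[2L],
                 glstring = parse_glstring(parts[3L])),
            class = "glstring_code")
}

#' @rdname parse_glstring_code
#' @param gc a `glstring_code`.
#' @export
render_glstring_code <- function(gc) {
  paste(gc$namespace, gc$version, render_glstring(gc$glstring), sep = "#")
}

#' @export
print.glstring_code <- function(x, ...) {
  cat("<glstring_code> ", render_glstring_code(x), "\n", sep = "")
  invisible(x)
}

#' Translate a GL String or GL String Code between releases
#'
#' Every allele leaf is translated through the allele history; structure and
#' delimiters are preserved exactly.  For a GL String Code the version field
#' is rewritten to `to_release` as well.
#'
#' @param gl a `glstring`, `glstring_code`, or their text form.
#' @inheritParams translate_allele
#' @param on_missing what to do with a leaf that has no name in
#'   `to_release`: `"fail"` (default) errors naming the leaf; `"keep"`
#'   keeps the source-release name; `"drop"` removes the leaf (an ambiguity
#'   collapses to its surviving alternatives).
#' @return same class as the input (text in, text out).
#' @export
translate_glstring <- function(gl, from_release, to_release, history,
                               on_missing = c("fail", "keep", "drop")) {
  on_missing <- match.arg(on_missing)
  if (is.character(gl)) {
    out <- if (grepl("#", gl, fixed = TRUE)) {
      render_glstring_code(translate_glstring(
        parse_glstring_code(gl), from_release, to_release, history, on_missing))
    } else {
      render_glstring(translate_glstring(
        parse_glstring(gl), from_release, to_release, history, on_missing))
    }
    return(out)
  }
  if (inherits(gl, "glstring_code")) {
    gl$glstring <- translate_glstring(gl$glstring, from_release, to_release,
                                      history, on_missing)
    gl$version <- hk_normalise_release(to_release)
    return(gl)
  }
  stopifnot(inherits(gl, "glstring"))
  toks <- gl$tokens
  is_delim <- gl$is_delim
  drop <- logical(length(toks))
  for (i in which(!is_delim)) {
    prefix <- if (startsWith(toks[i], "HLA-")) "HLA-" else ""
    new <- translate_allele(toks[i], from_release, to_release, history)
    if (is.na(new)) {
      if (on_missing == "fail") {
        stop("allele ", toks[i], " has no name in release ",
             hk_normalise_release(to_release), call. = FALSE)
      }
      if (on_missing == "drop") drop[i] <- TRUE
    } else {
      toks[i] <- new
    }
  }
  if (any(drop)) {
    for (i in which(drop)) {
      # drop one adjacent delimiter with the leaf, preferring the '/' of an
      # ambiguity group so the group collapses to its survivors
      j <- NA_integer_
      if (i > 1L && is_delim[i - 1L] && toks[i - 1L] == "/") j <- i - 1L
      else if (i < length(toks) && is_delim[i + 1L] && toks[i + 1L] == "/") j <- i + 1L
      else if (i > 1L && is_delim[i - 1L]) j <- i - 1L
      else if (i < length(toks)) j <- i + 1L
      if (!is.na(j)) drop[j] <- TRUE
    }
    toks <- toks[!drop]
    is_delim <- is_delim[!drop]
    if (length(toks) == 0L) {
      stop("translation dropped every allele in the GL String", call. = FALSE)
    }
  }
  structure(list(tokens = toks, is_delim = is_delim), class = "glstring")
}
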