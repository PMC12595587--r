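#' @title Versioned retrieval of repository files
#' @description
#' Every IPD-IMGT/HLA release corresponds to one branch of the
#' ANHIG/IMGTHLA repository.  [fetch_release_file()] downloads a file from
#' a release branch and caches it on disk keyed by `(release, path)`, so a
#' file is downloaded at most once per cache directory; all offline work
#' (tests, fixtures) bypasses this function entirely.
#' @name imgt_fetch
NULL

HK_RAW_BASE <- "https://raw.githubusercontent.com/ANHIG/IMGTHLA"

#' Default on-disk cache directory
#' @return path (created if absent).
#' @export
hk_cache_dir <- function() {
  d <- Sys.getenv("HLAKIT_CACHE", tools::R_user_dir("hlakit", "cache"))
  if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Fetch a file from a pinned release branch, with caching
#'
#' @param release release string (`"3.59.0"` style) or `"Latest"`.
#' @param path file path within the branch, e.g. `"alignments/DRB1_prot.txt"`.
#' @param cache_dir cache directory; defaults to [hk_cache_dir()].
#' @return file text (character scalar).
#' @export
fetch_release_file <- function(release, path, cache_dir = hk_cache_dir()) {
  branch <- release_to_branch(release)
  key <- file.path(cache_dir, branch, path)
  if (file.exists(key)) {
    return(paste(readLines(key, warn = FALSE), collapse = "\n"))
  }
  url <- paste(HK_RAW_BASE, branch, path, sep = "/")
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  ok <- tryCatch({
    suppressWarnings(utils::download.file(url, tmp, quiet = TRUE,
                                          mode = "wb")) == 0L
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    # distinguish unknown release from unknown file via the branch landing page
    if (inherits(ok, "error") &&
        grepl("cannot open URL|404", conditionMessage(ok))) {
      probe <- tryCatch({
        suppressWarnings(utils::download.file(
          paste(HK_RAW_BASE, branch, "README.md", sep = "/"),
          tempfile(), quiet = TRUE, mode = "wb")) == 0L
      }, error = function(e) FALSE)
      if (isTRUE(probe)) {
        stop("file '", path, "' not found in release ", release,
             " (cache untouched)", call. = FALSE)
      }
      stop("release ", release, " (branch ", branch, ") is unknown or ",
           "unreachable; if offline, use the fixture generators ",
           "(make_alignment_fixture and friends) instead", call. = FALSE)
    }
    stop("offline and '", path, "' for release ", release,
         " is not cached; use the fixture generators ",
         "(make_alignment_fixture and friends) for offline work",
         call. = FALSE)
  }
  dir.create(dirname(key), recursive = TRUE, showWarnings = FALSE)
  file.copy(tmp, key, overwrite = TRUE)
  paste(readLines(key, warn = FALSE), collapse = "\n")
}

#' List available alignments per locus
#'
#' Scans a directory of IMGT-dialect alignment files named
#' `{locus}_{prot|nuc|gen}.txt` and reports, per locus, the set of available
#' alignment types.  `codon` availability is implied by `nuc` for expressed
#' genes (the coding-nucleotide file carries the reading frame).
#'
#' @param dir directory containing alignment files (a local checkout, a
#'   cache subdirectory, or a fixture directory).
#' @param metadata gene-metadata data frame (see [load_gene_metadata()]);
#'   used to decide which loci are expressed.  Genes absent from `metadata`
#'   are treated as expressed for the codon rule only.
#' @return named list: locus -> character vector of types among
#'   `c("prot", "nuc", "codon", "gen")`.
#' @export
list_alignment_inventory <- function(dir, metadata = load_gene_metadata()) {
  if (!dir.exists(dir)) {
    stop("alignment directory '", dir, "' does not exist", call. = FALSE)
  }
  files <- list.files(dir, pattern = "^[A-Za-z0-9]+_(prot|nuc|gen)\\.txt$")
  if (length(files) == 0L) return(structure(list(), names = character(0)))
  locus <- sub("_(prot|nuc|gen)\\.txt$", "", files)
  type <- sub("^.*_(prot|nuc|gen)\\.txt$", "\\1", files)
  out <- lapply(split(type, locus), function(tt) {
    tt <- unique(tt)
    ord <- c("prot", "nuc", "codon", "gen")
    tt[order(match(tt, ord))]
  })
  for (g in names(out)) {
    expressed <- TRUE
    i <- match(g, metadata$gene)
    if (!is.na(i)) expressed <- metadata$status[i] == "expressed"
    if ("nuc" %in% out[[g]] && expressed) {
      out[[g]] <- intersect(c("prot", "nuc", "codon", "gen"),
                            c(out[[g]], "codon"))
    }
  }
  out[order(names(out))]
}
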