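#' @title Rebuilding every derived dataset in one step
#' @description
#' A bundle is the package's equivalent of rebuilding all derived reference
#' datasets for one database release in a single command: alignments,
#' allele history, inventory, gazetteer and per-locus atlases, each stamped
#' with the release version.  Writing is atomic (nothing is left behind on
#' partial failure) and idempotent (a rerun over unchanged sources is a
#' no-op, detected by content hashing).
#' @name bundle
NULL

#' Build a derived-data bundle from a source directory
#'
#' @param source_dir directory holding `{locus}_{prot|nuc|gen}.txt`
#'   alignment files and optionally `Allelelist_history.txt` (a repository
#'   checkout, a release cache, or a fixture corpus).
#' @param release version string stamped on every element; `"unknown"`
#'   falls back to the versions in the alignment headers.
#' @param metadata gene-metadata table.
#' @return An object of class `hk_bundle`: list with `version`,
#'   `alignments` (locus -> type -> `hla_alignment`), `history` (or
#'   `NULL`), `inventory`, `gazetteer`, `atlas` (locus ->
#'   `hla_atlas_entry`) and `source_hash`.
#' @export
build_bundle <- function(source_dir, release = "unknown",
                         metadata = load_gene_metadata()) {
  inventory <- list_alignment_inventory(source_dir, metadata)
  if (length(inventory) == 0L) {
    stop("no alignment files in ", source_dir, call. = FALSE)
  }
  alignments <- list()
  for (locus in names(inventory)) {
    for (tp in setdiff(inventory[[locus]], "codon")) {
      path <- file.path(source_dir, paste0(locus, "_", tp, ".txt"))
      aln <- parse_alignment(paste(readLines(path, warn = FALSE),
                                   collapse = "\n"), tp)
      if (identical(release, "unknown")) release <- aln$version
      alignments[[locus]][[tp]] <- aln
    }
    if ("codon" %in% inventory[[locus]] &&
        !is.null(alignments[[locus]]$nuc)) {
      alignments[[locus]]$codon <- derive_codon_table(alignments[[locus]]$nuc)
    }
  }
  hist_path <- file.path(source_dir, "Allelelist_history.txt")
  history <- if (file.exists(hist_path)) {
    parse_allele_history(paste(readLines(hist_path, warn = FALSE),
                               collapse = "\n"))
  } else NULL
  gazetteer <- build_gazetteer(inventory, metadata, version = release)
  atlas <- lapply(alignments, build_atlas, version = release)
  files <- list.files(source_dir, full.names = TRUE)
  src_hash <- unname(tools::md5sum(sort(files)))
  structure(list(version = release, alignments = alignments,
                 history = history, inventory = inventory,
                 gazetteer = gazetteer, atlas = atlas,
                 source_hash = paste(src_hash, collapse = "")),
            class = "hk_bundle")
}

#' @export
print.hk_bundle <- function(x, ...) {
  cat(sprintf("<hk_bundle> release %s: %d loci, %s history\n", x$version,
              length(x$alignments), if (is.null(x$history)) "no" else "with"))
  invisible(x)
}

#' Write a bundle to disk atomically
#'
#' All elements are serialized into a staging directory which replaces
#' `dir` only on success; a rerun over sources with an unchanged content
#' hash leaves `dir` untouched.
#'
#' @param bundle an `hk_bundle`.
#' @param dir output directory.
#' @return `dir` invisibly; attribute `skipped` is `TRUE` when the
#'   existing bundle was already current.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "hk_bundle"))
  manifest <- file.path(dir, "MANIFEST.json")
  if (file.exists(manifest)) {
    old <- jsonlite::fromJSON(manifest)
    if (identical(old$source_hash, bundle$source_hash)) {
      out <- dir
      attr(out, "skipped") <- TRUE
      return(invisible(out))
    }
  }
  stage <- paste0(dir, ".staging")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE), add = TRUE)

  for (locus in names(bundle$alignments)) {
    for (tp in names(bundle$alignments[[locus]])) {
      write_alignment_tsv(bundle$alignments[[locus]][[tp]],
                          file.path(stage, paste0(locus, "_", tp, ".tsv")))
    }
    atlas_to_json(bundle$atlas[[locus]],
                  file.path(stage, paste0(locus, "_atlas.json")))
  }
  if (!is.null(bundle$history)) {
    writeLines(write_allele_history(bundle$history),
               file.path(stage, "Allelelist_history.txt"))
  }
  writeLines(jsonlite::toJSON(unclass(bundle$gazetteer), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(stage, "gazetteer.json"))
  writeLines(jsonlite::toJSON(list(version = bundle$version,
                                   source_hash = bundle$source_hash),
                              auto_unbox = TRUE),
             file.path(stage, "MANIFEST.json"))
  unlink(dir, recursive = TRUE)
  if (!file.rename(stage, dir)) {
    stop("could not move staged bundle into place", call. = FALSE)
  }
  ok <- TRUE
  out <- dir
  attr(out, "skipped") <- FALSE
  invisible(out)
}
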