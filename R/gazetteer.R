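#' @title Gene metadata and the gazetteer
#' @description
#' The gazetteer organizes the genes curated by the IPD-IMGT/HLA Database
#' into a fixed roster of 19 structural and functional categories, built
#' from two inputs: the inventory of alignment files available for a
#' release, and a packaged tabular summary of per-gene molecular
#' characteristics (expression status, class, chromosomal map rank).  Map
#' order of the DRB3/DRB4/DRB5 and DRB6/DRB7 genes is ambiguous because of
#' structural variation in the DR region, so those clusters share one map
#' rank and render as merged labels.
#' @name gazetteer
NULL

#' The fixed gazetteer category roster
#' @return character vector of the 19 category names.
#' @export
gazetteer_categories <- function() c(
  "align", "prot", "nuc", "codon", "gen",
  "expressed", "pseudogene", "gene_fragment",
  "classI", "classII", "classI_hla", "classII_hla",
  "classical", "nonclassical",
  "hla_loci", "nonhla_loci",
  "expressed_hla", "not_expressed",
  "map")

#' Load the packaged gene-metadata table
#'
#' One row per gene curated by the IPD-IMGT/HLA Database: expression
#' `status` (expressed / pseudogene / gene_fragment), structural `class`
#' (I / II / other), whether the gene is an HLA locus (`hla`; HFE, MIC and
#' TAP are carried in the database but are not HLA genes), whether it is a
#' classical antigen-presenting locus (`classical`), its centromeric to
#' telomeric `map_index`, and an optional `merged_map_group` for the DRB
#' clusters whose internal order is ambiguous.
#'
#' @param path TSV path; defaults to the copy shipped with the package.
#' @return data frame of gene metadata.
#' @export
load_gene_metadata <- function(path = system.file("extdata",
                                                  "gene_metadata.tsv",
                                                  package = "hlakit")) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = "", fill = TRUE)
  md$hla <- as.logical(md$hla)
  md$classical <- as.logical(md$classical)
  ranks <- md$map_index[is.na(md$merged_map_group)]
  if (anyDuplicated(ranks)) {
    stop("map_index values must be unique outside merged map groups",
         call. = FALSE)
  }
  md
}

#' Build the gene gazetteer
#'
#' @param inventory named list locus -> available alignment types, from
#'   [list_alignment_inventory()].
#' @param metadata gene-metadata data frame.
#' @param version release string stamped on the result.
#' @return An object of class `hla_gazetteer`: named list of ordered gene
#'   vectors, one per category in [gazetteer_categories()], plus `version`.
#' @export
build_gazetteer <- function(inventory, metadata = load_gene_metadata(),
                            version = "unknown") {
  genes <- names(inventory)
  missing <- setdiff(genes, metadata$gene)
  if (length(missing)) {
    stop("gene(s) in inventory missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  md <- metadata[match(genes, metadata$gene), ]
  has <- function(type) sort(genes[vapply(inventory, function(tt)
    type %in% tt, logical(1))])
  by_status <- function(s) sort(genes[md$status == s])
  g <- list(
    align = sort(genes),
    prot = has("prot"),
    nuc = has("nuc"),
    codon = has("codon"),
    gen = has("gen"),
    expressed = by_status("expressed"),
    pseudogene = by_status("pseudogene"),
    gene_fragment = by_status("gene_fragment"),
    classI = sort(genes[md$class == "I"]),
    classII = sort(genes[md$class == "II"]),
    classI_hla = sort(genes[md$class == "I" & md$hla]),
    classII_hla = sort(genes[md$class == "II" & md$hla]),
    classical = sort(genes[md$classical]),
    nonclassical = sort(genes[md$hla & md$status == "expressed" &
                                !md$classical]),
    hla_loci = sort(genes[md$hla]),
    nonhla_loci = sort(genes[!md$hla]),
    expressed_hla = sort(genes[md$hla & md$status == "expressed"]),
    not_expressed = sort(genes[md$status != "expressed"]),
    map = gazetteer_map(metadata))
  stopifnot(identical(names(g), gazetteer_categories()))
  structure(c(g, list(version = version)), class = "hla_gazetteer")
}

# full chromosomal map (all curated genes, not only those with alignments),
# centromeric to telomeric, with merged DRB cluster labels
gazetteer_map <- function(metadata) {
  md <- metadata[order(metadata$map_index), ]
  labels <- ifelse(is.na(md$merged_map_group), md$gene, md$merged_map_group)
  labels[!duplicated(labels)]
}

#' @export
print.hla_gazetteer <- function(x, ...) {
  cat(sprintf("<hla_gazetteer> %d categories, release %s\n",
              length(gazetteer_categories()), x$version))
  for (nm in c("align", "expressed", "pseudogene", "gene_fragment")) {
    cat(sprintf("  %-14s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}
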