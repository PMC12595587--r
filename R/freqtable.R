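#' @title Population frequency tables
#' @description
#' Allele frequencies follow the layout of the published global
#' meta-analysis table (one row per population x locus x allele, with
#' population coordinates and a complexity code flagging migrant or admixed
#' populations); haplotype frequencies follow the layout used by the Allele
#' Frequencies Net Database (one row per population x multi-locus
#' haplotype).
#' @name freqtable
NULL

# complexity codes marking migrant or admixed populations
HK_MIGRANT_CODES <- c("mig", "adm", "migrant", "admixed", "1")

#' Read an allele-frequency table
#'
#' @param path TSV path with header
#'   `popname, latit, longit, locus, allele, frequency, sample_size, complex`,
#'   or a data frame already in that layout.
#' @return data frame of class `hk_freq_table` with the columns above plus
#'   `migrant` (logical, mapped from the complexity code).
#' @export
read_frequency_table <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  }
  need <- c("popname", "latit", "longit", "locus", "allele", "frequency",
            "sample_size", "complex")
  if (!all(need %in% names(tab))) {
    stop("frequency table is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (any(tab$frequency < 0 | tab$frequency > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(tab$latit) > 90) || any(tab$longit <= -180 | tab$longit > 180)) {
    stop("coordinates out of range (lat in [-90,90], lon in (-180,180])",
         call. = FALSE)
  }
  sums <- tapply(tab$frequency, paste(tab$popname, tab$locus), sum)
  if (any(sums > 1 + 1e-6)) {
    bad <- names(sums)[sums > 1 + 1e-6][1L]
    stop("frequencies for ", bad, " sum to more than 1", call. = FALSE)
  }
  tab$migrant <- tolower(as.character(tab$complex)) %in% HK_MIGRANT_CODES
  class(tab) <- c("hk_freq_table", class(tab))
  tab
}

#' Write an allele-frequency table
#' @param tab an `hk_freq_table` (or compatible data frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(tab, path) {
  cols <- c("popname", "latit", "longit", "locus", "allele", "frequency",
            "sample_size", "complex")
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a haplotype-frequency table
#'
#' @param path TSV path with header
#'   `population, haplotype, frequency, sample_size, latit, longit` (the
#'   AFND haplotype layout), or a data frame already in that layout.
#' @return data frame of class `hk_hap_table`.
#' @export
read_haplotype_table <- function(path) {
  tab <- if (is.data.frame(path)) path else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")
  }
  need <- c("population", "haplotype", "frequency", "sample_size",
            "latit", "longit")
  if (!all(need %in% names(tab))) {
    stop("haplotype table is missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  if (any(tab$frequency < 0 | tab$frequency > 1)) {
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  }
  # all haplotypes within one population must share one locus set
  loci_of <- function(h) paste(sort(vapply(
    strsplit(h, "~", fixed = TRUE)[[1]],
    function(a) parse_hla_allele(a)$locus, character(1))), collapse = "~")
  per_pop <- tapply(tab$haplotype, tab$population,
                    function(h) length(unique(vapply(h, loci_of, character(1)))))
  if (any(per_pop != 1L)) {
    stop("population ", names(per_pop)[per_pop != 1L][1L],
         " mixes haplotypes over different locus sets", call. = FALSE)
  }
  class(tab) <- c("hk_hap_table", class(tab))
  tab
}

#' Write a haplotype-frequency table
#' @param tab an `hk_hap_table` (or compatible data frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(tab, path) {
  cols <- c("population", "haplotype", "frequency", "sample_size",
            "latit", "longit")
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
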