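# tiny hand-built dialect texts with exactly known content

tiny_prot_text <- function() paste(c(
  "HLA-A Protein Sequence Alignments",
  "IPD-IMGT/HLA Release: 3.59.0",
  "",
  " Prot 1",
  " A*01:01 MAVMA",
  " A*02:01 -S---",
  "",
  " Prot 6",
  " A*01:01 PRTLL",
  " A*02:01 ----W"), collapse = "\n")

tiny_gen_text <- function() paste(c(
  "HLA-A Genomic Sequence Alignments",
  "IPD-IMGT/HLA Release: 3.59.0",
  "",
  " gDNA -3",
  " A*01:01 ACG|TTTGGG|AAACC",
  " A*02:01 ---|--C---|-T---"), collapse = "\n")

tiny_insertion_text <- function() paste(c(
  "HLA-A Protein Sequence Alignments",
  "IPD-IMGT/HLA Release: 3.59.0",
  "",
  " Prot 1",
  " A*01:01 AC.GT",
  " A*02:01 --W--"), collapse = "\n")

# brute-force per-character expansion of a single-block dialect body,
# independent of the parser's block machinery
expand_by_hand <- function(ref, coded) {
  r <- strsplit(ref, "")[[1]]
  v <- strsplit(coded, "")[[1]]
  paste(ifelse(v == "-", r, v), collapse = "")
}
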