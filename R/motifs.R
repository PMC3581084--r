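# Fixed synthetic reference motifs used by the corpus generator and by the
# default annotation profiles.  These are NOT biological 5.8S/18S/28S
# sequences: they are fixed random 160/60/60-nt strings so that the whole
# test and demo stack runs without any database download.  For biological
# work users build profiles from their own reference alignments with
# build_profile().

MOTIF_5_8S <- paste0(
  "AACCGGGAGCCTTACTTGAAGGATAGACCCCCCCGGTAGGTAGGTCTTCGACGAACAAAC",
  "CCGGACCGCGCCGCACTGGGGTGAGTCAGCCTAACATCCACAACTAGTTGTCTTGTCGCA",
  "ACCCTACCATTCTGCTGTATAAGCCACAGGGAACTCGACC")

MOTIF_FLANK_18S <- "AGACGGAAGACTTCCGGGATAATTTCAAAGCGAGCATCTGCGGCAGTGACGCATGGGCCT"

MOTIF_FLANK_28S <- "TAGCCGAAACGGAGGTGGCATATATCCTACGTTGTTTTTTGACGCATGATCCAAGACACT"

#' Synthetic reference motifs
#'
#' The fixed synthetic conserved segments used by [simulate_corpus()]: a
#' 160-nt stand-in for the 5.8S gene and 60-nt stand-ins for the flanking
#' 18S 3' and 28S 5' ends.  They are arbitrary fixed strings, not real rRNA
#' sequences (synthetic by design so that nothing needs to be downloaded).
#'
#' @return named character vector with elements `r5_8s`, `flank_18s`,
#'   `flank_28s`.
#' @export
reference_motifs <- function() {
  c(r5_8s = MOTIF_5_8S,
    flank_18s = MOTIF_FLANK_18S,
    flank_28s = MOTIF_FLANK_28S)
}

#' Reverse-complement of IUPAC nucleotide strings
#' @param x character vector of sequences.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}
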