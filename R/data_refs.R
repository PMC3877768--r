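# Bundled small-RNA sequences used by the examples, the simulator defaults
# and the complementarity-scan demo. Mature miRNA / star sequences are the
# canonical human miRBase sequences; the antagomir is the published
# anti-miR21 oligonucleotide. The pri-miR30 hairpin below is SYNTHETIC: a
# constructed stand-in (mature miR-30a-5p embedded in an artificial hairpin
# whose 3' arm carries a partial anti-miR21 complement), not a genomic
# transcript.

.mature_seqs <- c(
  miR21     = "UAGCUUAUCAGACUGAUGUUGA",   # hsa-miR-21-5p
  miR21star = "CAACACCAGUCGAUGGGCUGU",    # hsa-miR-21-3p (star strand)
  miR30     = "UGUAAACAUCCUCGACUGGAAG",   # hsa-miR-30a-5p
  miR20     = "UAAAGUGCUUAUAGUGCAGGUAG",  # hsa-miR-20a-5p
  miR28     = "AAGGAGCUCACAGUCUAUUGAG"    # hsa-miR-28-5p
)

.antimir21 <- "ACGGCAACACCAGUCGAUGGGCUGU"  # published anti-miR21 antagomir

#' Bundled mature miRNA and antagomir reference sequences
#'
#' Five human small RNAs central to the anti-miR21 antagomir experiment
#' (miR21, its star strand miR21*, miR30, miR20, miR28) plus the 25-nt
#' anti-miR21 antagomir itself. Sequences are returned DNA-normalized.
#'
#' @param include_antagomir Include the anti-miR21 oligo (role
#'   \code{antagomir}).
#' @return A reference set data.frame (see [reference_set()]).
#' @export
bundled_references <- function(include_antagomir = FALSE) {
  ids <- names(.mature_seqs)
  seqs <- unname(.mature_seqs)
  roles <- c("mature", "star", "mature", "mature", "mature")
  if (include_antagomir) {
    ids <- c(ids, "antimiR21")
    seqs <- c(seqs, .antimir21)
    roles <- c(roles, "antagomir")
  }
  reference_set(ids, seqs, roles)
}

#' The anti-miR21 antagomir sequence
#' @param as_dna Return DNA-normalized (default) rather than the RNA oligo.
#' @return Character scalar.
#' @export
anti_mir21 <- function(as_dna = TRUE) {
  if (as_dna) normalize_alphabet(.antimir21) else .antimir21
}

#' A synthetic pri-miR30 hairpin target
#'
#' A constructed (synthetic, not genomic) primary-transcript-like target:
#' the mature miR-30a-5p sequence near the 5' end, an artificial loop, and a
#' 3' region carrying an 18-nt stretch complementary to the anti-miR21
#' antagomir, so that a complement-mode [complementarity_scan()] locates its
#' best hybrid area toward the 3' end of the hairpin.
#'
#' @return A one-row reference set with role \code{pri_hairpin}.
#' @export
pri_mir30_synthetic <- function() {
  mature <- normalize_alphabet(.mature_seqs[["miR30"]])
  # 18-nt window of the antagomir's reverse complement, placed in the 3' arm
  hybrid <- substr(reverse_complement(anti_mir21()), 1L, 18L)
  seq <- paste0("GCGACCTG", mature, "CTGTAAACTGAG",
                "CTTTCAGTCGGATGTTTG", hybrid, "TGCCACAG")
  reference_set("pri_miR30_synthetic", seq, "pri_hairpin")
}
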