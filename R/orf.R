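# Six-frame open reading frame scanning.
#
# ORF convention: starts at ATG, ends at the first in-frame stop (TAA/TAG/TGA)
# or, if no stop follows, at the last complete codon (partial ORF).  Length is
# reported in amino acids counting codons from the ATG up to but excluding the
# stop.  Codons containing N match neither ATG nor a stop.

#' Reverse complement of a DNA string
#'
#' @param s a character scalar over ACGTN.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

frame_codons <- function(s, frame) {
  L <- nchar(s)
  if (L - frame < 3L) return(character(0))
  starts <- seq.int(frame + 1L, L - 2L, by = 3L)
  substring(s, starts, starts + 2L)
}

# longest ORF (in AA) among the 3 forward frames of one strand
longest_orf_strand <- function(s) {
  best <- 0L
  for (frame in 0:2) {
    codons <- frame_codons(s, frame)
    if (!length(codons)) next
    atg <- which(codons == "ATG")
    if (!length(atg)) next
    stops <- which(codons %in% STOP_CODONS)
    # index of the first stop at or after each ATG (none can coincide)
    nxt_idx <- findInterval(atg, stops) + 1L
    has_stop <- nxt_idx <= length(stops)
    len <- ifelse(has_stop, stops[nxt_idx] - atg, length(codons) - atg + 1L)
    best <- max(best, len)
  }
  as.integer(best)
}

#' Longest open reading frame
#'
#' Scans all three frames of the given strand(s) and returns the length in
#' amino acids of the longest ORF (see convention above: `"ATGAAATAA"` has a
#' 2-AA ORF, Met-Lys, the stop excluded; partial ORFs without a stop count to
#' the last complete codon).
#'
#' @param sequence a character scalar over ACGTN (empty allowed, returns 0).
#' @param both_strands scan the reverse complement as well (default `TRUE`).
#' @return integer AA length of the longest ORF; 0 if no ATG is found.
#' @export
longest_orf <- function(sequence, both_strands = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) return(0L)
  best <- longest_orf_strand(sequence)
  if (both_strands) best <- max(best, longest_orf_strand(revcomp(sequence)))
  best
}

#' Longest ORF with location and sequence
#'
#' Like [longest_orf()] but also returns the strand, the nucleotide sequence
#' of the ORF (ATG through the last counted codon, stop excluded) and its
#' span, for feature extraction by the coding-potential scorer.
#'
#' @inheritParams longest_orf
#' @return A list with `aa`, `strand` (`"+"`/`"-"`/`NA`), and `orf_seq`
#'   (character; `""` when no ORF exists).
#' @export
longest_orf_info <- function(sequence, both_strands = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) {
    return(list(aa = 0L, strand = NA_character_, orf_seq = ""))
  }
  strands <- if (both_strands) c("+", "-") else "+"
  best <- list(aa = 0L, strand = NA_character_, orf_seq = "")
  for (st in strands) {
    s <- if (st == "+") sequence else revcomp(sequence)
    for (frame in 0:2) {
      codons <- frame_codons(s, frame)
      if (!length(codons)) next
      atg <- which(codons == "ATG")
      if (!length(atg)) next
      stops <- which(codons %in% STOP_CODONS)
      nxt_idx <- findInterval(atg, stops) + 1L
      has_stop <- nxt_idx <= length(stops)
      len <- ifelse(has_stop, stops[nxt_idx] - atg, length(codons) - atg + 1L)
      i <- which.max(len)
      if (len[i] > best$aa) {
        nt_start <- frame + 1L + (atg[i] - 1L) * 3L
        best <- list(aa = as.integer(len[i]), strand = st,
                     orf_seq = substr(s, nt_start, nt_start + len[i] * 3L - 1L))
      }
    }
  }
  best
}
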