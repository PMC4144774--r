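# Coding-potential assessment.
#
# A transparent three-feature logistic score stands in for an external
# coding-potential classifier while preserving its decision semantics: a
# transcript with score < 0.5 is called non-coding, >= 0.5 coding.  Features
# are computed from the longest ORF on each strand and the score is the
# maximum over strands (a locus is non-coding only if every orientation is).

#' Codon usage of an ORF
#'
#' Counts every codon of the ORF reading frame (a trailing partial codon is
#' dropped; the stop codon, if present, is counted) and reports frequencies on
#' the conventional per-thousand-codons scale over all 64 codons.
#'
#' @param orf_sequence nucleotide sequence of an ORF (character scalar).
#' @return A list with `freq` (named numeric of length 64, per-thousand) and
#'   `total` (codons counted).  Sequences shorter than one codon give an
#'   all-zero table with `total = 0`.  Codons containing N are skipped.
#' @export
codon_usage <- function(orf_sequence) {
  s <- toupper(as.character(orf_sequence))
  freq <- setNames(numeric(64), ALL_CODONS)
  n <- nchar(s) %/% 3L
  if (n == 0L) return(list(freq = freq, total = 0L))
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  codons <- codons[codons %in% ALL_CODONS]
  if (!length(codons)) return(list(freq = freq, total = 0L))
  tab <- table(factor(codons, levels = ALL_CODONS))
  freq[] <- 1000 * as.numeric(tab) / length(codons)
  list(freq = freq, total = length(codons))
}

#' GC content of a sequence
#'
#' @param sequence character scalar over ACGTN.
#' @return (G+C)/(A+C+G+T); N is excluded from the denominator.  All-N (or
#'   empty) input is undefined and returned as `NA`.
#' @export
gc_content <- function(sequence) {
  s <- toupper(as.character(sequence))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  acgt <- sum(v %in% c("A", "C", "G", "T"))
  if (acgt == 0L) return(NA_real_)
  sum(v %in% c("G", "C")) / acgt
}

#' Pearson correlation between two codon usage tables
#'
#' Computed over the 61 sense codons (stop codons excluded, as frequency
#' tables conventionally cover sense codons).
#'
#' @param table_a,table_b codon usage tables from [codon_usage()] (or named
#'   numeric vectors over the 64 codons).
#' @return Pearson correlation in `[-1, 1]`, or `NA` if either table has zero
#'   variance.
#' @export
usage_correlation <- function(table_a, table_b) {
  fa <- if (is.list(table_a)) table_a$freq else table_a
  fb <- if (is.list(table_b)) table_b$freq else table_b
  a <- fa[SENSE_CODONS]
  b <- fb[SENSE_CODONS]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Synthetic plant-like reference codon usage table
#'
#' A deterministic stand-in for a species codon-usage reference: amino-acid
#' composition follows typical plant proteomes and synonymous-codon preference
#' is GC-biased so that coding sequence reaches the target GC fraction
#' (default 0.426, well above the AT-rich intergenic background).  The
#' synthetic genome generator and the coding-potential scorer share this
#' table.  A user-supplied 64-entry per-thousand table (e.g. from the Codon
#' Usage Database) can be used anywhere this one is accepted.
#'
#' @param target_gc desired expected GC fraction of coding sequence.
#' @return A codon usage table: list with `freq` (per-thousand over 64 codons;
#'   stop codons at 0) and `total = NA`.
#' @export
synthetic_codon_table <- function(target_gc = 0.426) {
  aa_weight <- c(L = 9.0, A = 6.5, S = 8.0, G = 6.5, V = 6.5, E = 6.5,
                 K = 6.5, I = 5.5, D = 5.5, T = 5.0, R = 5.0, P = 4.8,
                 N = 4.5, F = 4.5, Q = 3.5, Y = 3.0, H = 2.3, M = 2.4,
                 C = 1.8, W = 1.2)
  code <- Biostrings::GENETIC_CODE[SENSE_CODONS]
  gc_cnt <- vapply(strsplit(SENSE_CODONS, ""), function(v)
    sum(v %in% c("G", "C")), numeric(1))
  weights_for <- function(beta) {
    w <- aa_weight[code] * exp(beta * gc_cnt)
    w / sum(w)
  }
  expected_gc <- function(beta) sum(weights_for(beta) * gc_cnt) / 3
  lo <- -3; hi <- 3
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (expected_gc(mid) < target_gc) lo <- mid else hi <- mid
  }
  p <- weights_for((lo + hi) / 2)
  freq <- setNames(numeric(64), ALL_CODONS)
  freq[SENSE_CODONS] <- 1000 * p
  list(freq = freq, total = NA_integer_)
}

#' Mean per-codon log-likelihood ratio of an ORF against a reference table
#'
#' For each sense codon in the ORF reading frame, the log of its reference
#' frequency (normalised over sense codons, lightly smoothed) over the uniform
#' 1/61 frequency; the mean over codons is returned.  Positive values indicate
#' reference-like codon usage.
#'
#' @param orf_sequence ORF nucleotide sequence.
#' @param reference a codon usage table (see [codon_usage()]).
#' @return mean log-likelihood ratio; 0 for an empty ORF.
#' @export
codon_llr <- function(orf_sequence, reference) {
  ref <- if (is.list(reference)) reference$freq else reference
  p <- ref[SENSE_CODONS] + 0.1          # smoothing, per-thousand scale
  p <- p / sum(p)
  s <- toupper(as.character(orf_sequence))
  n <- nchar(s) %/% 3L
  if (n == 0L) return(0)
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  codons <- codons[codons %in% SENSE_CODONS]
  if (!length(codons)) return(0)
  mean(log(p[codons] * 61))
}

#' Frozen logistic weights of the coding-potential score
#'
#' Calibrated once, seed-pinned, on the synthetic generator's coding-gene
#' mRNAs (positive class) versus shuffled intergenic sequence (negative
#' class); see `tools/calibrate-coding-weights.R` in the package sources.
#' The ORF-length weight is non-negative, so the score is monotone
#' non-decreasing in ORF length at fixed other features.
#'
#' @return named numeric vector of weights `(intercept, log_orf_aa,
#'   orf_coverage, codon_llr)`.
#' @export
coding_weights <- function() {
  c(intercept = -13.0699, log_orf_aa = 1.9282,
    orf_coverage = 7.6064, codon_llr = 8.9273)
}

#' Coding-potential score of a transcript
#'
#' Computes, for each strand, the longest ORF and its features (ORF length in
#' AA, ORF coverage = ORF nt / transcript nt, codon usage log-likelihood ratio
#' against the reference table), scores each strand with a fixed logistic
#' model, and returns the maximum: a locus is labelled non-coding only when
#' both orientations score below 0.5.
#'
#' @param sequence transcript nucleotide sequence (character scalar).
#' @param reference reference codon usage table (default
#'   [synthetic_codon_table()]).
#' @param weights logistic weights (default [coding_weights()]).
#' @param threshold decision threshold (default 0.5): `score >= threshold`
#'   is labelled coding.
#' @return A list: `score` in `[0, 1]`, `label` (`"coding"`/`"noncoding"`),
#'   and `features` (from the best-scoring strand).
#' @export
coding_score <- function(sequence, reference = synthetic_codon_table(),
                         weights = coding_weights(), threshold = 0.5) {
  s <- toupper(as.character(sequence))
  best <- NULL
  for (st in c("+", "-")) {
    info <- longest_orf_info(if (st == "+") s else revcomp(s),
                             both_strands = FALSE)
    feats <- list(
      orf_aa = info$aa,
      orf_coverage = if (nzchar(s)) nchar(info$orf_seq) / nchar(s) else 0,
      codon_llr = codon_llr(info$orf_seq, reference),
      gc_fraction = gc_content(s))
    eta <- weights[["intercept"]] +
      weights[["log_orf_aa"]] * log(feats$orf_aa + 1) +
      weights[["orf_coverage"]] * feats$orf_coverage +
      weights[["codon_llr"]] * feats$codon_llr
    sc <- 1 / (1 + exp(-eta))
    if (is.null(best) || sc > best$score) {
      best <- list(score = sc, strand = st, features = feats)
    }
  }
  list(score = best$score,
       label = if (best$score >= threshold) "coding" else "noncoding",
       features = best$features)
}
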