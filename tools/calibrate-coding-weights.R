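#!/usr/bin/env Rscript
# One-off, seed-pinned calibration of the coding-potential logistic weights.
#
# Positive class: synthetic coding-gene mRNAs (UTRs + ATG-initiated ORF with
# codons drawn from the shared reference codon table).  Negative class:
# shuffled intergenic sequence (i.i.d. bases at the intergenic GC fraction).
# Features are the ones coding_score() uses: log(orf_aa + 1), ORF coverage,
# and the mean per-codon log-likelihood ratio against the reference table.
# A ridge-regularised logistic fit (glmnet, small lambda) keeps the weights
# finite under near-perfect separation.  The resulting weights are pasted
# into coding_weights() in R/coding.R.

suppressMessages({
  library(poplinc)
  library(glmnet)
})

set.seed(20260925)
ct <- synthetic_codon_table()

features_for <- function(s) {
  best <- NULL
  for (st in c("+", "-")) {
    info <- longest_orf_info(if (st == "+") s else revcomp(s),
                             both_strands = FALSE)
    if (is.null(best) || info$aa > best$aa) best <- info
  }
  c(log_orf_aa = log(best$aa + 1),
    orf_coverage = nchar(best$orf_seq) / nchar(s),
    codon_llr = codon_llr(best$orf_seq, ct))
}

make_mrna <- function() {
  aa <- sample(100:500, 1)
  paste0(poplinc:::random_seq(100, 0.34),
         poplinc:::coding_orf_seq(aa, ct),
         poplinc:::random_seq(200, 0.34))
}
make_negative <- function() poplinc:::random_seq(sample(300:1500, 1), 0.34)

n <- 400
pos <- replicate(n, make_mrna())
neg <- replicate(n, make_negative())
X <- t(vapply(c(pos, neg), features_for, numeric(3)))
y <- rep(1:0, each = n)

fit <- glmnet(X, y, family = "binomial", alpha = 0, lambda = 0.01)
w <- as.numeric(coef(fit))
names(w) <- c("intercept", colnames(X))
stopifnot(w[["log_orf_aa"]] >= 0)  # monotonicity in ORF length

score <- 1 / (1 + exp(-(w[1] + X %*% w[-1])))
cat(sprintf("coding sensitivity: %.3f\n", mean(score[y == 1] >= 0.5)))
cat(sprintf("noncoding specificity: %.3f\n", mean(score[y == 0] < 0.5)))
cat("weights:\n")
cat(sprintf("  c(intercept = %.4f, log_orf_aa = %.4f,\n    orf_coverage = %.4f, codon_llr = %.4f)\n",
            w[1], w[2], w[3], w[4]))
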