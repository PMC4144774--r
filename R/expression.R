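# Differential expression between two single-library conditions.
#
# FPKM normalisation within each library, the classical Audic–Claverie
# two-library read-count test for the P-value, the log2 FPKM ratio, and the
# drought-responsive call (|log2 ratio| strictly greater than 1 and P
# strictly below 0.001 by default).  The test's conditional distribution,
#   p(k | x) = (N2/N1)^k * (x+k)! / (x! k!) * (1 + N2/N1)^-(x+k+1),
# sums to one over k, so the upper tail is computed as the complement of the
# finite lower sum; everything is evaluated in log space.

#' Fragments per kilobase per million mapped fragments
#'
#' @param count fragment count at the locus.
#' @param length_bp spliced locus length in bp (> 0).
#' @param total_fragments total mapped fragments in the library (> 0).
#' @return `count / ((length_bp/1000) * (total_fragments/1e6))`.
#' @export
fpkm <- function(count, length_bp, total_fragments) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(total_fragments <= 0)) stop("total_fragments must be positive")
  count / ((length_bp / 1000) * (total_fragments / 1e6))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Kahan-compensated sum
sum_kahan <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Two-library read-count P-value (Audic–Claverie)
#'
#' Conditional on observing `x` reads in the first library (total `N1`), the
#' count in the second library (total `N2`) follows
#' `p(k|x) = (N2/N1)^k (x+k)!/(x! k!) (1+N2/N1)^-(x+k+1)`.  The two-sided
#' P-value is the smaller of the lower tail `sum_{k<=y} p(k|x)` and the upper
#' tail `sum_{k>=y} p(k|x)`; the upper tail is evaluated as
#' `1 - sum_{k<=y-1} p(k|x)` using the normalisation of the distribution.
#' Terms are computed in log space (log-gamma) with compensated summation.
#'
#' @param x,y non-negative integer read counts (CL, DL).
#' @param N1,N2 positive library totals (CL, DL).
#' @return P-value in (0, 1].  For `x = y = 0` with `N1 = N2` this is exactly
#'   0.5.
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  if (length(x) > 1L || length(y) > 1L) {
    return(mapply(ac_pvalue, x, y, MoreArgs = list(N1 = N1, N2 = N2)))
  }
  t <- ac_tails(x, y, N1, N2)
  min(t[["lower"]], t[["upper"]])
}

# both tail sums of p(k|x); the upper tail falls back from the complement of
# the finite lower sum to direct log-space summation when the complement
# would cancel catastrophically
ac_tails <- function(x, y, N1, N2) {
  if (x != round(x) || y != round(y) || x < 0 || y < 0) {
    stop("x and y must be non-negative integers")
  }
  stopifnot(N1 > 0, N2 > 0)
  r <- N2 / N1
  lr <- log(r); l1r <- log1p(r)
  logterm <- function(k) {
    k * lr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * l1r
  }
  lt <- logterm(0:y)
  lower <- min(1, exp(logsumexp(lt)))
  if (y == 0L) {
    upper <- 1
  } else {
    upper <- 1 - sum_kahan(sort(exp(lt[-length(lt)])))
    if (upper < 1e-4) {
      # sum k = y, y+1, ... in log space until terms are negligible
      acc <- -Inf
      k0 <- y
      block <- 256L
      repeat {
        lts <- logterm(k0:(k0 + block - 1L))
        acc <- logsumexp(c(acc, lts))
        if (lts[block] < acc - 60 || k0 > y + 1e7) break
        k0 <- k0 + block
      }
      upper <- exp(acc)
    }
  }
  c(lower = lower, upper = min(1, upper))
}

#' Log2 expression ratio (DL over CL)
#'
#' @param fpkm_dl,fpkm_cl non-negative FPKM values.
#' @return `log2(fpkm_dl / fpkm_cl)`; `+Inf` when only CL is zero, `-Inf`
#'   when only DL is zero, `NA` for 0/0 (excluded from DE calling and
#'   reported as missing).
#' @export
log2_ratio <- function(fpkm_dl, fpkm_cl) {
  out <- ifelse(fpkm_dl == 0 & fpkm_cl == 0, NA_real_,
                log2(fpkm_dl / fpkm_cl))
  out
}

#' Differential-expression configuration
#'
#' @param min_abs_log2 magnitude threshold on the log2 ratio, exclusive
#'   (default 1: a ratio of exactly 1 is not called).
#' @param alpha P-value threshold, exclusive (default 0.001).
#' @return list of class `de_config`.
#' @export
de_config <- function(min_abs_log2 = 1, alpha = 0.001) {
  stopifnot(min_abs_log2 > 0, alpha > 0)
  structure(list(min_abs_log2 = min_abs_log2, alpha = alpha),
            class = "de_config")
}

#' Call a locus drought-responsive
#'
#' `up` iff `log2_ratio > min_abs_log2` and `p < alpha` (both strict);
#' `down` iff `log2_ratio < -min_abs_log2` and `p < alpha`; otherwise
#' `none`.  Infinite ratios satisfy the magnitude condition; `NA` ratios
#' (0/0) are never called.
#'
#' @param log2_ratio log2 FPKM ratio (may be `+-Inf` or `NA`).
#' @param p_value Audic–Claverie P-value.
#' @param config a [de_config()].
#' @return one of `"none"`, `"up"`, `"down"` (vectorised).
#' @export
call_responsive <- function(log2_ratio, p_value, config = de_config()) {
  out <- rep("none", length(log2_ratio))
  sig <- !is.na(log2_ratio) & p_value < config$alpha
  out[sig & log2_ratio > config$min_abs_log2] <- "up"
  out[sig & log2_ratio < -config$min_abs_log2] <- "down"
  out
}

#' Count fragments overlapping locus exons
#'
#' A fragment (mate pair) is counted once per locus when either mate overlaps
#' the locus's exons by at least 1 bp.
#'
#' @param exons a `GRangesList` of locus exon sets (named by locus id).
#' @param aln alignment `data.table`.
#' @return named integer vector of fragment counts per locus.
#' @export
count_fragments <- function(exons, aln) {
  counts <- setNames(integer(length(exons)), names(exons))
  if (!length(exons) || !nrow(aln)) return(counts)
  reads <- alignments_as_granges(aln)
  flat <- unlist(exons, use.names = FALSE)
  locus_of <- rep(seq_along(exons), lengths(exons))
  hits <- findOverlaps(reads, flat, ignore.strand = TRUE)
  dt <- unique(data.table(read_id = mcols(reads)$read_id[queryHits(hits)],
                          locus = locus_of[subjectHits(hits)]))
  tab <- dt[, list(n = .N), by = "locus"]
  counts[tab$locus] <- tab$n
  counts
}

#' Expression and differential-expression table
#'
#' Per locus: raw fragment counts in the two libraries, FPKMs, log2 FPKM
#' ratio, the two-library P-value on the raw counts, and the responsive
#' call.  No multiple-testing correction is applied by default; set
#' `adjust = TRUE` to append a Benjamini–Hochberg column (`padj`) as an
#' extension.
#'
#' @param loci a `data.table` with `locus_id` and `spliced_length`.
#' @param exons `GRangesList` of locus exons (named by locus id).
#' @param cl_aln,dl_aln alignment `data.table`s.
#' @param N1,N2 library totals (default: mapped fragments in each alignment
#'   set).
#' @param config a [de_config()].
#' @param adjust append a BH-adjusted P-value column (off by default).
#' @return A `data.table` of expression records: `locus_id, x, y, N1, N2, L,
#'   fpkm_cl, fpkm_dl, log2_ratio, p_value, responsive`.
#' @export
expression_table <- function(loci, exons, cl_aln, dl_aln,
                             N1 = NULL, N2 = NULL, config = de_config(),
                             adjust = FALSE) {
  if (is.null(N1)) N1 <- length(unique(cl_aln$read_id[cl_aln$mapped]))
  if (is.null(N2)) N2 <- length(unique(dl_aln$read_id[dl_aln$mapped]))
  x <- count_fragments(exons, cl_aln)[loci$locus_id]
  y <- count_fragments(exons, dl_aln)[loci$locus_id]
  out <- data.table(locus_id = loci$locus_id,
                    x = as.integer(x), y = as.integer(y),
                    N1 = N1, N2 = N2, L = loci$spliced_length)
  out[, fpkm_cl := fpkm(x, L, N1)]
  out[, fpkm_dl := fpkm(y, L, N2)]
  out[, log2_ratio := log2_ratio(fpkm_dl, fpkm_cl)]
  out[, p_value := ac_pvalue(x, y, N1 = N1[1], N2 = N2[1])]
  out[, responsive := call_responsive(log2_ratio, p_value, config)]
  if (adjust) out[, padj := stats::p.adjust(p_value, method = "BH")]
  out[]
}
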