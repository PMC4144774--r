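# Independent brute-force oracles.  Each is written from the definition of
# the quantity it checks and shares no code with the implementation path.

random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# every ATG in all six frames, walked codon by codon
oracle_longest_orf <- function(s) {
  best <- 0L
  for (seq in c(s, oracle_revcomp(s))) {
    v <- strsplit(seq, "")[[1]]
    n <- length(v)
    for (i in seq_len(max(0L, n - 2L))) {
      if (v[i] == "A" && v[i + 1] == "T" && v[i + 2] == "G") {
        len <- 0L
        j <- i
        while (j + 2L <= n) {
          codon <- paste(v[j:(j + 2L)], collapse = "")
          if (codon %in% c("TAA", "TAG", "TGA")) break
          len <- len + 1L
          j <- j + 3L
        }
        best <- max(best, len)
      }
    }
  }
  best
}

kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c; t <- s + y; c <- (t - s) - y; s <- t
  }
  s
}

# direct summation of p(k|x) terms by exact ratio recursion, both tails
# summed directly (the upper tail to convergence), Kahan-compensated
oracle_ac_pvalue <- function(x, y, N1, N2) {
  r <- N2 / N1
  q <- r / (1 + r)
  t <- (1 + r)^(-(x + 1))
  lower_terms <- numeric(y + 1)
  k <- 0
  while (k <= y) {
    lower_terms[k + 1] <- t
    t <- t * (x + k + 1) / (k + 1) * q
    k <- k + 1
  }
  # t now holds the term at k = y + 1; sum the upper tail from k = y on
  upper_terms <- lower_terms[y + 1]
  while (t > .Machine$double.xmin && t / max(upper_terms) > 1e-25) {
    upper_terms <- c(upper_terms, t)
    t <- t * (x + k + 1) / (k + 1) * q
    k <- k + 1
  }
  min(kahan_sum(lower_terms), kahan_sum(upper_terms))
}

# per-base membership count over a small scaffold
oracle_coverage <- function(starts, ends, len) {
  depth <- integer(len)
  for (i in seq_along(starts)) {
    depth[starts[i]:ends[i]] <- depth[starts[i]:ends[i]] + 1L
  }
  depth
}

# maximal runs of depth >= min_depth by linear scan
oracle_tars <- function(depth, min_depth) {
  keep <- depth >= min_depth
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cbind(start = starts[runs$values], end = ends[runs$values])
}

# union-find connected components over TAR indices given linking pairs
oracle_components <- function(n, pairs) {
  # plain iterative union-find (no path tricks)
  parent <- seq_len(n)
  if (nrow(pairs)) {
    for (e in seq_len(nrow(pairs))) {
      a <- parent[pairs[e, 1]]
      while (parent[a] != a) a <- parent[a]
      b <- parent[pairs[e, 2]]
      while (parent[b] != b) b <- parent[b]
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }, integer(1))
}

# minimum distance (bases strictly between) from [s, e] to any gene boundary
oracle_min_gene_distance <- function(s, e, gene_starts, gene_ends) {
  if (!length(gene_starts)) return(Inf)
  d <- numeric(length(gene_starts))
  for (i in seq_along(gene_starts)) {
    if (e < gene_starts[i]) d[i] <- gene_starts[i] - e - 1L
    else if (s > gene_ends[i]) d[i] <- s - gene_ends[i] - 1L
    else d[i] <- 0L
  }
  min(d)
}

# pairing class of one miRNA base (DNA alphabet, T = U) vs one window base
oracle_pair_class <- function(mb, wb) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (!is.na(comp[mb]) && identical(unname(comp[mb]), wb)) return("wc")
  if ((mb == "G" && wb == "T") || (mb == "T" && wb == "G")) return("gu")
  "mm"
}

# exhaustive all-window target enumeration; coordinates on the sense strand
oracle_scan_targets <- function(mirna, linc, limit) {
  mc <- strsplit(mirna, "")[[1]]
  m <- length(mc)
  L <- nchar(linc)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  comp_m <- unname(comp[mc])
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") linc else oracle_revcomp(linc)
    sv <- strsplit(s, "")[[1]]
    for (i in seq_len(L - m + 1L)) {
      wv <- sv[i + m - seq_len(m)]       # window base opposite miRNA pos j
      wc <- wv == comp_m
      gu <- !wc & ((mc == "G" & wv == "T") | (mc == "T" & wv == "G"))
      mm <- sum(!wc & !gu); gu <- sum(gu)
      if (mm + gu <= limit) {
        st <- i; en <- i + m - 1L
        if (strand == "-") { st <- L - en + 1L; en <- L - (i) + 1L }
        hits[[length(hits) + 1L]] <-
          data.frame(strand = strand, start = st, end = en,
                     mismatches = mm, gu_pairs = gu)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      gu_pairs = integer(0)))
  }
  do.call(rbind, hits)
}

# exhaustive window x bulge-placement mimic enumeration, with target-overlap
# suppression computed from the oracle's own target list
oracle_scan_mimics <- function(mirna, linc, rules) {
  mc <- strsplit(mirna, "")[[1]]
  m <- length(mc)
  b <- rules$mimic_bulge_length
  w <- m + b
  L <- nchar(linc)
  seed <- seq(rules$mimic_seed_range[1], rules$mimic_seed_range[2])
  ps <- seq(rules$mimic_bulge_positions[1], rules$mimic_bulge_positions[2] - 1L)
  targets <- oracle_scan_targets(mirna, linc, rules$max_mismatch_plus_gu)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  comp_m <- unname(comp[mc])
  in_seed <- seq_len(m) %in% seed
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") linc else oracle_revcomp(linc)
    sv <- strsplit(s, "")[[1]]
    if (L < w) next
    for (i in seq_len(L - w + 1L)) {
      for (p in ps) {
        wpos <- ifelse(seq_len(m) <= p, w + 1L - seq_len(m),
                       w + 1L - seq_len(m) - b)
        wv <- sv[i + wpos - 1L]
        wc <- wv == comp_m
        ok_seed <- all(wc[in_seed])
        budget <- sum(!wc[!in_seed])
        if (ok_seed && budget <= rules$mimic_max_other_mm_gu) {
          st <- i; en <- i + w - 1L
          bl <- i + (w - p - b)            # local bulge start
          if (strand == "-") {
            st2 <- L - en + 1L; en2 <- L - i + 1L
            bl <- L - (bl + b - 1L) + 1L
            st <- st2; en <- en2
          }
          hits[[length(hits) + 1L]] <-
            data.frame(strand = strand, start = st, end = en,
                       bulge_start = bl)
        }
      }
    }
  }
  out <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(strand = character(0), start = integer(0), end = integer(0),
               bulge_start = integer(0))
  if (nrow(out) && nrow(targets)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      !any(targets$strand == out$strand[i] &
             targets$start <= out$end[i] & targets$end >= out$start[i])
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out
}

# ungapped Smith–Waterman via pairwiseAlignment with prohibitive gap costs
oracle_sw_flag <- function(query, library, min_identity, min_length) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  best <- list(identity = 0, length = 0, score = -Inf)
  for (q in c(query, oracle_revcomp(query))) {
    for (s in library) {
      al <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 1e6, gapExtension = 1e6)
      len <- Biostrings::nchar(Biostrings::alignedPattern(al))
      nm <- Biostrings::nmatch(al)
      if (Biostrings::score(al) > best$score) {
        best <- list(identity = nm / len, length = len,
                     score = Biostrings::score(al))
      }
    }
  }
  best$identity >= min_identity && best$length >= min_length
}
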