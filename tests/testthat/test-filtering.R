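test_that("longest ORF follows the ATG-to-stop convention", {
  expect_equal(longest_orf("ATGAAATAA"), 2L)          # Met-Lys, stop excluded
  expect_equal(longest_orf("AAAAAAAAA"), 0L)          # no ATG on either strand
  expect_equal(longest_orf("ATGAAAAAA"), 3L)          # partial ORF, no stop
  expect_equal(longest_orf(""), 0L)
  # ORF on the reverse strand only: revcomp of ATGAAATAA
  expect_equal(longest_orf("TTATTTCAT"), 2L)
  expect_equal(longest_orf("TTATTTCAT", both_strands = FALSE), 0L)
  # N never completes an ATG or stop codon
  expect_equal(longest_orf("ATGAANTAA"), 2L)
})

test_that("longest ORF equals six-frame brute force on random sequences", {
  set.seed(606)
  for (rep in 1:200) {
    s <- random_dna(sample(60:600, 1), gc = runif(1, 0.3, 0.6))
    expect_equal(longest_orf(s), oracle_longest_orf(s))
  }
})

test_that("longest_orf_info returns the ORF sequence it measured", {
  set.seed(607)
  for (rep in 1:50) {
    s <- random_dna(500)
    info <- longest_orf_info(s)
    expect_equal(info$aa, oracle_longest_orf(s))
    if (info$aa > 0) {
      expect_equal(nchar(info$orf_seq), 3L * info$aa)
      expect_equal(substr(info$orf_seq, 1, 3), "ATG")
    }
  }
})

test_that("library intersection merges overlapping TUs and drops singletons", {
  genome <- Biostrings::DNAStringSet(c(s = random_dna(2000)))
  cl <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("s", IRanges::IRanges(100, 400)),
    GenomicRanges::GRanges("s", IRanges::IRanges(1200, 1500)))
  dl <- GenomicRanges::GRangesList(
    GenomicRanges::GRanges("s", IRanges::IRanges(350, 700)))
  merged <- merge_library_tus(cl, dl, genome)
  expect_equal(nrow(merged$loci), 2L)
  both <- merged$loci[merged$loci$present_in == "CL,DL"]
  expect_equal(both$start, 100L)
  expect_equal(both$end, 700L)
  cl_only <- merged$loci[merged$loci$present_in == "CL"]
  expect_equal(cl_only$start, 1200L)
})

test_that("merged loci equal brute-force interval-graph components", {
  set.seed(707)
  genome <- Biostrings::DNAStringSet(c(s = random_dna(10000)))
  for (rep in 1:10) {
    mk <- function(n) {
      st <- sample(9000L, n)
      GenomicRanges::GRangesList(lapply(st, function(s0)
        GenomicRanges::GRanges("s", IRanges::IRanges(s0, s0 + sample(100:800, 1)))))
    }
    cl <- mk(sample(2:6, 1)); dl <- mk(sample(2:6, 1))
    merged <- merge_library_tus(cl, dl, genome)
    spans <- c(unlist(range(cl)), unlist(range(dl)))
    n <- length(spans)
    prs <- which(outer(seq_len(n), seq_len(n), function(i, j) {
      GenomicRanges::start(spans)[i] <= GenomicRanges::end(spans)[j] &
        GenomicRanges::start(spans)[j] <= GenomicRanges::end(spans)[i] & i < j
    }), arr.ind = TRUE)
    comp <- oracle_components(n, prs)
    expect_equal(nrow(merged$loci), length(unique(comp)))
  }
})

test_that("length and ORF filters are strict at their thresholds", {
  genome <- Biostrings::DNAStringSet(c(s = random_dna(5000)))
  loci <- data.table::data.table(
    locus_id = c("l1", "l2", "l3"),
    scaffold = "s", start = c(1L, 300L, 700L),
    end = c(200L, 500L, 1100L), n_exons = 1L,
    present_in = "CL,DL",
    seq = c(strrep("A", 200), strrep("A", 201),
            paste0("ATG", strrep("GCT", 99), "TAA")),  # exactly 100 AA
    spliced_length = c(200L, 201L, 303L))
  cand <- filter_candidates(list(loci = loci, exons = NULL))
  expect_equal(cand$pass_length, c(FALSE, TRUE, TRUE))  # 200 fails, 201 passes
  expect_equal(cand$longest_orf_aa[3], 100L)
  expect_false(cand$pass_orf[3])                        # 100 AA fails
  # 99 AA passes
  loci99 <- data.table::copy(loci[3])
  loci99[, seq := paste0("ATG", strrep("GCT", 98), "TAA")]
  loci99[, spliced_length := nchar(seq)]
  cand99 <- filter_candidates(list(loci = loci99, exons = NULL))
  expect_equal(cand99$longest_orf_aa, 99L)
  expect_true(cand99$pass_orf)
})

test_that("similarity scanner flags exact copies but not short matches", {
  set.seed(808)
  lib <- c(rep1 = random_dna(600))
  copy60 <- paste0(random_dna(150), substr(lib[[1]], 100, 159),
                   random_dna(150))
  short20 <- paste0(random_dna(150), substr(lib[[1]], 100, 119),
                    random_dna(150))
  hits <- exclude_by_similarity(c(a = copy60, b = short20), lib)
  expect_true(hits$flagged[hits$query == "a"])
  expect_false(hits$flagged[hits$query == "b"])
  # the best alignment may extend a few lucky bases past the planted copy,
  # so identity is near-perfect over at least the copy length
  expect_gte(hits$identity[hits$query == "a"], 0.95)
  expect_gte(hits$aln_length[hits$query == "a"], 60L)
})

test_that("empty similarity library warns and flags nothing", {
  expect_warning(h <- exclude_by_similarity(c(a = random_dna(100)),
                                            character(0)), "empty")
  expect_false(any(h$flagged))
})

test_that("similarity flags agree with a Smith-Waterman oracle on mutated copies", {
  set.seed(909)
  cfg <- filter_config()
  lib <- c(rep1 = random_dna(800), rep2 = random_dna(600))
  mutate_copy <- function(rate) {
    src <- lib[[sample(2, 1)]]
    frag <- substr(src, 200, 200 + sample(80:200, 1))
    v <- strsplit(frag, "")[[1]]
    mut <- which(runif(length(v)) < rate)
    for (i in mut) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    frag <- paste(v, collapse = "")
    if (runif(1) < 0.5) frag <- oracle_revcomp(frag)
    c(q = paste0(random_dna(100), frag, random_dna(100)))
  }
  # decision-clear instances: lightly mutated copies and copy-free sequences
  for (rate in c(0, 0.05, 0.10)) {
    for (rep in 1:4) {
      cand <- mutate_copy(rate)
      got <- exclude_by_similarity(cand, lib, cfg)$flagged
      want <- oracle_sw_flag(cand[[1]], lib, cfg$similarity_min_identity,
                             cfg$similarity_min_length_bp)
      expect_equal(got, want, info = sprintf("rate=%.2f rep=%d", rate, rep))
    }
  }
  for (rep in 1:6) {
    cand <- c(q = random_dna(400))
    got <- exclude_by_similarity(cand, lib, cfg)$flagged
    want <- oracle_sw_flag(cand[[1]], lib, cfg$similarity_min_identity,
                           cfg$similarity_min_length_bp)
    expect_equal(got, want, info = sprintf("no-copy rep=%d", rep))
  }
  # near the identity boundary the heuristic and the optimum may legitimately
  # pick different segments; the optimum always bounds the heuristic's score
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (rate in c(0.25, 0.30)) {
    for (rep in 1:3) {
      cand <- mutate_copy(rate)
      h <- exclude_by_similarity(cand, lib, cfg)
      if (is.na(h$score)) next
      sw_best <- max(vapply(c(cand[[1]], oracle_revcomp(cand[[1]])),
                            function(q) max(vapply(lib, function(s)
                              Biostrings::score(Biostrings::pairwiseAlignment(
                                q, s, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 1e6, gapExtension = 1e6)),
                              numeric(1))), numeric(1)))
      expect_gte(sw_best, h$score)
    }
  }
})

test_that("the filter cascade is order-independent pure predicates", {
  st <- tiny_study(seed = 31L, fragments = 2e4)
  cl <- assemble_library(st$sim$alignments$CL, st$gen$genes,
                         st$planted$genome, "CL")
  dl <- assemble_library(st$sim$alignments$DL, st$gen$genes,
                         st$planted$genome, "DL")
  merged <- merge_library_tus(cl[S4Vectors::mcols(cl)$intergenic],
                              dl[S4Vectors::mcols(dl)$intergenic],
                              st$planted$genome)
  cand <- filter_candidates(merged, repeats = st$repeats,
                            precursors = st$precursors)
  expect_equal(cand$passed,
               cand$pass_length & cand$pass_orf & cand$pass_both_libraries &
                 cand$pass_similarity)
})
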