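wrap_site <- function(site, left = 40, right = 40) {
  paste0(random_dna(left), site, random_dna(right))
}

test_that("an exact reverse-complement window is a perfect target hit", {
  set.seed(1313)
  m <- random_dna(21, gc = 0.5)
  linc <- wrap_site(oracle_revcomp(m))
  hits <- scan_targets(m, linc)
  perfect <- hits[hits$mismatches == 0 & hits$gu_pairs == 0]
  expect_true(nrow(perfect) >= 1)
  expect_true(any(perfect$start == 41 & perfect$end == 61 &
                    perfect$strand == "+"))
  expect_equal(perfect$pairing[perfect$start == 41][1], strrep("|", 21))
})

test_that("the combined mismatch plus G:U budget is exactly three", {
  set.seed(1414)
  # miRNA with G bases so wobbles can be planted (G pairs T instead of C)
  m <- "GGAGGCAGAGTTCAGTCGGAG"
  site <- strsplit(oracle_revcomp(m), "")[[1]]
  mc <- strsplit(m, "")[[1]]
  g_pos <- which(mc == "G")[1:4]
  make_site <- function(n_wobble) {
    s <- site
    for (j in g_pos[seq_len(n_wobble)]) s[21 + 1 - j] <- "T"
    paste(s, collapse = "")
  }
  linc3 <- wrap_site(make_site(3))
  linc4 <- wrap_site(make_site(4))
  h3 <- scan_targets(m, linc3)
  h4 <- scan_targets(m, linc4)
  expect_true(any(h3$start == 41 & h3$gu_pairs == 3 & h3$mismatches == 0))
  expect_false(any(h4$start == 41 & h4$strand == "+"))
})

test_that("a zero-budget scan equals exact string search of the reverse complement", {
  set.seed(1515)
  rules0 <- pairing_rules(max_mismatch_plus_gu = 0L)
  for (rep in 1:20) {
    m <- random_dna(21, gc = 0.5)
    linc <- wrap_site(oracle_revcomp(m), left = sample(30:100, 1))
    hits <- scan_targets(m, linc, rules0)
    plus <- hits[hits$strand == "+"]
    found <- gregexpr(oracle_revcomp(m), linc, fixed = TRUE)[[1]]
    found <- found[found > 0]
    expect_equal(sort(plus$start), sort(found))
    # on the minus strand: occurrences of the miRNA itself (T read as U)
    minus <- hits[hits$strand == "-"]
    found_m <- gregexpr(m, linc, fixed = TRUE)[[1]]
    found_m <- found_m[found_m > 0]
    expect_equal(sort(minus$start), sort(found_m))
  }
})

test_that("mimic sites require the bulge opposite the configured positions", {
  set.seed(1616)
  m <- random_dna(21, gc = 0.5)
  # bulge between pairing positions 10 and 11: a mimic
  good <- wrap_site(poplinc:::mimic_site_seq(m, p = 10L))
  h <- scan_mimics(m, good)
  expect_true(any(h$strand == "+" & h$start == 41))
  # the same insertion opposite position 15: no mimic
  bad <- wrap_site(poplinc:::mimic_site_seq(m, p = 15L))
  h_bad <- scan_mimics(m, bad)
  expect_false(any(h_bad$strand == "+" & h_bad$start == 41))
})

test_that("bulge-free perfect sites are reported as targets, not mimics", {
  set.seed(1717)
  m <- random_dna(21, gc = 0.5)
  linc <- wrap_site(oracle_revcomp(m))
  h <- scan_mimics(m, linc)
  expect_false(any(h$start <= 61 & h$end >= 41 & h$strand == "+"))
})

test_that("degenerate miRNA bases error", {
  expect_error(scan_targets("ACGTNACGTACGTACGTACGT", random_dna(100)),
               "degenerate")
})

test_that("scanning the reverse complement swaps strands, preserving hits", {
  set.seed(1818)
  for (rep in 1:10) {
    m <- random_dna(21, gc = 0.5)
    linc <- wrap_site(oracle_revcomp(m), left = sample(30:80, 1))
    h1 <- scan_targets(m, linc)
    h2 <- scan_targets(m, oracle_revcomp(linc))
    expect_equal(nrow(h1), nrow(h2))
    k1 <- sort(paste(h1$strand, h1$mismatches, h1$gu_pairs))
    k2 <- sort(paste(ifelse(h2$strand == "+", "-", "+"),
                     h2$mismatches, h2$gu_pairs))
    expect_equal(k1, k2)
  }
})

test_that("target and mimic scans equal brute-force enumeration", {
  set.seed(1919)
  rules <- pairing_rules()
  for (rep in 1:8) {
    m <- random_dna(21, gc = 0.5)
    linc <- random_dna(150, gc = runif(1, 0.35, 0.6))
    if (rep %% 2 == 0) {
      # plant a near-perfect site to exercise the hit paths
      site <- poplinc:::mimic_site_seq(m, p = sample(9:11, 1))
      substr(linc, 50, 50 + nchar(site) - 1) <- site
    }
    got_t <- scan_targets(m, linc, rules)
    want_t <- oracle_scan_targets(m, linc, rules$max_mismatch_plus_gu)
    expect_equal(nrow(got_t), nrow(want_t))
    if (nrow(got_t)) {
      expect_equal(
        sort(paste(got_t$strand, got_t$start, got_t$end,
                   got_t$mismatches, got_t$gu_pairs)),
        sort(paste(want_t$strand, want_t$start, want_t$end,
                   want_t$mismatches, want_t$gu_pairs)))
    }
    got_m <- scan_mimics(m, linc, rules)
    want_m <- oracle_scan_mimics(m, linc, rules)
    expect_equal(nrow(got_m), nrow(want_m))
    if (nrow(got_m)) {
      expect_equal(sort(paste(got_m$strand, got_m$start, got_m$end,
                              got_m$bulge_start)),
                   sort(paste(want_m$strand, want_m$start, want_m$end,
                              want_m$bulge_start)))
    }
  }
})

test_that("the interaction network mirrors site collections", {
  t_sites <- data.table::rbindlist(lapply(sprintf("linc%d", 1:4), function(l)
    data.table::data.table(mirna_id = "miR482", linc_id = l, kind = "target")))
  m_sites <- data.table::rbindlist(lapply(sprintf("linc%d", 5:7), function(l)
    data.table::data.table(mirna_id = "miR482", linc_id = l, kind = "mimic")))
  net <- build_interaction_network(t_sites, m_sites)
  expect_equal(net$summary$degrades, 4L)
  expect_equal(net$summary$mimicked_by, 3L)
  # a lincRNA with both roles for different miRNAs appears in two edges
  both <- build_interaction_network(
    data.table::data.table(mirna_id = "miR156", linc_id = "lincX"),
    data.table::data.table(mirna_id = "miR482", linc_id = "lincX"))
  expect_equal(nrow(both$edges), 2L)
  empty <- build_interaction_network(NULL, NULL)
  expect_equal(nrow(empty$edges), 0L)
})
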