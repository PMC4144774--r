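make_aln <- function(starts, ends, scaffold = "s",
                     read_id = sprintf("r%03d", seq_along(starts)),
                     mate = rep(1L, length(starts))) {
  data.table::data.table(read_id = read_id, mate = mate, scaffold = scaffold,
                         start = as.integer(starts), end = as.integer(ends),
                         strand = "+", mapped = TRUE)
}

test_that("coverage counts alignment blocks per base", {
  sl <- c(s = 200L)
  cov <- build_coverage(make_aln(1, 90), sl)
  expect_equal(sum(cov$s == 1), 90)
  expect_equal(sum(cov$s), 90)

  cov2 <- build_coverage(make_aln(c(1, 46), c(90, 135)), sl)
  expect_equal(as.integer(cov2$s[46:90]), rep(2L, 45))
  expect_equal(sum(cov2$s), 180)
})

test_that("out-of-bounds alignments error naming the record", {
  expect_error(build_coverage(make_aln(150, 239, read_id = "bad_read"),
                              c(s = 200L)), "bad_read")
})

test_that("coverage equals a brute-force per-base count on random read sets", {
  set.seed(101)
  for (rep in 1:10) {
    len <- 5000L
    n <- sample(50:200, 1)
    starts <- sample(len - 90L, n, replace = TRUE)
    aln <- make_aln(starts, starts + 89L)
    cov <- build_coverage(aln, c(s = len))
    expect_equal(as.integer(cov$s), oracle_coverage(starts, starts + 89L, len))
  }
})

test_that("TAR calling keeps maximal runs at or above the depth threshold", {
  cov <- IRanges::RleList(s = S4Vectors::Rle(c(3, 3, 3, 1, 3, 3)))
  tars <- call_tars(cov, min_depth = 2L)
  expect_equal(GenomicRanges::start(tars), c(1L, 5L))
  expect_equal(GenomicRanges::end(tars), c(3L, 6L))
  expect_equal(S4Vectors::mcols(tars)$min_depth, c(3, 3))

  # depth exactly 2 is kept ("less than 2" is dropped)
  cov2 <- IRanges::RleList(s = S4Vectors::Rle(rep(2, 500)))
  tars2 <- call_tars(cov2, min_depth = 2L)
  expect_equal(GenomicRanges::width(tars2), 500L)
})

test_that("TAR calling equals a run-length scan on random tracks", {
  set.seed(202)
  for (rep in 1:20) {
    depth <- sample(0:4, 300, replace = TRUE)
    tars <- call_tars(IRanges::RleList(s = S4Vectors::Rle(depth)),
                      min_depth = 2L)
    exp <- oracle_tars(depth, 2L)
    expect_equal(GenomicRanges::start(tars), unname(exp[, "start"]))
    expect_equal(GenomicRanges::end(tars), unname(exp[, "end"]))
  }
})

test_that("TAR set is invariant to alignment input order", {
  set.seed(303)
  starts <- sample(4000L, 100, replace = TRUE)
  aln <- make_aln(starts, starts + 89L)
  t1 <- call_tars(build_coverage(aln, c(s = 5000L)))
  t2 <- call_tars(build_coverage(aln[sample(nrow(aln))], c(s = 5000L)))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("mate pairs link TARs into multi-exon models", {
  # two TARs joined by one spanning pair
  aln <- rbind(
    make_aln(c(1, 46), c(90, 135), read_id = c("a", "b")),
    make_aln(c(301, 346), c(390, 435), read_id = c("a", "b"),
             mate = c(2L, 2L)))
  cov <- build_coverage(aln, c(s = 1000L))
  tars <- call_tars(cov, 2L)
  expect_length(tars, 2L)
  models <- link_tars(tars, aln)
  expect_length(models, 1L)
  expect_equal(S4Vectors::mcols(models)$n_exons, 2L)
  expect_equal(S4Vectors::mcols(models)$link_support, 2L)

  # no spanning pairs: each TAR its own model
  aln2 <- rbind(make_aln(c(1, 46), c(90, 135), read_id = c("a", "b")),
                make_aln(c(301, 346), c(390, 435), read_id = c("c", "d")))
  models2 <- link_tars(call_tars(build_coverage(aln2, c(s = 1000L)), 2L), aln2)
  expect_length(models2, 2L)
  expect_true(all(S4Vectors::mcols(models2)$n_exons == 1L))
})

test_that("TAR linking equals union-find components on random instances", {
  set.seed(404)
  for (rep in 1:10) {
    n_tar <- sample(4:10, 1)
    tar_starts <- seq(1L, by = 500L, length.out = n_tar)
    tars <- GenomicRanges::GRanges("s", IRanges::IRanges(tar_starts,
                                                         tar_starts + 99L))
    n_pair <- sample(0:6, 1)
    pr <- if (n_pair > 0) {
      cbind(sample(n_tar, n_pair, replace = TRUE),
            sample(n_tar, n_pair, replace = TRUE))
    } else matrix(integer(0), 0, 2)
    parts <- list()
    for (i in seq_len(nrow(pr))) {
      parts[[i]] <- make_aln(c(tar_starts[pr[i, 1]], tar_starts[pr[i, 2]]),
                             c(tar_starts[pr[i, 1]] + 50L,
                               tar_starts[pr[i, 2]] + 50L),
                             read_id = sprintf("p%d", i), mate = c(1L, 2L))
    }
    aln <- if (length(parts)) data.table::rbindlist(parts) else make_aln(1, 50)
    models <- link_tars(tars, aln)
    comp <- oracle_components(n_tar, pr[pr[, 1] != pr[, 2], , drop = FALSE])
    expect_equal(length(models), length(unique(comp)))
    # same partition: exon start sets per component agree
    got <- sort(vapply(seq_along(models), function(i)
      paste(sort(GenomicRanges::start(models[[i]])), collapse = ","),
      character(1)))
    exp <- sort(vapply(split(tar_starts, comp), function(v)
      paste(sort(v), collapse = ","), character(1)))
    expect_equal(got, unname(exp))
  }
})

test_that("intergenic classification applies the 200 bp distance rule", {
  genes <- GenomicRanges::GRanges("s", IRanges::IRanges(1000, 2000))
  S4Vectors::mcols(genes)$gene_id <- "g1"
  # model ending 199 bp before the gene (bases between = 199): not intergenic
  near <- make_tu("s", 500, 800)
  far <- make_tu("s", 500, 799)     # exactly 200 bases between
  near_c <- classify_intergenic(near, genes)
  far_c <- classify_intergenic(far, genes)
  expect_false(S4Vectors::mcols(near_c)$intergenic)
  expect_equal(S4Vectors::mcols(near_c)$distance_to_nearest_gene, 199)
  expect_true(S4Vectors::mcols(far_c)$intergenic)
  expect_equal(S4Vectors::mcols(far_c)$distance_to_nearest_gene, 200)
  # overlap is always excluded
  ov <- classify_intergenic(make_tu("s", 1500, 1600), genes)
  expect_false(S4Vectors::mcols(ov)$intergenic)
})

test_that("gene distance equals the brute-force minimum on random layouts", {
  set.seed(505)
  for (rep in 1:20) {
    n_genes <- sample(1:5, 1)
    gs <- sort(sample(9000L, n_genes))
    genes <- GenomicRanges::GRanges("s", IRanges::IRanges(gs, gs + 199L))
    S4Vectors::mcols(genes)$gene_id <- paste0("g", seq_len(n_genes))
    ms <- sample(9500L, 1); me <- ms + sample(100:400, 1)
    mod <- classify_intergenic(make_tu("s", ms, me), genes)
    d_oracle <- oracle_min_gene_distance(ms, me, gs, gs + 199L)
    expect_equal(S4Vectors::mcols(mod)$distance_to_nearest_gene, d_oracle)
    expect_equal(S4Vectors::mcols(mod)$intergenic, d_oracle >= 200)
  }
})

test_that("a model on a scaffold absent from the genome errors", {
  genes <- GenomicRanges::GRanges("s", IRanges::IRanges(10, 20))
  S4Vectors::mcols(genes)$gene_id <- "g"
  genome <- Biostrings::DNAStringSet(c(s = "ACGTACGTACGTACGTACGTACGT"))
  expect_error(classify_intergenic(make_tu("other", 1, 10), genes, genome),
               "absent")
})

test_that("TU spliced sequence concatenates exon sequences in order", {
  genome <- Biostrings::DNAStringSet(c(s = paste(rep("ACGTA", 40),
                                                 collapse = "")))
  genes <- GenomicRanges::GRanges("s", IRanges::IRanges(190, 200))
  S4Vectors::mcols(genes)$gene_id <- "g"
  tu <- GenomicRanges::GRangesList(GenomicRanges::GRanges(
    "s", IRanges::IRanges(c(1, 11), c(5, 15))))
  out <- classify_intergenic(tu, genes, genome)
  s <- as.character(genome)[[1]]
  expect_equal(S4Vectors::mcols(out)$spliced_sequence,
               paste0(substr(s, 1, 5), substr(s, 11, 15)))
  expect_equal(S4Vectors::mcols(out)$spliced_length, 10L)
})
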