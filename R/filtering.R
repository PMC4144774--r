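# The four-filter lincRNA candidate cascade:
#   1. spliced length strictly greater than min_length_bp (default 200);
#   2. longest ORF over both strands strictly smaller than max_orf_aa
#      (default 100);
#   3. the locus must appear in both libraries (CL and DL);
#   4. no high similarity to the repeat or miRNA-precursor library
#      (seed-and-extend local alignment; flagged at >= 80% identity over
#      >= 50 bp by default).
# Each filter is a pure predicate; the trace records all four outcomes and a
# candidate passes iff every filter passes.

#' Filter configuration
#'
#' @param min_length_bp minimum spliced length, exclusive (default 200:
#'   length 201 passes, 200 fails).
#' @param max_orf_aa maximum longest-ORF length, exclusive (default 100:
#'   99 AA passes, 100 fails).
#' @param similarity_min_identity,similarity_min_length_bp similarity-flag
#'   thresholds.
#' @param seed_kmer exact seed length of the similarity scanner.
#' @param match,mismatch,xdrop ungapped extension scoring.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_length_bp = 200L, max_orf_aa = 100L,
                          similarity_min_identity = 0.80,
                          similarity_min_length_bp = 50L,
                          seed_kmer = 11L, match = 1, mismatch = -2,
                          xdrop = 10) {
  stopifnot(min_length_bp > 0, max_orf_aa > 0,
            similarity_min_identity > 0, similarity_min_length_bp > 0)
  structure(list(min_length_bp = min_length_bp, max_orf_aa = max_orf_aa,
                 similarity_min_identity = similarity_min_identity,
                 similarity_min_length_bp = similarity_min_length_bp,
                 seed_kmer = seed_kmer, match = match, mismatch = mismatch,
                 xdrop = xdrop),
            class = "filter_config")
}

#' Merge transcription units across libraries into loci
#'
#' TUs from the two libraries are clustered by genomic overlap (>= 1 bp on
#' the same scaffold, transitively); each cluster becomes one locus whose
#' exon structure is the union (reduction) of member exons and whose
#' `present_in` records the libraries it appeared in.
#'
#' @param cl_tus,dl_tus `GRangesList`s of intergenic TUs from
#'   [assemble_library()] (CL and DL).
#' @param genome genome `DNAStringSet` for spliced-sequence extraction.
#' @return A list: `loci` (a `data.table` with `locus_id`, coordinates,
#'   `n_exons`, `spliced_length`, `present_in`, `seq`) and `exons` (a
#'   `GRangesList` named by locus id).
#' @export
merge_library_tus <- function(cl_tus, dl_tus, genome) {
  spans <- c(unlist(range(cl_tus)), unlist(range(dl_tus)))
  libs <- c(rep("CL", length(cl_tus)), rep("DL", length(dl_tus)))
  all_exons <- c(unlist(cl_tus, use.names = FALSE),
                 unlist(dl_tus, use.names = FALSE))
  exon_of <- rep(seq_along(spans), c(lengths(cl_tus), lengths(dl_tus)))
  if (!length(spans)) {
    return(list(loci = data.table(locus_id = character(0)),
                exons = GRangesList()))
  }
  ov <- findOverlaps(spans, ignore.strand = TRUE, drop.self = TRUE,
                     drop.redundant = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(queryHits(ov)),
               to = as.character(subjectHits(ov))),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_along(spans))))
  memb <- igraph::components(g)$membership[as.character(seq_along(spans))]

  scstr <- as.character(genome)
  parts <- lapply(split(seq_along(spans), memb), function(idx) {
    ex <- reduce(granges(all_exons[exon_of %in% idx]), ignore.strand = TRUE)
    sc <- as.character(seqnames(ex))[1]
    seqs <- substring(scstr[[sc]], start(ex), end(ex))
    list(exons = ex, scaffold = sc, start = min(start(ex)), end = max(end(ex)),
         present_in = paste(sort(unique(libs[idx])), collapse = ","),
         seq = paste(seqs, collapse = ""))
  })
  ord <- order(vapply(parts, `[[`, character(1), "scaffold"),
               vapply(parts, `[[`, numeric(1), "start"))
  parts <- parts[ord]
  ids <- sprintf("locus%04d", seq_along(parts))
  loci <- data.table(
    locus_id = ids,
    scaffold = vapply(parts, `[[`, character(1), "scaffold"),
    start = as.integer(vapply(parts, `[[`, numeric(1), "start")),
    end = as.integer(vapply(parts, `[[`, numeric(1), "end")),
    n_exons = vapply(parts, function(p) length(p$exons), integer(1)),
    present_in = vapply(parts, `[[`, character(1), "present_in"),
    seq = vapply(parts, `[[`, character(1), "seq"))
  loci[, spliced_length := nchar(seq)]
  exons <- GRangesList(lapply(parts, `[[`, "exons"))
  names(exons) <- ids
  list(loci = loci, exons = exons)
}

# ungapped X-drop extension along one diagonal; returns best segment
extend_diagonal <- function(qa, sa, qpos, spos, k, match, mismatch, xdrop) {
  nq <- length(qa); ns <- length(sa)
  d <- spos - qpos
  i0 <- max(1L, 1L - d); i1 <- min(nq, ns - d)
  m <- qa[i0:i1] == sa[(i0:i1) + d]
  step <- ifelse(m, match, mismatch)
  seed_a <- qpos - i0 + 1L              # seed start, local index
  seed_b <- seed_a + k - 1L
  extend <- function(v) {               # v: steps outward from the seed
    if (!length(v)) return(list(len = 0L, score = 0, matches = 0L))
    sc <- cumsum(v)
    run <- cummax(sc)
    stop_at <- which(run - sc > xdrop)[1]
    lim <- if (is.na(stop_at)) length(sc) else stop_at - 1L
    if (lim < 1L) return(list(len = 0L, score = 0, matches = 0L))
    best <- which.max(sc[seq_len(lim)])
    if (sc[best] <= 0) return(list(len = 0L, score = 0, matches = 0L))
    list(len = best, score = sc[best],
         matches = sum(v[seq_len(best)] == match))
  }
  r <- extend(if (seed_b < length(m)) step[(seed_b + 1L):length(m)] else numeric(0))
  l <- extend(if (seed_a > 1L) rev(step[1:(seed_a - 1L)]) else numeric(0))
  len <- k + r$len + l$len
  list(score = k * match + r$score + l$score,
       length = len,
       matches = k + r$matches + l$matches,
       q_start = qpos - l$len, q_end = qpos + k - 1L + r$len)
}

#' Scan candidate sequences against a sequence library
#'
#' Seed-and-extend local alignment: exact k-mer seeds (default k = 11),
#' ungapped extension with match +1 / mismatch -2 and X-drop 10, both
#' strands of the candidate.  A candidate is flagged when its best local
#' alignment reaches `similarity_min_identity` over at least
#' `similarity_min_length_bp`.
#'
#' @param seqs named character vector of candidate sequences.
#' @param library named character vector of library sequences (repeats or
#'   miRNA precursors); empty gives no hits with a warning.
#' @param config a [filter_config()].
#' @return A `data.table`, one row per candidate: best `subject`, `identity`,
#'   `aln_length`, `score`, `strand`, and the `flagged` decision.
#' @export
exclude_by_similarity <- function(seqs, library, config = filter_config()) {
  empty <- data.table(query = names(seqs), subject = NA_character_,
                      identity = NA_real_, aln_length = NA_integer_,
                      score = NA_real_, strand = NA_character_,
                      flagged = FALSE)
  if (!length(library)) {
    warning("empty similarity library: no hits")
    return(empty)
  }
  k <- config$seed_kmer
  lib_chars <- lapply(library, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  lib_kmers <- lapply(library, function(s) {
    n <- nchar(s)
    if (n < k) return(data.table(kmer = character(0), spos = integer(0)))
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
               spos = 1:(n - k + 1L))
  })
  out <- empty
  for (qi in seq_along(seqs)) {
    best <- NULL
    for (strand in c("+", "-")) {
      q <- if (strand == "+") seqs[[qi]] else revcomp(seqs[[qi]])
      nq <- nchar(q)
      if (nq < k) next
      qa <- strsplit(q, "", fixed = TRUE)[[1]]
      qk <- data.table(kmer = substring(q, 1:(nq - k + 1L), k:nq),
                       qpos = 1:(nq - k + 1L))
      for (si in seq_along(library)) {
        seeds <- merge(qk, lib_kmers[[si]], by = "kmer",
                       allow.cartesian = TRUE)
        if (!nrow(seeds)) next
        seeds[, diag := spos - qpos]
        seeds <- seeds[, .SD[which.min(qpos)], by = "diag"]
        for (r in seq_len(nrow(seeds))) {
          h <- extend_diagonal(qa, lib_chars[[si]], seeds$qpos[r],
                               seeds$spos[r], k, config$match,
                               config$mismatch, config$xdrop)
          if (is.null(best) || h$score > best$score) {
            best <- c(h, list(subject = names(library)[si], strand = strand))
          }
        }
      }
    }
    if (!is.null(best)) {
      set(out, qi, c("subject", "identity", "aln_length", "score", "strand"),
          list(best$subject, best$matches / best$length,
               as.integer(best$length), best$score, best$strand))
      set(out, qi, "flagged",
          best$matches / best$length >= config$similarity_min_identity &&
            best$length >= config$similarity_min_length_bp)
    }
  }
  out
}

#' Apply the four-filter cascade to merged loci
#'
#' @param merged output of [merge_library_tus()].
#' @param config a [filter_config()].
#' @param repeats,precursors named character vectors of library sequences.
#' @return The `loci` table extended with `longest_orf_aa`, the four
#'   `pass_*` trace columns (in pipeline order: length, ORF, both libraries,
#'   similarity), per-library hit columns, and `passed`.
#' @export
filter_candidates <- function(merged, config = filter_config(),
                              repeats = character(0),
                              precursors = character(0)) {
  cand <- copy(merged$loci)
  if (!nrow(cand)) return(cand)
  cand[, longest_orf_aa := vapply(seq, longest_orf, integer(1))]
  cand[, pass_length := spliced_length > config$min_length_bp]
  cand[, pass_orf := longest_orf_aa < config$max_orf_aa]
  cand[, pass_both_libraries := present_in == "CL,DL"]
  seqs <- setNames(cand$seq, cand$locus_id)
  rep_hits <- if (length(repeats)) exclude_by_similarity(seqs, repeats, config)
              else NULL
  pre_hits <- if (length(precursors)) exclude_by_similarity(seqs, precursors, config)
              else NULL
  cand[, repeat_hit := if (is.null(rep_hits)) NA_character_ else
    ifelse(rep_hits$flagged, rep_hits$subject, NA_character_)]
  cand[, repeat_identity := if (is.null(rep_hits)) NA_real_ else
    ifelse(rep_hits$flagged, rep_hits$identity, NA_real_)]
  cand[, precursor_hit := if (is.null(pre_hits)) NA_character_ else
    ifelse(pre_hits$flagged, pre_hits$subject, NA_character_)]
  cand[, precursor_identity := if (is.null(pre_hits)) NA_real_ else
    ifelse(pre_hits$flagged, pre_hits$identity, NA_real_)]
  cand[, pass_similarity := is.na(repeat_hit) & is.na(precursor_hit)]
  cand[, passed := pass_length & pass_orf & pass_both_libraries &
         pass_similarity]
  cand[]
}
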