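# Transcript assembly from read coverage.
#
# Per-base coverage -> transcription active regions (maximal runs of bases
# with depth >= min_depth; the default 2 drops bases with fewer than 2 reads
# per base pair) -> gene models (TARs connected by mate-pair evidence;
# connected components) -> transcription units classified as intergenic when
# they overlap no annotated gene and lie at least min_distance (default
# 200 bp) from the nearest gene boundary.  TARs and TUs are unstranded: the
# libraries carry no strand information, and downstream sequence analyses
# scan both strands explicitly.

#' Per-base read coverage
#'
#' Depth at a base is the number of mapped alignment blocks covering it;
#' unmapped records are ignored.
#'
#' @param aln alignment `data.table` (see [read_alignments()]).
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @return A per-scaffold `RleList` of depths.  An alignment outside scaffold
#'   bounds is an error naming the record.
#' @export
build_coverage <- function(aln, scaffold_lengths) {
  m <- aln[aln$mapped, ]
  if (nrow(m)) {
    unknown <- !(m$scaffold %in% names(scaffold_lengths))
    if (any(unknown)) {
      stop("alignment on unknown scaffold: read ", m$read_id[which(unknown)[1]])
    }
    oob <- m$start < 1L | m$end > scaffold_lengths[m$scaffold]
    if (any(oob)) {
      stop("alignment out of scaffold bounds: read ", m$read_id[which(oob)[1]])
    }
  }
  gr <- GRanges(m$scaffold, IRanges(m$start, m$end),
                seqlengths = scaffold_lengths)
  coverage(gr)
}

#' Call transcription active regions
#'
#' TARs are the maximal runs of bases with depth >= `min_depth` ("read
#' numbers per base pair of less than `min_depth` are not considered"; a base
#' at exactly the threshold is kept).
#'
#' @param cov coverage `RleList` from [build_coverage()].
#' @param min_depth minimum per-base depth (default 2).
#' @return An unstranded `GRanges` with `min_depth` and `mean_depth` metadata
#'   columns; empty coverage gives an empty set.
#' @export
call_tars <- function(cov, min_depth = 2L) {
  stopifnot(min_depth >= 1L)
  parts <- lapply(names(cov), function(sc) {
    v <- IRanges::Views(cov[[sc]],
                        IRanges::slice(cov[[sc]], lower = min_depth,
                                       rangesOnly = TRUE))
    if (!length(v)) return(GRanges())
    gr <- GRanges(sc, as(v, "IRanges"))
    mcols(gr)$min_depth <- IRanges::viewMins(v)
    mcols(gr)$mean_depth <- IRanges::viewMeans(v)
    gr
  })
  out <- suppressWarnings(do.call(c, parts))
  seqlevels(out) <- names(cov)
  out
}

# fragment spans (min start / max end over both mates) for the given read ids
fragment_spans <- function(aln, read_ids) {
  m <- aln[aln$mapped & aln$read_id %in% read_ids, ]
  sp <- m[, list(start = min(start), end = max(end),
                 scaffold = scaffold[1L]), by = "read_id"]
  GRanges(sp$scaffold, IRanges(sp$start, sp$end))
}

#' Link TARs into gene models with mate-pair evidence
#'
#' Two TARs are connected when at least `min_link` mate pairs have one mate
#' overlapping each; gene models are the connected components (transitive
#' closure).  Gaps between consecutive exons are introns; `link_support` is
#' the minimum, over introns, of the number of linking pairs spanning the
#' gap.  Singleton TARs become single-exon models.
#'
#' @param tars `GRanges` from [call_tars()].
#' @param aln alignment `data.table` resolving mate pairs by `read_id`.
#' @param min_link minimum number of linking mate pairs (default 1).
#' @param id_prefix prefix for model ids.
#' @return A `GRangesList` of exon sets, one element per model, with metadata
#'   columns `model_id`, `n_exons`, `link_support`, `mean_depth`.
#' @export
link_tars <- function(tars, aln, min_link = 1L, id_prefix = "TU") {
  if (!length(tars)) {
    out <- GRangesList()
    mcols(out) <- DataFrame(model_id = character(0), n_exons = integer(0),
                            link_support = integer(0), mean_depth = numeric(0))
    return(out)
  }
  reads <- alignments_as_granges(aln)
  hits <- findOverlaps(reads, tars, ignore.strand = TRUE)
  hdt <- data.table(read_id = mcols(reads)$read_id[queryHits(hits)],
                    mate = mcols(reads)$mate[queryHits(hits)],
                    tar = subjectHits(hits))
  hdt <- unique(hdt)
  pairs <- merge(hdt[hdt$mate == 1L, list(read_id, t1 = tar)],
                 hdt[hdt$mate == 2L, list(read_id, t2 = tar)],
                 by = "read_id", allow.cartesian = TRUE)
  pairs <- pairs[pairs$t1 != pairs$t2]
  if (nrow(pairs)) {
    a <- pmin(pairs$t1, pairs$t2); b <- pmax(pairs$t1, pairs$t2)
    edge_dt <- data.table(a = a, b = b, read_id = pairs$read_id)
    edge_n <- edge_dt[, list(n = length(unique(read_id))), by = c("a", "b")]
    edge_n <- edge_n[edge_n$n >= min_link]
    # never link across scaffolds
    same_sc <- as.character(seqnames(tars))[edge_n$a] ==
      as.character(seqnames(tars))[edge_n$b]
    edge_n <- edge_n[same_sc]
  } else {
    edge_dt <- data.table(a = integer(0), b = integer(0),
                          read_id = character(0))
    edge_n <- data.table(a = integer(0), b = integer(0), n = integer(0))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edge_n$a), to = as.character(edge_n$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_along(tars))))
  memb <- igraph::components(g)$membership[as.character(seq_along(tars))]

  ord <- order(memb, as.integer(factor(as.character(seqnames(tars)))),
               start(tars))
  tars_sorted <- tars[ord]
  grl <- S4Vectors::split(tars_sorted, memb[ord])
  # order models genomically
  first <- unlist(range(grl))
  mord <- order(as.integer(factor(as.character(seqnames(first)),
                                  levels = seqlevels(tars))), start(first))
  grl <- grl[mord]
  model_id <- sprintf("%s%04d", id_prefix, seq_along(grl))
  names(grl) <- model_id

  # per-intron support from fragments linking distinct exons
  link_support <- rep(NA_integer_, length(grl))
  multi <- which(lengths(grl) > 1L)
  if (length(multi)) {
    spans <- fragment_spans(aln, unique(edge_dt$read_id))
    for (i in multi) {
      ex <- grl[[i]]
      gaps_gr <- GRanges(seqnames(ex)[-1],
                         IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1] - 1L))
      cnt <- countOverlaps(gaps_gr, spans, type = "within")
      link_support[i] <- min(cnt)
    }
  }
  wm <- vapply(seq_along(grl), function(i) {
    ex <- grl[[i]]
    sum(mcols(ex)$mean_depth * width(ex)) / sum(width(ex))
  }, numeric(1))
  mcols(grl) <- DataFrame(model_id = model_id,
                          n_exons = unname(lengths(grl)),
                          link_support = link_support, mean_depth = wm)
  grl
}

#' Classify gene models as intergenic transcription units
#'
#' A model is intergenic iff it overlaps no annotated gene and the distance
#' from its span to the nearest gene boundary is at least `min_distance`
#' (default 200 bp; a model exactly 200 bp away is intergenic, 199 bp is
#' not).  Distance is the number of bases strictly between the model span and
#' the gene.
#'
#' @param models `GRangesList` from [link_tars()].
#' @param genes `GRanges` of annotated genes.
#' @param genome optional `DNAStringSet`; when given, every model scaffold
#'   must be present (else an error) and `spliced_sequence` (exon sequences
#'   concatenated in genomic order) is attached.
#' @param min_distance minimum distance in bp (default 200).
#' @return `models` with metadata columns `intergenic` (logical),
#'   `distance_to_nearest_gene` (bp; `Inf` when the annotation is empty) and,
#'   with a genome, `spliced_sequence` and `spliced_length`.
#' @export
classify_intergenic <- function(models, genes, genome = NULL,
                                min_distance = 200L) {
  stopifnot(min_distance >= 0L)
  if (!length(models)) {
    mcols(models)$intergenic <- logical(0)
    mcols(models)$distance_to_nearest_gene <- numeric(0)
    return(models)
  }
  span <- unlist(range(models))
  if (!is.null(genome)) {
    missing_sc <- setdiff(unique(as.character(seqnames(span))), names(genome))
    if (length(missing_sc)) {
      stop("model scaffold(s) absent from the genome: ",
           paste(missing_sc, collapse = ", "))
    }
  }
  if (length(genes)) {
    ov <- countOverlaps(span, genes, ignore.strand = TRUE) > 0L
    dtn <- distanceToNearest(span, genes, ignore.strand = TRUE)
    dist <- rep(Inf, length(span))
    dist[queryHits(dtn)] <- mcols(dtn)$distance
  } else {
    ov <- rep(FALSE, length(span))
    dist <- rep(Inf, length(span))
  }
  mcols(models)$intergenic <- !ov & dist >= min_distance
  mcols(models)$distance_to_nearest_gene <- dist
  if (!is.null(genome)) {
    scstr <- as.character(genome)
    flat <- unlist(models, use.names = FALSE)
    seqs <- substring(scstr[as.character(seqnames(flat))], start(flat), end(flat))
    mcols(models)$spliced_sequence <-
      unname(vapply(split(seqs, rep(seq_along(models), lengths(models))),
                    paste, character(1), collapse = ""))
    mcols(models)$spliced_length <- nchar(mcols(models)$spliced_sequence)
  }
  models
}

#' Assemble intergenic transcription units for one library
#'
#' Convenience chain: coverage -> TARs -> linked gene models -> intergenic
#' classification, with the library label attached.
#'
#' @param aln alignment `data.table`.
#' @param genes annotated genes (`GRanges`).
#' @param genome genome `DNAStringSet`.
#' @param library library label (`"CL"` or `"DL"`).
#' @param min_depth,min_distance,min_link assembly thresholds.
#' @return A `GRangesList` of all models with classification metadata and a
#'   `library` column.
#' @export
assemble_library <- function(aln, genes, genome, library,
                             min_depth = 2L, min_distance = 200L,
                             min_link = 1L) {
  scaffold_lengths <- setNames(Biostrings::width(genome), names(genome))
  cov <- build_coverage(aln, scaffold_lengths)
  tars <- call_tars(cov, min_depth = min_depth)
  models <- link_tars(tars, aln, min_link = min_link,
                      id_prefix = paste0(library, "_TU"))
  models <- classify_intergenic(models, genes, genome,
                                min_distance = min_distance)
  mcols(models)$library <- library
  models
}
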