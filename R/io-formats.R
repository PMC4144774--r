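#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqnames
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement width
#' @importFrom data.table fread fwrite data.table as.data.table setorder :=
#'   rbindlist set copy setattr .N .SD
#' @importFrom stats rnorm rpois runif setNames rbinom
NULL

# Internal coordinates throughout the package are GRanges (1-based, closed
# intervals), the Bioconductor convention.  On disk, GFF3 is 1-based closed
# and the BED-pair dialect is 0-based half-open (BED convention).

BEDPAIR_HEADER <- "#poplinc-bedpair-v1"

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased and restricted to the ACGTN alphabet.  `U` (RNA
#' input, e.g. mature miRNAs) is accepted and normalised to `T`; records that
#' contained `U` are flagged in `mcols(x)$rna` so downstream pairing logic can
#' reinterpret `T` as `U`.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with an `rna` logical metadata column.
#'   Duplicate record ids are an error; an empty file yields an empty set with
#'   a warning.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) {
    warning("empty FASTA file: ", path)
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out)$rna <- logical(0)
    return(out)
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  rna <- grepl("U", seqs, fixed = TRUE)
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN/U character(s) in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(out)$rna <- rna
  out
}

#' Write sequences as FASTA
#'
#' @param seqs a named character vector or [Biostrings::DNAStringSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    # BStringSet accommodates RNA-alphabet output (e.g. miRNA FASTA with U)
    seqs <- if (any(grepl("U", seqs, fixed = TRUE))) {
      Biostrings::BStringSet(seqs)
    } else {
      Biostrings::DNAStringSet(seqs)
    }
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Keeps features of type `gene` (all features if none are typed `gene`).
#' Coordinates are validated before parsing: a line with end < start is an
#' error naming the offending line number.
#'
#' @param path path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] of genes with a `gene_id` metadata
#'   column (unique).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && e < s) {
        stop("GFF3 line ", i, ": end (", e, ") < start (", s, ")")
      }
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene", seq_along(gr))
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  out <- granges(gr)
  mcols(out)$gene_id <- as.character(ids)
  out
}

#' Write gene annotation as GFF3
#'
#' @param genes a `GRanges` with a `gene_id` metadata column.
#' @param path output path.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "poplinc") {
  gr <- genes
  mcols(gr) <- NULL
  gr$source <- source
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

new_alignment_table <- function(read_id = character(), mate = integer(),
                                scaffold = character(), start = integer(),
                                end = integer(), strand = character(),
                                mapped = logical()) {
  data.table(read_id = read_id, mate = as.integer(mate),
             scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), strand = strand, mapped = mapped)
}

#' Read paired-end alignments
#'
#' Two dialects are supported: standard SAM/BAM (via Rsamtools), and the
#' package's plain-text BED-pair dialect, a 7-column TSV
#' (`read_id, mate, scaffold, start, end, strand, mapped`) with 0-based
#' half-open coordinates and the header comment `#poplinc-bedpair-v1`.
#'
#' @param path path to the alignment file.
#' @param dialect `"auto"`, `"sam"` or `"bedpair"`.
#' @return A `data.table` of per-block alignment records with columns
#'   `read_id`, `mate` (1 or 2), `scaffold`, `start`, `end` (1-based, closed),
#'   `strand`, `mapped`.  Unmapped records are retained with `mapped = FALSE`
#'   and `NA` coordinates; spliced/multi-block alignments are split into one
#'   record per block.
#' @export
read_alignments <- function(path, dialect = c("auto", "sam", "bedpair")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("sam", "bam")) "sam" else {
      first <- readLines(path, n = 1L)
      if (identical(first, BEDPAIR_HEADER)) "bedpair"
      else if (startsWith(first, "@")) "sam"
      else stop("cannot determine alignment dialect of ", path)
    }
  }
  switch(dialect, sam = read_sam_alignments(path),
         bedpair = read_bedpair(path))
}

read_bedpair <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, BEDPAIR_HEADER)) {
    stop("missing ", BEDPAIR_HEADER, " header in ", path)
  }
  dt <- fread(path, skip = 1L, header = TRUE, sep = "\t",
              colClasses = list(character = c("read_id", "scaffold", "strand")))
  out <- new_alignment_table(
    read_id = dt$read_id, mate = dt$mate, scaffold = dt$scaffold,
    start = dt$start + 1L, end = dt$end, strand = dt$strand,
    mapped = as.logical(dt$mapped))
  out[!out$mapped, c("scaffold", "strand") := list(NA_character_, NA_character_)]
  out[!out$mapped, c("start", "end") := list(NA_integer_, NA_integer_)]
  out[]
}

#' Write alignments in the BED-pair dialect
#'
#' @param aln an alignment `data.table` as returned by [read_alignments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpair <- function(aln, path) {
  dt <- data.table(read_id = aln$read_id, mate = aln$mate,
                   scaffold = ifelse(aln$mapped, aln$scaffold, "."),
                   start = ifelse(aln$mapped, aln$start - 1L, 0L),
                   end = ifelse(aln$mapped, aln$end, 0L),
                   strand = ifelse(aln$mapped, aln$strand, "."),
                   mapped = as.integer(aln$mapped))
  con <- file(path, "w")
  writeLines(BEDPAIR_HEADER, con)
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

read_sam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM/BAM")
  }
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  blocks <- GenomicAlignments::grglist(ga)
  nb <- lengths(blocks)
  flat <- unlist(blocks, use.names = FALSE)
  mate <- ifelse(bitwAnd(mcols(ga)$flag, 128L) > 0L, 2L, 1L)
  mapped_dt <- new_alignment_table(
    read_id = rep(mcols(ga)$qname, nb), mate = rep(mate, nb),
    scaffold = as.character(seqnames(flat)), start = start(flat),
    end = end(flat), strand = as.character(strand(flat)),
    mapped = rep(TRUE, length(flat)))
  # unmapped mates: fetch flags only
  un <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))[[1]]
  un_dt <- new_alignment_table(
    read_id = un$qname,
    mate = ifelse(bitwAnd(un$flag, 128L) > 0L, 2L, 1L),
    scaffold = rep(NA_character_, length(un$qname)),
    start = rep(NA_integer_, length(un$qname)),
    end = rep(NA_integer_, length(un$qname)),
    strand = rep(NA_character_, length(un$qname)),
    mapped = rep(FALSE, length(un$qname)))
  rbind(mapped_dt, un_dt)
}

#' Write alignments as SAM
#'
#' Minimal SAM emission for the synthetic generator: sequence and quality are
#' `*`, the CIGAR is a single match block.
#'
#' @param aln an alignment `data.table`.
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, scaffold_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(scaffold_lengths),
                     as.integer(scaffold_lengths)), con)
  flag <- 1L + 2L +
    ifelse(aln$mate == 1L, 64L, 128L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L)
  flag <- flag + ifelse(aln$mapped, 0L, 4L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                   aln$read_id, flag,
                   ifelse(aln$mapped, aln$scaffold, "*"),
                   ifelse(aln$mapped, aln$start, 0L),
                   ifelse(aln$mapped, 60L, 0L),
                   ifelse(aln$mapped,
                          sprintf("%dM", aln$end - aln$start + 1L), "*"))
  writeLines(lines, con)
  invisible(path)
}

#' Alignment records as genomic ranges
#'
#' @param aln an alignment `data.table`.
#' @param keep_unmapped drop unmapped records (default) or error if present.
#' @return A `GRanges` with `read_id` and `mate` metadata columns.
#' @export
alignments_as_granges <- function(aln, keep_unmapped = FALSE) {
  m <- aln[aln$mapped, ]
  gr <- GRanges(m$scaffold, IRanges(m$start, m$end), strand = m$strand)
  mcols(gr)$read_id <- m$read_id
  mcols(gr)$mate <- m$mate
  gr
}
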