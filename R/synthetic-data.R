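# Synthetic two-condition RNA-seq study generator.
#
# Emulates the statistical structure the discovery pipeline assumes: an
# AT-rich intergenic background, GC-biased protein-coding genes, planted
# intergenic elements of known classes (true lincRNA, long-ORF decoy, repeat
# copy, miRNA-precursor copy, near-gene decoy), and two paired-end libraries
# (CL control, DL drought) whose per-element fragment counts are Poisson with
# known fold changes — matching the Poisson null of the two-library count
# test.  Everything is deterministic under a fixed seed.

ELEMENT_CLASSES <- c("lincRNA", "long_orf_decoy", "repeat_copy",
                     "precursor_copy", "near_gene_decoy", "coding_gene")

random_seq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random sequence guaranteed free of ORFs >= max_orf_aa on either strand
orf_free_seq <- function(n, gc, max_orf_aa = 100L, max_tries = 500L) {
  for (i in seq_len(max_tries)) {
    s <- random_seq(n, gc)
    if (longest_orf(s) < max_orf_aa) return(s)
  }
  stop("could not generate an ORF-free sequence of length ", n)
}

sample_codons <- function(n, codon_table) {
  p <- codon_table$freq[SENSE_CODONS]
  paste(sample(SENSE_CODONS, n, replace = TRUE, prob = p), collapse = "")
}

# coding sequence: ATG + (aa-1) sense codons + stop
coding_orf_seq <- function(orf_aa, codon_table) {
  paste0("ATG", sample_codons(orf_aa - 1L, codon_table),
         sample(STOP_CODONS, 1L))
}

#' Generate a toy genome with annotated protein-coding genes
#'
#' Scaffolds are i.i.d. sequence at the intergenic GC fraction (default 0.34,
#' AT-rich as in plant intergenic space).  Genes are placed without overlap,
#' evenly spread, each carrying an ATG-initiated ORF whose codons are drawn
#' from the reference codon table, flanked by short UTRs — so coding sequence
#' is systematically GC-richer than the background, the contrast the
#' coding-potential features exploit.
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length length of each scaffold in bp (>= 10 kb).
#' @param n_genes total number of genes (distributed round-robin).
#' @param seed integer seed; fully determines the output.
#' @param gc_intergenic background GC fraction.
#' @param codon_table reference codon usage table (shared with the
#'   coding-potential scorer).
#' @param gene_orf_aa_range range of gene ORF lengths in amino acids.
#' @return A list: `genome` ([Biostrings::DNAStringSet]), `genes` (`GRanges`
#'   with `gene_id`, `orf_aa`), and `codon_table`.
#' @export
generate_genome <- function(n_scaffolds = 2L, scaffold_length = 2e6,
                            n_genes = 40L, seed = 1L,
                            gc_intergenic = 0.34,
                            codon_table = synthetic_codon_table(),
                            gene_orf_aa_range = c(250L, 500L)) {
  stopifnot(scaffold_length >= 1e4)
  set.seed(seed)
  utr5 <- 100L; utr3 <- 200L
  scafs <- character(n_scaffolds)
  names(scafs) <- sprintf("scaffold_%d", seq_len(n_scaffolds))
  for (i in seq_len(n_scaffolds)) scafs[i] <- random_seq(scaffold_length, gc_intergenic)

  genes_per <- tabulate(rep(seq_len(n_scaffolds), length.out = n_genes),
                        nbins = n_scaffolds)
  gene_rows <- list()
  gi <- 0L
  for (i in seq_len(n_scaffolds)) {
    np <- genes_per[i]
    if (np == 0L) next
    slot <- floor(scaffold_length / np)
    max_gene_len <- utr5 + 3L * (max(gene_orf_aa_range) + 1L) + utr3
    if (slot < max_gene_len + 2L * 3000L) {
      stop("infeasible gene packing: slot width ", slot,
           " too small for gene length ", max_gene_len)
    }
    for (j in seq_len(np)) {
      gi <- gi + 1L
      orf_aa <- sample(seq(gene_orf_aa_range[1], gene_orf_aa_range[2]), 1L)
      gseq <- paste0(random_seq(utr5, gc_intergenic),
                     coding_orf_seq(orf_aa, codon_table),
                     random_seq(utr3, gc_intergenic))
      glen <- nchar(gseq)
      lo <- (j - 1L) * slot + 3000L
      start <- lo + sample.int(slot - glen - 6000L, 1L)  # 1-based
      substr(scafs[i], start, start + glen - 1L) <- gseq
      gene_rows[[gi]] <- data.table(
        gene_id = sprintf("gene%03d", gi), scaffold = names(scafs)[i],
        start = start, end = start + glen - 1L, orf_aa = orf_aa)
    }
  }
  gdt <- rbindlist(gene_rows)
  sl <- setNames(rep(as.integer(scaffold_length), n_scaffolds), names(scafs))
  genes <- if (nrow(gdt)) {
    GRanges(gdt$scaffold, IRanges(gdt$start, gdt$end), strand = "+",
            seqlengths = sl)
  } else {
    GRanges(seqlengths = sl)
  }
  mcols(genes)$gene_id <- gdt$gene_id
  mcols(genes)$orf_aa <- gdt$orf_aa
  list(genome = Biostrings::DNAStringSet(scafs), genes = genes,
       codon_table = codon_table)
}

#' Generate a small library of sequences (repeats, precursors or miRNAs)
#'
#' Library sequences are ORF-free so that planted copies are rejected by the
#' similarity filter, not the ORF filter.
#'
#' @param n number of sequences.
#' @param length_range length range in bp.
#' @param gc GC fraction.
#' @param prefix id prefix.
#' @return named character vector of sequences.
#' @export
generate_sequence_library <- function(n, length_range, gc = 0.40,
                                      prefix = "lib") {
  lens <- if (length_range[1] == length_range[2]) rep(length_range[1], n)
          else sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  setNames(vapply(lens, orf_free_seq, character(1), gc = gc),
           sprintf("%s%02d", prefix, seq_len(n)))
}

# mimic-site construction: reverse complement of the miRNA with `bulge_len`
# extra lincRNA nucleotides inserted opposite the miRNA between positions
# `p` and `p + 1` (antiparallel geometry; see scan_mimics()).
mimic_site_seq <- function(mirna, p = 10L, bulge_len = 3L) {
  m <- nchar(mirna)
  R <- revcomp(mirna)
  bulge <- paste(sample(c("A", "C", "G", "T"), bulge_len, replace = TRUE),
                 collapse = "")
  paste0(substr(R, 1L, m - p), bulge, substr(R, m - p + 1L, m))
}

#' Plant intergenic elements of known classes into a genome
#'
#' Writes elements into intergenic space: true lincRNAs (ORF-free, >= 200 bp
#' from every gene), long-ORF decoys (embedded >= 100 AA ORF), exact copies of
#' repeat and miRNA-precursor library sequences, and near-gene decoys
#' (< 200 bp from a gene).  Selected lincRNAs carry planted miRNA target or
#' target-mimic sites.  Expression means (expected fragments per library) are
#' assigned per element; lincRNA fold changes (DL/CL) follow
#' `linc_fold_changes`.
#'
#' @param genome,genes output of [generate_genome()] (`genome` a
#'   `DNAStringSet`, `genes` a `GRanges` with `gene_id`).
#' @param class_counts named integer vector over
#'   `lincRNA, long_orf_decoy, repeat_copy, precursor_copy, near_gene_decoy`.
#' @param seed integer seed.
#' @param repeats,precursors named character vectors of library sequences
#'   (required when the corresponding class count is positive).
#' @param mirnas named character vector of mature miRNA sequences (DNA
#'   alphabet) for planting interaction sites.
#' @param mirna_role_counts named counts of lincRNAs carrying a planted
#'   `target` / `mimic` site.
#' @param linc_fold_changes DL/CL expression ratios recycled over planted
#'   lincRNAs (default: a 4-fold up/down "drought responsive" set with two
#'   exactly-2-fold boundary probes).
#' @param coverage_fold target per-base read depth of planted elements (sets
#'   the CL expression mean).
#' @param fragments_per_library approximate total fragments per library;
#'   the remainder after planted elements is spread over coding genes.
#' @param read_length read length in bp (default 90).
#' @param linc_length_range,decoy_orf_aa_range element size knobs.
#' @return A list: `genome` (modified `DNAStringSet`) and `manifest` (a
#'   `data.table` of planted elements — the truth manifest; attributes `seed`
#'   and `read_length`).
#' @export
plant_elements <- function(genome, genes, class_counts, seed = 1L,
                           repeats = NULL, precursors = NULL, mirnas = NULL,
                           mirna_role_counts = c(target = 2L, mimic = 2L),
                           linc_fold_changes = c(4, 4, 0.25, 0.25, 2, 2, 1, 1, 1, 1),
                           coverage_fold = 15,
                           fragments_per_library = 5e5,
                           read_length = 90L,
                           linc_length_range = c(500L, 1500L),
                           decoy_orf_aa_range = c(120L, 180L)) {
  set.seed(seed + 1L)
  cc <- setNames(integer(length(ELEMENT_CLASSES)), ELEMENT_CLASSES)
  cc[names(class_counts)] <- as.integer(class_counts)
  if (cc[["repeat_copy"]] > 0L && is.null(repeats))
    stop("repeat_copy elements require a repeat library")
  if (cc[["precursor_copy"]] > 0L && is.null(precursors))
    stop("precursor_copy elements require a precursor library")

  scafs <- as.character(genome)
  scaffold_length <- setNames(nchar(scafs), names(scafs))
  gene_margin <- 1200L; sep <- 600L

  # free intergenic intervals, >= gene_margin from every gene
  free <- list()
  for (sc in names(scafs)) {
    g <- genes[as.character(seqnames(genes)) == sc]
    occ <- reduce(ranges(g) + gene_margin)
    fr <- gaps(occ, start = 1L, end = scaffold_length[[sc]])
    free[[sc]] <- data.table(scaffold = sc, start = start(fr), end = end(fr))
  }
  free <- rbindlist(free)

  take_interval <- function(len) {
    ok <- which(free$end - free$start + 1L >= len + 2L * sep)
    if (!length(ok)) stop("not enough intergenic space to plant an element")
    i <- ok[sample.int(length(ok), 1L)]
    lo <- free$start[i] + sep
    hi <- free$end[i] - sep - len + 1L
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    row <- free[i]
    free <<- rbind(free[-i],
                   data.table(scaffold = row$scaffold, start = row$start,
                              end = s - sep),
                   data.table(scaffold = row$scaffold, start = s + len + sep,
                              end = row$end))
    free <<- free[free$end - free$start + 1L > 0L]
    list(scaffold = row$scaffold, start = s)
  }

  rows <- list()
  add_row <- function(id, class, scaffold, start, len, seq_str,
                      mirna_id = NA_character_, mirna_role = NA_character_,
                      site_start = NA_integer_, site_len = NA_integer_) {
    substr(scafs[[scaffold]], start, start + len - 1L) <<- seq_str
    rows[[length(rows) + 1L]] <<- data.table(
      element_id = id, class = class, scaffold = scaffold,
      start = start, end = start + len - 1L, strand = "*", length = len,
      mirna_id = mirna_id, mirna_role = mirna_role,
      site_start = site_start, site_len = site_len)
  }

  gc_bg <- 0.34
  # lincRNAs (with optional planted miRNA sites)
  n_linc <- cc[["lincRNA"]]
  roles <- character(n_linc)
  if (n_linc > 0L && !is.null(mirnas)) {
    nt <- min(mirna_role_counts[["target"]], n_linc)
    nm <- min(mirna_role_counts[["mimic"]], max(0L, n_linc - nt))
    roles[seq_len(nt)] <- "target"
    if (nm > 0L) roles[nt + seq_len(nm)] <- "mimic"
  }
  for (i in seq_len(n_linc)) {
    len <- sample(seq(linc_length_range[1], linc_length_range[2]), 1L)
    mirna_id <- NA_character_; site_start <- NA_integer_; site_len <- NA_integer_
    repeat {
      s <- orf_free_seq(len, gc_bg)
      if (nzchar(roles[i])) {
        mirna_id <- names(mirnas)[((i - 1L) %% length(mirnas)) + 1L]
        site <- if (roles[i] == "target") revcomp(mirnas[[mirna_id]])
                else mimic_site_seq(mirnas[[mirna_id]])
        site_len <- nchar(site)
        site_start <- sample.int(len - site_len - 20L, 1L) + 10L
        substr(s, site_start, site_start + site_len - 1L) <- site
      }
      if (longest_orf(s) < 100L) break
    }
    pos <- take_interval(len)
    add_row(sprintf("linc%02d", i), "lincRNA", pos$scaffold, pos$start, len, s,
            mirna_id = mirna_id,
            mirna_role = if (nzchar(roles[i])) roles[i] else NA_character_,
            site_start = site_start, site_len = site_len)
  }
  # long-ORF decoys: embedded coding ORF >= 100 AA in the element centre
  for (i in seq_len(cc[["long_orf_decoy"]])) {
    orf_aa <- sample(seq(decoy_orf_aa_range[1], decoy_orf_aa_range[2]), 1L)
    orf <- coding_orf_seq(orf_aa, synthetic_codon_table())
    len <- max(1200L, nchar(orf) + 400L)
    s <- orf_free_seq(len, gc_bg)
    off <- (len - nchar(orf)) %/% 2L
    substr(s, off + 1L, off + nchar(orf)) <- orf
    pos <- take_interval(len)
    add_row(sprintf("orfdecoy%02d", i), "long_orf_decoy",
            pos$scaffold, pos$start, len, s)
  }
  # exact copies of repeat / precursor library sequences
  for (i in seq_len(cc[["repeat_copy"]])) {
    s <- repeats[[((i - 1L) %% length(repeats)) + 1L]]
    pos <- take_interval(nchar(s))
    add_row(sprintf("repcopy%02d", i), "repeat_copy",
            pos$scaffold, pos$start, nchar(s), s)
  }
  for (i in seq_len(cc[["precursor_copy"]])) {
    s <- precursors[[((i - 1L) %% length(precursors)) + 1L]]
    pos <- take_interval(nchar(s))
    add_row(sprintf("precopy%02d", i), "precursor_copy",
            pos$scaffold, pos$start, nchar(s), s)
  }
  # near-gene decoys: < 200 bp downstream of distinct genes
  n_ng <- cc[["near_gene_decoy"]]
  if (n_ng > 0L) {
    picked <- sample(seq_along(genes), n_ng)
    for (i in seq_len(n_ng)) {
      g <- genes[picked[i]]
      len <- sample(500:800, 1L)
      d <- sample(10:150, 1L)       # distance to gene end = d - 1 < 200
      s <- orf_free_seq(len, gc_bg)
      add_row(sprintf("neargene%02d", i), "near_gene_decoy",
              as.character(seqnames(g)), end(g) + d, len, s)
    }
  }

  manifest <- rbindlist(rows)
  # expression: planted elements at coverage_fold read depth in CL
  manifest[, expression_CL := round(coverage_fold * length / (2 * read_length))]
  fc <- rep(1, nrow(manifest))
  is_linc <- manifest$class == "lincRNA"
  fc[is_linc] <- rep_len(linc_fold_changes, sum(is_linc))
  manifest[, fold_change := fc]
  manifest[, expression_DL := expression_CL * fold_change]

  # coding genes absorb the remaining fragment budget, equally in CL and DL
  n_genes <- length(genes)
  gene_mean <- max(0, (fragments_per_library - sum(manifest$expression_CL)) /
                     max(1L, n_genes))
  gene_dt <- data.table(
    element_id = genes$gene_id, class = "coding_gene",
    scaffold = as.character(seqnames(genes)),
    start = start(genes), end = end(genes), strand = "+",
    length = width(genes),
    mirna_id = NA_character_, mirna_role = NA_character_,
    site_start = NA_integer_, site_len = NA_integer_,
    expression_CL = gene_mean, fold_change = 1, expression_DL = gene_mean)
  manifest <- rbind(manifest, gene_dt)
  setattr(manifest, "seed", seed)
  setattr(manifest, "read_length", as.integer(read_length))
  list(genome = Biostrings::DNAStringSet(scafs), manifest = manifest)
}

#' Simulate two paired-end alignment libraries from a truth manifest
#'
#' Per element and library, the fragment count is Poisson with the manifest's
#' expression mean.  Fragments are placed uniformly within the element; each
#' yields two `read_length` mates on opposite strands with inner distance
#' Normal(`inner_mean`, `inner_sd`) truncated at 0 (the fragment is clipped to
#' the element, so no read extends past element boundaries).  Optional
#' background noise fragments are placed uniformly on the genome.  Alignment
#' is emulated as exact placement — no sequencing errors.
#'
#' @param manifest truth manifest from [plant_elements()].
#' @param genome the `DNAStringSet` genome (for scaffold lengths).
#' @param seed integer seed.
#' @param read_length read length in bp.
#' @param inner_mean,inner_sd inner-distance distribution parameters.
#' @param noise_rate background noise fragments per Mbp per library
#'   (default 0).
#' @return A list: `alignments` (list of `CL` and `DL` alignment
#'   `data.table`s) and `totals` (named vector `N1` = CL fragments,
#'   `N2` = DL fragments).
#' @export
simulate_alignments <- function(manifest, genome, seed = 1L,
                                read_length = 90L, inner_mean = 200,
                                inner_sd = 30, noise_rate = 0) {
  if (any(manifest$length < read_length)) {
    stop("element(s) shorter than the read length: ",
         paste(manifest$element_id[manifest$length < read_length],
               collapse = ", "))
  }
  scaffold_length <- setNames(Biostrings::width(genome), names(genome))
  out <- list()
  totals <- c(N1 = 0L, N2 = 0L)
  for (li in 1:2) {
    lib <- c("CL", "DL")[li]
    set.seed(seed + 10L + li)
    mu <- if (lib == "CL") manifest$expression_CL else manifest$expression_DL
    parts <- vector("list", nrow(manifest) + 1L)
    for (e in seq_len(nrow(manifest))) {
      n <- rpois(1L, mu[e])
      if (n == 0L) next
      L <- manifest$length[e]
      inner <- pmax(0, round(rnorm(n, inner_mean, inner_sd)))
      span <- pmin(2L * read_length + inner, L)
      s0 <- floor(runif(n, 0, L - span + 1))           # 0-based in element
      a_start <- manifest$start[e] + s0                # mate A (leftmost)
      b_start <- manifest$start[e] + s0 + span - read_length
      flip <- rbinom(n, 1L, 0.5) == 1L                 # which mate is mate 1
      id <- sprintf("%s_%s_f%06d", lib, manifest$element_id[e], seq_len(n))
      parts[[e]] <- data.table(
        read_id = c(id, id),
        mate = c(ifelse(flip, 2L, 1L), ifelse(flip, 1L, 2L)),
        scaffold = manifest$scaffold[e],
        start = as.integer(c(a_start, b_start)),
        end = as.integer(c(a_start, b_start) + read_length - 1L),
        strand = c(ifelse(flip, "-", "+"), ifelse(flip, "+", "-")),
        mapped = TRUE)
      totals[li] <- totals[li] + n
    }
    if (noise_rate > 0) {
      gsize <- sum(scaffold_length)
      nn <- rpois(1L, noise_rate * gsize / 1e6)
      if (nn > 0L) {
        sc <- sample(names(scaffold_length), nn, replace = TRUE,
                     prob = scaffold_length / gsize)
        span <- pmax(2L * read_length,
                     2L * read_length + pmax(0, round(rnorm(nn, inner_mean, inner_sd))))
        s <- floor(runif(nn, 1, scaffold_length[sc] - span))
        id <- sprintf("%s_noise_f%06d", lib, seq_len(nn))
        parts[[nrow(manifest) + 1L]] <- data.table(
          read_id = c(id, id), mate = c(rep(1L, nn), rep(2L, nn)),
          scaffold = c(sc, sc),
          start = as.integer(c(s, s + span - read_length)),
          end = as.integer(c(s, s + span - read_length) + read_length - 1L),
          strand = c(rep("+", nn), rep("-", nn)), mapped = TRUE)
        totals[li] <- totals[li] + nn
      }
    }
    out[[lib]] <- rbindlist(parts)
  }
  list(alignments = out, totals = totals)
}

#' Write / read a truth manifest as TSV
#'
#' Scalar attributes (seed, read length, library totals) travel in `#key=value`
#' header comments; the round trip is lossless.
#'
#' @param manifest a truth-manifest `data.table`.
#' @param path file path.
#' @param totals optional named totals `c(N1=, N2=)` to record.
#' @return `path` (write) or the manifest (read).
#' @export
write_truth_manifest <- function(manifest, path, totals = NULL) {
  con <- file(path, "w")
  writeLines(sprintf("#seed=%d", attr(manifest, "seed")), con)
  writeLines(sprintf("#read_length=%d", attr(manifest, "read_length")), con)
  if (!is.null(totals)) {
    writeLines(sprintf("#N1=%d", as.integer(totals[["N1"]])), con)
    writeLines(sprintf("#N2=%d", as.integer(totals[["N2"]])), con)
  }
  close(con)
  fwrite(manifest, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, character(1), 2L),
                   vapply(kv, `[`, character(1), 1L))
  m <- fread(path, skip = length(hdr), header = TRUE, sep = "\t",
             na.strings = c("", "NA"),
             colClasses = list(character = c("element_id", "class", "scaffold",
                                             "strand", "mirna_id", "mirna_role")))
  setattr(m, "seed", as.integer(vals[["seed"]]))
  setattr(m, "read_length", as.integer(vals[["read_length"]]))
  if ("N1" %in% names(vals)) {
    setattr(m, "totals", c(N1 = as.integer(vals[["N1"]]),
                           N2 = as.integer(vals[["N2"]])))
  }
  m[]
}
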