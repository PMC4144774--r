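# End-to-end orchestration: simulate -> assemble -> filter -> coding -> DE ->
# miRNA scan -> run report.  One flat config carries every pipeline threshold
# exactly once; the run report contains the per-stage candidate funnel, DE
# and network summaries, and the seed, and is byte-identical across reruns
# with the same config.

#' Pipeline configuration
#'
#' All thresholds of the discovery pipeline in one flat list: assembly
#' (per-base depth >= 2, intergenic distance >= 200 bp, >= 1 linking mate
#' pair), filtering (length > 200 bp, longest ORF < 100 AA, both libraries,
#' similarity thresholds), coding assessment (0.5 decision threshold), DE
#' (|log2 ratio| > 1, P < 0.001) and miRNA pairing rules, plus the synthetic
#' study design (2 scaffolds x 2 Mbp, 40 genes, 90 bp paired-end reads,
#' ~5e5 fragments per library by default).
#'
#' @param seed integer seed driving every stochastic stage.
#' @param outdir optional output directory; when given, all intermediates
#'   are persisted as FASTA/GFF3/BED-pair/TSV.
#' @param class_counts planted element counts per class.
#' @param n_scaffolds,scaffold_length,n_genes,fragments_per_library,
#'   read_length,noise_rate synthetic study design.
#' @param min_depth,min_distance,min_link assembly thresholds.
#' @param filter a [filter_config()].
#' @param de a [de_config()].
#' @param rules a [pairing_rules()].
#' @param coding_threshold coding-score decision threshold.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL,
                            class_counts = c(lincRNA = 10L,
                                             long_orf_decoy = 5L,
                                             near_gene_decoy = 3L,
                                             repeat_copy = 2L,
                                             precursor_copy = 2L),
                            n_scaffolds = 2L, scaffold_length = 2e6,
                            n_genes = 40L, fragments_per_library = 5e5,
                            read_length = 90L, noise_rate = 0,
                            min_depth = 2L, min_distance = 200L,
                            min_link = 1L,
                            filter = filter_config(), de = de_config(),
                            rules = pairing_rules(),
                            coding_threshold = 0.5) {
  structure(list(seed = as.integer(seed), outdir = outdir,
                 class_counts = class_counts, n_scaffolds = n_scaffolds,
                 scaffold_length = scaffold_length, n_genes = n_genes,
                 fragments_per_library = fragments_per_library,
                 read_length = read_length, noise_rate = noise_rate,
                 min_depth = min_depth, min_distance = min_distance,
                 min_link = min_link, filter = filter, de = de,
                 rules = rules, coding_threshold = coding_threshold),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[poplinc] %s: %s", stage, sprintf(...)))
}

#' Run the full discovery pipeline on synthetic data
#'
#' Generates the synthetic study (genome, annotation, repeat / precursor /
#' miRNA libraries, planted elements, two alignment libraries), assembles
#' intergenic transcription units per library, applies the four-filter
#' cascade, scores coding potential, computes differential expression, scans
#' passing candidates for miRNA targets and mimics, and returns a run
#' report.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `run_report`: `funnel` (per-stage counts),
#'   `candidates`, `expression`, `coding`, `network`, `density`, `manifest`,
#'   `totals`, `seed`.  With `config$outdir` set, all intermediates are
#'   written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  set.seed(seed)
  stage_log("simulate", "seed %d", seed)
  gen <- generate_genome(config$n_scaffolds, config$scaffold_length,
                         config$n_genes, seed = seed)
  set.seed(seed + 2L)
  repeats <- generate_sequence_library(3L, c(600L, 1000L), prefix = "repeat")
  precursors <- generate_sequence_library(3L, c(500L, 600L), prefix = "premir")
  mirnas <- generate_sequence_library(10L, c(21L, 21L), gc = 0.5,
                                      prefix = "mir")
  planted <- plant_elements(gen$genome, gen$genes, config$class_counts,
                            seed = seed, repeats = repeats,
                            precursors = precursors, mirnas = mirnas,
                            fragments_per_library = config$fragments_per_library,
                            read_length = config$read_length)
  sim <- simulate_alignments(planted$manifest, planted$genome, seed = seed,
                             read_length = config$read_length,
                             noise_rate = config$noise_rate)
  stage_log("simulate", "N1=%d N2=%d fragments", sim$totals[["N1"]],
            sim$totals[["N2"]])

  stage_log("assemble", "CL")
  cl <- assemble_library(sim$alignments$CL, gen$genes, planted$genome, "CL",
                         config$min_depth, config$min_distance,
                         config$min_link)
  stage_log("assemble", "DL")
  dl <- assemble_library(sim$alignments$DL, gen$genes, planted$genome, "DL",
                         config$min_depth, config$min_distance,
                         config$min_link)
  cl_tus <- cl[mcols(cl)$intergenic]
  dl_tus <- dl[mcols(dl)$intergenic]
  stage_log("assemble", "%d CL TUs, %d DL TUs intergenic",
            length(cl_tus), length(dl_tus))

  merged <- merge_library_tus(cl_tus, dl_tus, planted$genome)
  cand <- filter_candidates(merged, config$filter, repeats, precursors)
  passing <- cand[cand$passed]
  stage_log("filter", "%d loci -> %d candidates", nrow(cand), nrow(passing))

  coding <- if (nrow(passing)) {
    scores <- lapply(passing$seq, coding_score,
                     reference = gen$codon_table,
                     threshold = config$coding_threshold)
    data.table(locus_id = passing$locus_id,
               score = vapply(scores, `[[`, numeric(1), "score"),
               label = vapply(scores, `[[`, character(1), "label"),
               orf_aa = vapply(scores, function(s) s$features$orf_aa,
                               integer(1)),
               gc_fraction = vapply(scores, function(s) s$features$gc_fraction,
                                    numeric(1)),
               n_exons = passing$n_exons)
  } else data.table()

  expr <- expression_table(passing, merged$exons[passing$locus_id],
                           sim$alignments$CL, sim$alignments$DL,
                           N1 = sim$totals[["N1"]], N2 = sim$totals[["N2"]],
                           config = config$de)

  linc_seqs <- setNames(passing$seq, passing$locus_id)
  tg <- list(); mm <- list()
  for (mi in names(mirnas)) {
    for (li in names(linc_seqs)) {
      tg[[paste(mi, li)]] <- scan_targets(mirnas[[mi]], linc_seqs[[li]],
                                          config$rules, mi, li)
      mm[[paste(mi, li)]] <- scan_mimics(mirnas[[mi]], linc_seqs[[li]],
                                         config$rules, mi, li)
    }
  }
  target_sites <- rbindlist(tg)
  mimic_sites <- rbindlist(mm)
  network <- build_interaction_network(target_sites, mimic_sites)

  funnel <- data.table(
    stage = c("TUs_CL", "TUs_DL", "merged_loci", "pass_length", "pass_orf",
              "pass_both_libraries", "pass_similarity", "candidates"),
    count = c(length(cl_tus), length(dl_tus), nrow(cand),
              sum(cand$pass_length),
              sum(cand$pass_length & cand$pass_orf),
              sum(cand$pass_length & cand$pass_orf & cand$pass_both_libraries),
              sum(cand$pass_length & cand$pass_orf & cand$pass_both_libraries &
                    cand$pass_similarity),
              nrow(passing)))

  density <- report_density(
    passing, setNames(Biostrings::width(planted$genome),
                      names(planted$genome)))

  report <- structure(list(
    funnel = funnel, candidates = cand, coding = coding, expression = expr,
    target_sites = target_sites, mimic_sites = mimic_sites,
    network = network, density = density, manifest = planted$manifest,
    totals = sim$totals, seed = seed,
    de_counts = c(up = sum(expr$responsive == "up"),
                  down = sum(expr$responsive == "down"))),
    class = "run_report")

  if (!is.null(config$outdir)) {
    persist_run(report, planted, gen, sim, repeats, precursors, mirnas,
                config$outdir)
  }
  report
}

persist_run <- function(report, planted, gen, sim, repeats, precursors,
                        mirnas, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(planted$genome, file.path(outdir, "genome.fa"))
  write_gff3(gen$genes, file.path(outdir, "genes.gff3"))
  write_fasta(repeats, file.path(outdir, "repeats.fa"))
  write_fasta(precursors, file.path(outdir, "precursors.fa"))
  # miRNAs are written in the RNA alphabet
  write_fasta(setNames(chartr("T", "U", mirnas), names(mirnas)),
              file.path(outdir, "mirnas.fa"))
  write_bedpair(sim$alignments$CL, file.path(outdir, "CL.bedpair.tsv"))
  write_bedpair(sim$alignments$DL, file.path(outdir, "DL.bedpair.tsv"))
  write_truth_manifest(planted$manifest, file.path(outdir, "truth.tsv"),
                       totals = sim$totals)
  fwrite(report$candidates[, setdiff(names(report$candidates), "seq"),
                           with = FALSE],
         file.path(outdir, "candidates.tsv"), sep = "\t")
  passing <- report$candidates[report$candidates$passed]
  if (nrow(passing)) {
    write_fasta(setNames(passing$seq, passing$locus_id),
                file.path(outdir, "lincRNAs.fa"))
  }
  fwrite(report$expression, file.path(outdir, "expression.tsv"), sep = "\t")
  if (nrow(report$coding)) {
    fwrite(report$coding, file.path(outdir, "coding.tsv"), sep = "\t")
  }
  fwrite(report$target_sites, file.path(outdir, "mirna_targets.tsv"),
         sep = "\t")
  fwrite(report$mimic_sites, file.path(outdir, "mirna_mimics.tsv"),
         sep = "\t")
  fwrite(report$network$edges, file.path(outdir, "network_edges.tsv"),
         sep = "\t")
  fwrite(report$funnel, file.path(outdir, "funnel.tsv"), sep = "\t")
  invisible(outdir)
}

#' Candidate density per scaffold and length histogram
#'
#' @param candidates candidate table with `scaffold` and `spliced_length`
#'   columns (typically passing candidates).
#' @param scaffold_lengths named integer vector of scaffold lengths.
#' @param bin_bp histogram bin width in bp (default 100).
#' @return A list: `density` (`data.table` of candidates per Mbp per
#'   scaffold) and `length_histogram` (100 bp bins; bin counts sum to the
#'   number of candidates).
#' @export
report_density <- function(candidates, scaffold_lengths, bin_bp = 100L) {
  n <- vapply(names(scaffold_lengths), function(sc)
    sum(candidates$scaffold == sc), integer(1))
  density <- data.table(scaffold = names(scaffold_lengths),
                        n_candidates = n,
                        per_mbp = n / (scaffold_lengths / 1e6))
  if (nrow(candidates)) {
    bins <- (candidates$spliced_length %/% bin_bp) * bin_bp
    tab <- table(bins)
    hist <- data.table(bin_start = as.integer(names(tab)),
                       count = as.integer(tab))
  } else {
    hist <- data.table(bin_start = integer(0), count = integer(0))
  }
  list(density = density, length_histogram = hist)
}
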