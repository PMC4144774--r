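# Shared tiny-study fixture: a 1 x 200 kb genome with 4 genes and one
# element of each planted class, built in code at test time.

tiny_study <- function(seed = 3L, fragments = 2e4) {
  gen <- generate_genome(n_scaffolds = 1L, scaffold_length = 2e5,
                         n_genes = 4L, seed = seed)
  set.seed(seed + 100L)
  repeats <- generate_sequence_library(2L, c(600L, 800L), prefix = "rep")
  precursors <- generate_sequence_library(2L, c(500L, 600L), prefix = "pre")
  mirnas <- generate_sequence_library(3L, c(21L, 21L), gc = 0.5,
                                      prefix = "mir")
  planted <- plant_elements(gen$genome, gen$genes,
                            c(lincRNA = 3L, long_orf_decoy = 2L,
                              near_gene_decoy = 1L, repeat_copy = 1L,
                              precursor_copy = 1L),
                            seed = seed, repeats = repeats,
                            precursors = precursors, mirnas = mirnas,
                            fragments_per_library = fragments)
  sim <- simulate_alignments(planted$manifest, planted$genome, seed = seed)
  list(gen = gen, planted = planted, sim = sim, repeats = repeats,
       precursors = precursors, mirnas = mirnas)
}

# exon GRangesList + loci table wrapper for hand-built merge inputs
make_tu <- function(scaffold, start, end) {
  GenomicRanges::GRangesList(GenomicRanges::GRanges(
    scaffold, IRanges::IRanges(start, end)))
}
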