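# Shared alphabet constants.  One alphabet everywhere: sequences are DNA
# (ACGTN); RNA inputs are normalised to T on read and reinterpreted as U by
# the miRNA pairing logic.

STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
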