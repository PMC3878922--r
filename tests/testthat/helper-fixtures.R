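# Shared synthetic fixtures: a small genome and event sets reused across
# module tests. Everything is generated in code; no files are read.

tiny_genome <- function() genome_def(c(chr1 = 33e6, chr2 = 20e6))

gain3_event <- function(g = tiny_genome(), start = 10e6, end = 12e6) {
  truth_events("chr1", start, end, "gain", 3L, g)
}

# a probe table built by hand (not via simulate_acgh) for splitter tests
step_probes <- function(values, spacing = 1000, chrom = "c1") {
  data.frame(chrom = chrom,
             pos = seq(0, by = spacing, length.out = length(values)),
             log2_ratio = values, stringsAsFactors = FALSE)
}
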