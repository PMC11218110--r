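# Small fixtures built in code, shared across test files.

# genes x samples matrix with named dims
toy_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# minimal variant data.frame
toy_variants <- function(patient, gene, filter = "PASS",
                         chasm = 0.9, vest = 0.9) {
  n <- max(length(patient), length(gene))
  data.frame(patient = rep_len(patient, n), gene = rep_len(gene, n),
             chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
             filter = rep_len(filter, n), chasm = rep_len(chasm, n),
             vest = rep_len(vest, n), stringsAsFactors = FALSE)
}

# reproducible normal draws without touching the ambient RNG stream
rnorm_fixed <- function(n, seed, mean = 0, sd = 1) {
  withr::with_seed(seed, rnorm(n, mean, sd))
}

# metadata for a two-group unpaired design
toy_meta <- function(samples, groups) {
  data.frame(sample = samples, group = groups, stringsAsFactors = FALSE)
}
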