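# Small in-code fixtures shared across test files.

# a profile list entry as the readers/generators produce it
make_profile <- function(counts, gene_id = "gA", time_point = "t1") {
  list(gene_id = gene_id, time_point = time_point, counts = as.integer(counts))
}

# tiny deterministic genome: each gene is an explicit codon vector
tiny_genome <- function() {
  list(
    gA = rep(c("AAA", "GAA", "TTG"), length.out = 60),
    gB = rep(c("AAA", "CCA"), length.out = 50)
  )
}

# write a profiles TSV and return its path
write_profile_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\ttime_point\tcounts", rows), path)
  path
}
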