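# Generate the synthetic study: a genome, dynamic ground-truth codon
# decoding rates with one programmed rare-codon rank inversion, transcript
# levels, ribo-seq-like count profiles, and a PPI network coupled to the
# (later estimated) MTDR co-patterns.

source("analysis/00_config.R")

usage <- setNames(rep(1, 61), sense_codons())
usage[inversion_codons] <- 0.25   # rare, but above the admission threshold

genome <- generate_genome(n_genes, c(150L, 400L), codon_usage = usage,
                          seed = seed)

set.seed(seed + 1L)
base_rates <- setNames(exp(runif(61, log(0.5), log(2))), sense_codons())
rates <- generate_rate_trajectories(
  base_rates, n_timepoints,
  inversion = list(codons = inversion_codons, timepoints = inversion_tp),
  noise_sd = 0.05, seed = seed + 2L)
levels <- generate_transcript_levels(names(genome), n_timepoints,
                                     seed = seed + 3L)
truth <- synthetic_truth(rates, levels,
                         setNames(rep(0.1, n_genes), names(genome)),
                         pause_prob = 0.05, pause_scale = 1.0)
profiles <- simulate_profiles(genome, truth, depth = depth, seed = seed + 4L)

write_genome_fasta(genome, file.path(data_dir, "genome.fasta"))
write_profiles(profiles, file.path(data_dir, "profiles.tsv"))
write_matrix_tsv(levels, file.path(data_dir, "transcript_levels.tsv"),
                 "gene_id")
write_matrix_tsv(rates, file.path(data_dir, "true_codon_rates.tsv"), "codon")

cat(sprintf("simulated %d genes x %d time points, %d profiles, depth %g\n",
            n_genes, n_timepoints, length(profiles), depth))
cat(sprintf("rank inversion programmed for %s at %s\n",
            paste(inversion_codons, collapse = "/"),
            paste0("t", inversion_tp)))
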