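# Per-gene MTDR across time points, standardized z-scores (the matrix an
# external clustering tool would consume), and the gene-gene co-score
# matrix of MTDR trajectories.

source("analysis/00_config.R")

genome <- read_genome_fasta(file.path(data_dir, "genome.fasta"))
tdr <- as.matrix(read.delim(file.path(out_dir, "tdr_table.tsv"),
                            row.names = 1, check.names = FALSE))

mm <- mtdr_matrix(genome, tdr)
z <- standardize_mtdr(mm$mtdr)
write_matrix_tsv(mm$mtdr, file.path(out_dir, "mtdr_matrix.tsv"), "gene_id")
write_matrix_tsv(z, file.path(out_dir, "mtdr_zscores.tsv"), "gene_id")

co <- mtdr_coscore(mm$mtdr)
write_matrix_tsv(round(co, 4), file.path(out_dir, "mtdr_coscores.tsv"),
                 "gene_id")

cat(sprintf("MTDR for %d genes x %d time points; %.1f%% of cells imputed\n",
            nrow(mm$mtdr), ncol(mm$mtdr), 100 * mean(mm$imputed > 0)))
cat(sprintf("z-score columns: mean %s, sd %s (per time point)\n",
            paste(sprintf("%.2g", colMeans(z)), collapse = "/"),
            paste(sprintf("%.2f", apply(z, 2, sd)), collapse = "/")))
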