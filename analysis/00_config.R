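# Shared settings for the analysis drivers.  Everything downstream is
# deterministic given this seed; outputs land under results/.

library(ribodyn)

seed <- 42L
data_dir <- file.path("results", "data")
out_dir <- "results"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

n_genes <- 300L
n_timepoints <- 4L
depth <- 40            # mean reads per codon: "high depth" regime
inversion_codons <- c("CGG", "CCG")
inversion_tp <- 3L
vegetative_tp <- "t1"

write_matrix_tsv <- function(m, path, row_label = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
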