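#!/usr/bin/env Rscript
# Per-sample spurious-hit filters on the decontaminated tables, then
# depth normalisation (taxon RPM, gene DPM). Taxa need >= 10 NT
# alignments, >= 1 NR alignment and >= 50 b alignment length; genes are
# dropped when coverage breadth < 5% and they are rare (<= 5% of
# ARG-bearing samples) or shallow (DPM <= 1 and <= 10 alignments).

library(azresistome)

out <- "results/filtered"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

meta <- read_sample_metadata("results/data/sample_metadata.csv")
taxa <- read_taxon_report("results/decontam/taxa_decontaminated.tsv")
args <- read_arg_report("results/decontam/args_decontaminated.tsv")

taxa_res <- filter_taxa(taxa)
taxa_f <- add_abundance(taxa_res$retained, meta)

args_dpm <- add_abundance(args, meta)
prev <- arg_prevalence(args_dpm)
args_res <- filter_args(args_dpm, prev)

readr::write_tsv(taxa_f, file.path(out, "taxa_filtered.tsv"))
readr::write_tsv(args_res$retained, file.path(out, "args_filtered.tsv"))
readr::write_tsv(taxa_res$decisions, file.path(out, "taxa_decisions.tsv"))
readr::write_tsv(args_res$decisions, file.path(out, "args_decisions.tsv"))

message(sprintf("taxa: %d/%d records retained", nrow(taxa_res$retained), nrow(taxa)))
message(sprintf("ARGs: %d/%d records retained", nrow(args_res$retained), nrow(args)))
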