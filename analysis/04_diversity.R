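#!/usr/bin/env Rscript
# Alpha and beta diversity of the filtered microbiome and resistome:
# per-sample Shannon indices, Bray-Curtis dissimilarities, PCoA
# coordinates, and a one-factor permutational test of exposure-group
# separation in the genus-level microbiome.

library(azresistome)

out <- "results/diversity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- as.integer(sub("seed: ", "", readLines("results/data/config.txt")[1]))

meta <- read_sample_metadata("results/data/sample_metadata.csv")
taxa <- readr::read_tsv("results/filtered/taxa_filtered.tsv", show_col_types = FALSE)
args <- readr::read_tsv("results/filtered/args_filtered.tsv", show_col_types = FALSE)
intervals <- readr::read_csv("results/data/antibiotic_intervals.csv",
                             show_col_types = FALSE)

bact <- taxa[taxa$kingdom == "bacteria", ]
tab <- pivot_to_table(bact, "name", "rpm", "rpm")
arg_tab <- pivot_to_table(args, "gene", "dpm", "dpm")

alpha <- tibble::tibble(
  sample_id = rownames(tab),
  shannon_taxa = apply(unclass(tab), 1, function(x) {
    if (sum(x) == 0) NA_real_ else shannon(x)
  })
)
readr::write_csv(alpha, file.path(out, "alpha_diversity.csv"))

keep <- rowSums(unclass(tab)) > 0
d <- bray_curtis_matrix(unclass(tab)[keep, ])
readr::write_tsv(tibble::as_tibble(d, rownames = "sample_id"),
                 file.path(out, "bray_curtis_taxa.tsv"))

ord <- pcoa(d, k = 2)
coords <- tibble::as_tibble(ord$coords, rownames = "sample_id")
readr::write_csv(coords, file.path(out, "pcoa_taxa.csv"))
message(sprintf("PCoA axes 1-2 explain %.1f%% / %.1f%% of positive inertia",
                100 * ord$proportion_explained[1],
                100 * ord$proportion_explained[2]))

# one-factor permutational test of exposure-group separation
groups <- assign_exposure_group(complete_exposures(
  expand_exposures(intervals),
  unique(meta$patient_id[!meta$is_negative_control])))
grp <- as.character(groups$group[match(
  meta$patient_id[match(rownames(d), meta$sample_id)], groups$patient_id)])
ok <- !is.na(grp)
pt <- permanova_oneway(d[ok, ok], grp[ok], n_perm = 999, seed = seed)
message(sprintf("PERMANOVA (one-way, exposure group): pseudo-F = %.2f, p = %.3f",
                pt$statistic, pt$p_value))
readr::write_csv(tibble::tibble(test = "permanova_oneway_group",
                                statistic = pt$statistic,
                                p_value = pt$p_value, n_perm = pt$n_perm),
                 file.path(out, "permanova.csv"))
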