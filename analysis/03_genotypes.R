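#!/usr/bin/env Rscript
# Stage 3 — genotype processing: common-variant QC funnel, LD pruning,
# GRM construction, ancestry PCA, and gene-level rare burden collapsing.
# Genotypes are read back from the VCF written by stage 1.
source("analysis/00_config.R")

ann <- read_annotation_tsv(res_path("annotation.tsv"))
geno <- read_genotypes_vcf(res_path("genotypes.vcf"), annotation = ann)
cat(sprintf("loaded %d variants x %d donors from VCF\n",
            nrow(geno$variants), length(geno$donors)))

common <- qc_common_variants(geno, maf_min = 0.05, miss_max = 0.05,
                             hwe_p_min = 1e-5)
log <- attr(common, "qc_log")
cat(sprintf("common-variant QC: %d in -> %d structural pass -> %d out\n",
            log$n_in, log$n_structural_pass, log$n_out))

pruned <- ld_prune(common, mode = "bp")   # r2 > 0.1, 50 kb / 10 kb
cat(sprintf("LD pruning: %d -> %d variants\n",
            nrow(common$variants), length(pruned)))

grm <- compute_grm(subset_variants(common, pruned))
pca <- pca_from_grm(grm, k = 20)
write_grm(grm, res_path("cohort"))
write_trait_tsv(cbind(data.frame(donor_id = rownames(pca$pcs)),
                      as.data.frame(pca$pcs)),
                res_path("ancestry_pcs.tsv"))
cat(sprintf("GRM: %d donors, mean diagonal %.3f; top eigenvalue %.2f\n",
            nrow(grm), mean(diag(grm)), pca$eigenvalues[1]))

burden <- collapse_rare_burden(geno, maf_max = 0.01,
                               call_rate_min = 0.95,
                               min_carrier_fraction = 0.02)
cat(sprintf("burden collapsing: %d genes with >= %d carriers (of %d donors)\n",
            ncol(burden$burden), burden$min_carriers,
            nrow(burden$burden)))
write_trait_tsv(cbind(data.frame(donor_id = rownames(burden$burden)),
                      as.data.frame(burden$burden)),
                res_path("gene_burden.tsv"))
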