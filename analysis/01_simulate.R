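#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic cohort and export its genotype side.
#
# Writes the donor genotypes as VCFv4.2 with a variant annotation table
# and donor metadata; records the planted ground truth for later stages.
source("analysis/00_config.R")

st <- analysis_study()

cat(sprintf("cohort: %d donors, %d plates, %s cells, %d traits\n",
            length(unique(st$cells$donor_id)),
            length(unique(st$cells$plate_id)),
            format(nrow(st$cells), big.mark = ","),
            length(trait_names(st$cells))))
cat(sprintf("genotypes: %d variants (%d common, %d rare in %d genes)\n",
            nrow(st$genotypes$variants),
            sum(st$genotypes$variants$type == "common"),
            sum(st$genotypes$variants$type == "rare"),
            length(unique(st$genotypes$annotation$gene))))

write_genotypes_vcf(st$genotypes, res_path("genotypes.vcf"))
write_annotation_tsv(st$genotypes$annotation, res_path("annotation.tsv"))
write_trait_tsv(st$metadata, res_path("donor_metadata.tsv"))
write_trait_tsv(st$truth$registry, res_path("planted_effects.tsv"))

cat("planted effects:\n")
print(st$truth$registry, row.names = FALSE)
cat(sprintf("isolate cells: %.2f%%\n",
            100 * mean(st$cells$neighbor_count == 0)))
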