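#!/usr/bin/env Rscript
# Stage 2 — profile processing: cell and trait QC, colony/isolate split,
# well-level aggregation, inverse normal transformation, composite-trait
# selection, and donor-level pseudo-bulking.
source("analysis/00_config.R")

st <- analysis_study()

cells <- qc_cells(st$cells, max_missing_fraction = 0.05)
log1 <- attr(cells, "qc_log")
cat(sprintf("cell QC: %s of %s cells retained\n",
            format(log1$n_kept, big.mark = ","),
            format(log1$n_in, big.mark = ",")))
cells <- qc_traits(cells)

ctx <- split_context(cells)
cat(sprintf("context split: %s colony / %s isolate cells\n",
            format(nrow(ctx$colony), big.mark = ","),
            format(nrow(ctx$isolate), big.mark = ",")))

wells <- lapply(ctx, function(tab) {
  inverse_normal_transform(aggregate_wells(tab))
})
donor_all <- lapply(wells, pseudo_bulk)
composite <- select_composite_traits(lapply(donor_all, donor_correlation),
                                     threshold = 0.9)
cat(sprintf("composite traits: %d of %d retained (|r| < 0.9 in both contexts)\n",
            length(composite$traits), length(trait_names(cells))))

for (cx in names(wells)) {
  write_trait_tsv(wells[[cx]], res_path(sprintf("wells_%s.tsv", cx)))
  donors <- pseudo_bulk(wells[[cx]], composite)
  write_trait_tsv(donors, res_path(sprintf("donor_traits_%s.tsv", cx)))
  cat(sprintf("%s: %d wells -> %d donors x %d traits\n", cx,
              nrow(wells[[cx]]), nrow(donors),
              length(trait_names(donors))))
}
write_trait_tsv(data.frame(trait = composite$traits,
                           order = seq_along(composite$traits)),
                res_path("composite_traits.tsv"))
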