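#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# The real exome data behind this analysis are access-controlled, so the
# workflow runs on a simulated stand-in with the same shape: 111 trios
# screened over the three B56-family genes (true protein lengths, synthetic
# sequences), de novo events planted at per-gene per-transmission rates,
# inherited background polymorphisms for the relatedness checks, and a
# 1000-sample control series. Everything is written as plain VCF/TSV/FASTA
# under results/sim/.

suppressMessages(library(trioburden))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

fam <- synthetic_b56_family()
rates <- synthetic_rate_table(fam$models)

# Simulation rates are boosted well above the natural per-gene rates so a
# 111-trio cohort actually contains events to filter; the burden test in
# stage 3 uses the unboosted rates.
cfg <- simulation_config(
  n_trios = 111,
  genes = fam$models[, c("gene_id", "cds_length")],
  rate_per_gene = setNames(rep(5e-3, 3), fam$models$gene_id),
  n_controls = 1000,
  n_background_sites = 200,
  mean_depth = 40,
  seed = 2015L
)
cohort <- generate_trio_cohort(cfg)
controls <- generate_control_cohort(cfg, carrier_fraction = 0.001)

message(sprintf("simulated %d trios: %d calls, %d planted de novo events",
                nrow(cohort$trios), nrow(cohort$calls), nrow(cohort$truth)))
message(sprintf("simulated %d controls: %d carriers",
                nrow(controls), sum(controls$carrier)))

write_cohort_vcf(cohort, file.path(out, "cohort.vcf"))
write_variant_tsv(cohort$calls, file.path(out, "cohort_calls.tsv"))
write_truth_table(cohort$truth, file.path(out, "truth.tsv"))
utils::write.table(cohort$trios, file.path(out, "pedigree.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_rate_table(rates, file.path(out, "rates_synthetic.tsv"))
write_paralog_alignment(fam$alignment, file.path(out, "b56_synthetic.afa"))
utils::write.table(
  data.frame(gene = fam$models$gene_id, accession = fam$models$accession,
             cds_length = fam$models$cds_length,
             protein_length = fam$models$protein_length),
  file.path(out, "gene_models.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(controls, file.path(out, "controls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("inputs written under ", out)
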