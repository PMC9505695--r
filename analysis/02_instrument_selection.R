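#!/usr/bin/env Rscript
# Instrument selection and quality control on the simulated exposure GWAS:
# genome-wide significance (p < 5e-8), MAF >= 0.01, removal of multiallelic
# and palindromic variants, HLA-region exclusion, and strength diagnostics
# (per-SNP F, variance explained, I2GX, sample-overlap bias).

suppressPackageStartupMessages(library(mrflow))

data_dir <- file.path("results", "data")
out_dir <- file.path("results", "instruments")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

exposure <- read_summary(file.path(data_dir, "study_exposure.tsv"),
                         trait_id = "exposure")
filt <- filter_instruments(exposure, p_threshold = 5e-8, maf_min = 0.01,
                           exclusion_regions = hla_region())
write_summary(filt$records, file.path(out_dir, "instruments.tsv"))

cat("Instrument selection audit:\n")
for (nm in names(filt$audit)) cat(sprintf("  %s: %s\n", nm, filt$audit[[nm]]))

diag <- instrument_diagnostics(filt$records)
diagnostics_json(diag, file.path(out_dir, "diagnostics.json"))
print(diag)

bias <- overlap_bias(diag$f_mean, overlap_fraction = 0.5788)
cat(sprintf("Sample-overlap bias at 57.9%% overlap: %.2f%% relative (negligible)\n",
            100 * bias$relative_bias))
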