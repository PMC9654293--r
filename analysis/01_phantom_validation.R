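#!/usr/bin/env Rscript
# Stage 1 — phantom validation of the segmentation and banding chain.
# A ring phantom with analytically known compartment areas is generated,
# segmented and quantified: at zero HU noise every measure must be recovered
# pixel-exactly; under increasing noise the recovery error is summarized.
# Writes results/phantom_validation.csv and a mask QC overlay.

suppressPackageStartupMessages(library(l3compo))
dir.create("results", showWarnings = FALSE)
set.seed(1)

spec0 <- phantom_spec()
ph0 <- generate_phantom(spec0)
rec0 <- measure_slice(ph0$slice)
stopifnot(identical(unname(rec0$area_cm2), unname(ph0$truth)))
cat("zero-noise phantom: all 11 measures recovered exactly\n")

rows <- list()
for (sd in c(5, 10, 15)) {
  errs <- sapply(1:10, function(s) {
    sp <- phantom_spec(tissue_hu_sd = sd, seed = s)
    rec <- measure_slice(generate_phantom(sp)$slice)
    (rec$area_cm2 - ph0$truth) / ph0$truth * 100
  })
  rows[[as.character(sd)]] <- data.frame(
    noise_sd = sd, measure = rownames(errs),
    truth_cm2 = unname(ph0$truth),
    mean_rel_err_pct = rowMeans(errs),
    sd_rel_err_pct = apply(errs, 1, sd))
}
val <- do.call(rbind, c(rows, make.row.names = FALSE))
write.csv(val, "results/phantom_validation.csv", row.names = FALSE)

worst <- val[which.max(abs(val$mean_rel_err_pct)), ]
cat(sprintf("noisy recovery (10 seeds per level): worst mean error %.2f%% (%s at sd %d)\n",
            worst$mean_rel_err_pct, worst$measure, worst$noise_sd))

body <- compute_body_mask(ph0$slice)
masks <- separate_compartments(ph0$slice, body)
export_mask_png(masks, "results/phantom_masks_qc.png")
write_slice(ph0$slice, "results/phantom_slice.nii")
cat("wrote results/phantom_validation.csv, phantom_masks_qc.png, phantom_slice.nii\n")
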