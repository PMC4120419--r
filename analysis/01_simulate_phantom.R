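#!/usr/bin/env Rscript
# Simulate one default spinal-cord resting-state phantom subject and write
# the raw inputs every later stage consumes: the 4-D functional volume
# (with the planted motion applied), the tissue label map, the physio
# recording and the ground truth.

library(spinecorr)

out_dir <- file.path("results", "phantom")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- phantom_config(seed = 1L)
ph <- generate_phantom(cfg)
moved <- render_motion(ph$volume, ph$truth)

write_volume_nifti(moved, file.path(out_dir, "func.nii.gz"))
write_masks_nifti(ph$masks, file.path(out_dir, "tissue_labels.nii.gz"))
write_physio(ph$physio, file.path(out_dir, "physio.tsv"))
write_truth_json(ph$truth, file.path(out_dir, "truth.json"))

cat(sprintf("phantom subject: %d x %d x %d x %d, TR %.1f s\n",
            cfg$grid, cfg$grid, cfg$n_slices, cfg$n_volumes, cfg$tr))
cat(sprintf("planted correlations: ventral %.2f, dorsal %.2f\n",
            cfg$rho_vv, cfg$rho_dd))
cat(sprintf("max planted translation: %.2f voxels\n",
            max(abs(ph$truth$translations))))
cat("written to", out_dir, "\n")
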