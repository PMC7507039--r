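#!/usr/bin/env Rscript
# Stage 1 - simulate every input the pipeline needs.
#
# Generates (a) the DCE phantom: a 32x32x4 voxel grid with an acute-lesion
# territory (Ktrans 0.098 /min), its contralateral mirror (0.003 /min) and
# background tissue (0.007 /min), plus a sagittal-sinus strip carrying the
# blood signal, imaged with the seven-angle VFA series and 45 dynamic
# frames at SNR 50; (b) four annular vessel cross-sections spanning mild
# stenosis to near-occlusion; (c) the 36-patient aetiology cohort whose
# categorical structure matches the reference counts exactly.
#
# Outputs land under results/simulated/.

suppressPackageStartupMessages(library(vesselperm))
seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ph <- generate_phantom(seed, grid_shape = c(32, 32, 4), snr = 50)
print(ph)
write_format(ph$vfa, file.path(out, "vfa.nii.gz"), "nifti")
write_format(ph$dyn, file.path(out, "dynamic.nii.gz"), "nifti")
write_format(ph$labels + 0, file.path(out, "labels.nii.gz"), "nifti")
write_format(ph$sinus_mask + 0, file.path(out, "sinus_mask.nii.gz"), "nifti")
write_format(as.data.frame(ph$truth), file.path(out, "phantom_truth.csv"),
             "csv")
write_format(data.frame(time_s = ph$times, cp_mM = ph$aif$cp),
             file.path(out, "plasma_curve.csv"), "csv")

vs <- generate_vessel_sections(seed,
                               data.frame(la = c(10, 5, 2, 0.5),
                                          va = c(18, 12, 10, 8)),
                               pixel_spacing = 0.1)
write_format(vs$truth, file.path(out, "vessel_truth.csv"), "csv")
for (k in seq_along(vs$images))
  write_format(array(vs$images[[k]], c(dim(vs$images[[k]]), 1)),
               file.path(out, sprintf("vessel_section_%d.nii.gz", k)),
               "nifti")
cat(sprintf("vessel sections: %d images, lumen areas %s mm^2\n",
            length(vs$images), paste(vs$truth$la, collapse = ", ")))

cohort <- generate_cohort(seed)
write_format(as.data.frame(cohort), file.path(out, "cohort.csv"), "csv")
cat(sprintf("cohort: %d patients (%s)\n", nrow(cohort),
            paste(names(table(cohort$aetiology)), table(cohort$aetiology),
                  sep = " = ", collapse = ", ")))
cat("wrote", out, "\n")
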