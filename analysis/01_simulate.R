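#!/usr/bin/env Rscript
# Generate every synthetic dataset the downstream analyses consume, with
# ground truth recorded beside each artifact.

suppressMessages(library(lysoquant))
seed <- 1L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# Two-channel vesicle scenes across designed colocalization fractions.
for (frac in c(0, 0.25, 0.5, 0.75, 1)) {
  sc <- make_vesicle_scene(vesicle_scene_spec(coloc_fraction = frac,
                                              seed = seed))
  tag <- sprintf("frac%02d", round(100 * frac))
  write_stack(sc$stack_a, file.path(out, paste0("scene_", tag, "_A.tif")),
              voxel_size = c(0.3777, 0.06, 0.06))
  write_stack(sc$stack_b, file.path(out, paste0("scene_", tag, "_B.tif")),
              voxel_size = c(0.3777, 0.06, 0.06))
  write_output_csv(sc$truth, file.path(out, paste0("scene_", tag, "_truth.csv")),
                   seed = seed)
}
cat("wrote 5 vesicle scenes (fractions 0-1)\n")

# Emission-spectrum populations for every condition x ApoD class.
conds <- ph_condition_defaults()
spectra <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
  gt <- spectrum_ground_truth(condition = conds$condition[i],
                              class = conds$class[i], seed = seed + i)
  make_spectra(gt)$spectra
}))
write_output_csv(spectra, file.path(out, "emission_spectra.csv"), seed = seed)
cat("wrote", length(unique(paste(spectra$condition, spectra$class))),
    "spectral populations (30 lysosomes each)\n")

# Excitation plate, lattices, particle field.
ex <- make_excitation_readings(seed = seed)
write_output_csv(ex$wells, file.path(out, "excitation_wells.csv"), seed = seed)
write_output_csv(ex$standards, file.path(out, "excitation_standards.csv"),
                 seed = seed)
for (j in c(0, 2, 4)) {
  lat <- make_lattice_image(lattice_spec(jitter_sd = j, seed = seed))
  write_stack(lat$image, file.path(out, sprintf("lattice_jitter%d.tif", j)))
  write_output_csv(lat$truth,
                   file.path(out, sprintf("lattice_jitter%d_truth.csv", j)),
                   seed = seed)
}
pf <- make_particle_field(particle_field_spec(seed = seed))
write_stack(pf$image, file.path(out, "particles.tif"))
write_output_csv(pf$truth, file.path(out, "particles_truth.csv"), seed = seed)
cat("wrote excitation plate, 3 lattices, 1 particle field under", out, "\n")
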