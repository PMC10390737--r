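#!/usr/bin/env Rscript
# Generate one synthetic lesioned slice per condition and write the channel
# stacks as calibrated 16-bit TIFFs with ground-truth CSVs. Downstream
# scripts (02-05) quantify these images; every computation lives in the
# slicequant package.

library(slicequant)

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
presets <- condition_presets()

for (cond in names(presets)) {
  p <- presets[[cond]]
  tag <- gsub("[^A-Za-z0-9]", "_", cond)

  pi_spec <- slice_spec(pi_amplitude = p$pi_amplitude, seed = 1000 + match(cond, names(presets)))
  pi_sim <- simulate_pi_channel(pi_spec)
  write_slice_image(pi_sim$image, file.path(out, paste0(tag, "_pi.tif")),
                    pixel_size = pi_spec$pixel_size,
                    lesion_center = pi_spec$lesion_center)
  write.csv(pi_sim$ground_truth,
            file.path(out, paste0(tag, "_pi_truth.csv")), row.names = FALSE)

  nr_spec <- slice_spec(image_shape = c(800L, 800L), pixel_size = 4,
                        density_factors = p$density_factors,
                        seed = 2000 + match(cond, names(presets)))
  nr_sim <- simulate_neurite_channel(nr_spec)
  write_slice_image(nr_sim$image, file.path(out, paste0(tag, "_map2.tif")),
                    pixel_size = nr_spec$pixel_size,
                    lesion_center = nr_spec$lesion_center)
  write.csv(nr_sim$ground_truth,
            file.path(out, paste0(tag, "_map2_truth.csv")), row.names = FALSE)

  cell_spec <- slice_spec(image_shape = c(1100L, 1100L), pixel_size = 1,
                          lesion_center = c(250, 250), cell_count = 150L,
                          amoeboid_fraction_core = p$amoeboid_fraction_core,
                          amoeboid_fraction_periphery = p$amoeboid_fraction_periphery,
                          seed = 3000 + match(cond, names(presets)))
  cell_sim <- simulate_cell_channel(cell_spec)
  write_slice_image(cell_sim$image, file.path(out, paste0(tag, "_iba1.tif")),
                    pixel_size = cell_spec$pixel_size,
                    lesion_center = cell_spec$lesion_center)
  write.csv(cell_sim$ground_truth,
            file.path(out, paste0(tag, "_iba1_truth.csv")), row.names = FALSE)

  message(cond, ": PI ", paste(dim(pi_sim$image)[1:2], collapse = "x"),
          " px; ", nrow(nr_sim$ground_truth), " filaments; ",
          nrow(cell_sim$ground_truth), " cells (",
          sum(cell_sim$ground_truth$class == "amoeboid"), " amoeboid)")
}
message("channel TIFFs and ground-truth tables written to ", out)
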