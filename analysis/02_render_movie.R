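#!/usr/bin/env Rscript
# Render a synthetic two-channel TIRF movie: a static eGFP channel showing
# the motors and a blinking fluorescent-ATP channel driven by the kinetic
# simulator.  Ground truth goes to results/, image stacks to scratch/.

library(smatpase)

seed <- 202
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

camera <- camera_spec(unit_intensity = 400)
spec <- movie_spec(
  width = 64, height = 64, n_frames = 2000, camera = camera,
  psf_sigma = 0.13, background_level = 20,
  filaments = list(rbind(c(2, 5), c(15, 9)), rbind(c(4, 13), c(14, 13))),
  motor_density = 1 / 150,        # mid-range motor:monomer ratio
  off_filament_motor_rate = 0.02, # sparse surface-adsorbed motors
  shot_noise = TRUE)

# elevated fluorescent-ATP concentration so each ROI accumulates enough
# events within a short synthetic recording
truth <- place_motors(spec, seed = seed, hot_conc = 50)
movie <- render_movie(spec, truth, seed = seed + 1, egfp_intensity = 400)

scale_a <- write_stack_tiff(movie$alexa, "scratch/02_alexa647.tif")
scale_g <- write_stack_tiff(movie$egfp, "scratch/02_egfp.tif")
jsonlite::write_json(
  list(seed = seed, pixel_size_um = spec$pixel_size,
       n_frames = spec$n_frames, tiff_scale = list(alexa = scale_a,
                                                   egfp = scale_g),
       emitters = movie$truth$emitters),
  "results/02_ground_truth.json", auto_unbox = TRUE, digits = NA)
true_dwells <- unlist(movie$truth$dwells)
write_dwells_csv(dwell_sample(true_dwells, provenance = "simulated"),
                 "results/02_true_dwells.csv")

on_fil <- sum(truth$emitters$on_filament)
cat(sprintf("placed %d motors (%d on filaments, %d surface-adsorbed)\n",
            nrow(truth$emitters), on_fil, nrow(truth$emitters) - on_fil))
cat(sprintf("rendered %d frames of %dx%d px (%.1f s of recording)\n",
            spec$n_frames, spec$width, spec$height,
            spec$n_frames * camera$frame_interval))
cat(sprintf("%d true visible dwells written; mean %.3f s\n",
            length(true_dwells), mean(true_dwells)))
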