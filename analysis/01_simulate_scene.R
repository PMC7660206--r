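#!/usr/bin/env Rscript
# Build the synthetic study scene: one spring-maize season of daily weather,
# 30 quadrats with measured soil available nutrients, per-quadrat "true"
# green/brown LAI from the crop simulator, three noisy field campaigns and
# six UAV flight dates of five-band reflectance with saturation and
# late-season browning. Everything downstream reads these tables.

library(laiseason)

weather <- gen_weather(160, 140, seed = 1)       # DOY 140-299 (~20 May-26 Oct)
san <- gen_san(30, seed = 2)
scene <- gen_truth_and_obs(crop_params(), weather, san, seed = 3)

files <- write_scene_csv(scene, weather, san, "results/scene")

truth_plot <- aggregate(lai_green ~ doy, scene$truth, mean)
cat(sprintf("Season DOY %d-%d; %d quadrats; campaigns at DOY %s\n",
            min(weather$doy), max(weather$doy), nrow(san),
            paste(sort(unique(scene$field_obs$doy)), collapse = ", ")))
cat(sprintf("True plot-mean LAI: peak %.2f at DOY %d, final %.2f\n",
            max(truth_plot$lai_green),
            truth_plot$doy[which.max(truth_plot$lai_green)],
            truth_plot$lai_green[nrow(truth_plot)]))
cat(sprintf("Field LAI CV across quadrats at the campaigns: %s %%\n",
            paste(sapply(sort(unique(scene$field_obs$doy)), function(d)
              sprintf("%.1f", cv_percent(
                scene$field_obs$lai[scene$field_obs$doy == d])$cv)),
              collapse = ", ")))
cat("Wrote:", paste(basename(files), collapse = ", "), "to results/scene/\n")
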