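#!/usr/bin/env Rscript
# Per-campaign vegetation-index screening: correlation of each of the five
# indices with field LAI per campaign date (with significance classes), the
# winning index and its linear LAI model per date, and the spatial CV of
# each index per date as a saturation diagnostic (a shrinking CV late in
# the season means the index no longer resolves the LAI variation).

library(laiseason)

weather <- read.csv("results/scene/weather.csv")
refl <- read.csv("results/scene/reflectance.csv")
obs <- read.csv("results/scene/field_obs.csv")

campaigns <- sort(unique(obs$doy))
cor_rows <- list(); cv_rows <- list(); model_rows <- list()
for (d in campaigns) {
  m <- merge(refl[refl$doy == d, ], obs[obs$doy == d, c("quadrat_id", "lai")],
             by = "quadrat_id")
  fits <- lapply(vi_names(), function(ix)
    fit_linear_model(compute_vi(m, ix), m$lai, ix))
  names(fits) <- vi_names()
  cor_rows[[as.character(d)]] <- data.frame(
    doy = d, n = nrow(m),
    t(sapply(fits, function(f) sprintf("%.2f %s", f$r,
                                       sub("ns", "", f$significance)))))
  cv_rows[[as.character(d)]] <- data.frame(
    doy = d, field_lai = cv_percent(m$lai)$cv,
    t(sapply(vi_names(), function(ix) cv_percent(compute_vi(m, ix))$cv)))
  best <- select_best_vi(fits)
  bf <- fits[[best]]
  model_rows[[as.character(d)]] <- data.frame(
    doy = d, index = best, slope = bf$a, intercept = bf$b, r = bf$r,
    n = bf$n, significance = bf$significance)
}
cors <- do.call(rbind, cor_rows)
cvs <- do.call(rbind, cv_rows)
models <- do.call(rbind, model_rows)

dir.create("results", showWarnings = FALSE)
write.csv(cors, "results/vi_correlations.csv", row.names = FALSE)
write.csv(cvs, "results/vi_cv.csv", row.names = FALSE)
write.csv(models, "results/vi_models.csv", row.names = FALSE)

cat("Index-LAI correlations per campaign (r, ** p<0.01, * p<0.05):\n")
print(cors, row.names = FALSE)
cat("\nSelected index per campaign:\n")
print(models[, c("doy", "index", "slope", "intercept", "r")],
      row.names = FALSE)
cat("\nSpatial CV (%) per index and campaign (saturation diagnostic):\n")
print(cvs, digits = 3, row.names = FALSE)
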