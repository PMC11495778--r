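#!/usr/bin/env Rscript
# Stage 3: pool the location curves with the multivariate random-effects
# meta-regression (REML) and derive each location's BLUP.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_config.R"))
cfg <- analysis_config()

run_pipeline(cfg, stages = "meta")

psi <- as.matrix(read.csv(file.path(cfg$out_dir, "results", "meta_psi.csv")))
beta <- read.csv(file.path(cfg$out_dir, "results", "meta_beta.csv"))
cat("Pooled fixed effects (rows = curve coefficients):\n")
print(beta, digits = 3)
cat(sprintf("Between-location heterogeneity: tr(Psi) = %.4f, leading SD = %.3f.\n",
            sum(diag(psi)), sqrt(max(diag(psi)))))
fs <- read_curves(file.path(cfg$out_dir, "results", "curves_first_stage.csv"))
bl <- read_curves(file.path(cfg$out_dir, "results", "curves_blup.csv"))
shrink <- mean(vapply(names(fs), function(id)
  sqrt(sum((bl[[id]]$coef - fs[[id]]$coef)^2) / sum(fs[[id]]$coef^2)), 0))
cat(sprintf("Mean relative coefficient shrinkage from first stage to BLUP: %.1f%%.\n",
            100 * shrink))
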