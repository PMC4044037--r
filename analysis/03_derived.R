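#!/usr/bin/env Rscript
# Downstream analyses of the fitted model: cohort survival from age 1 to 4
# with credible bands, recruits per 0-group, interannual variance by life
# stage, year-class strength ratios, bootstrap abundance-survival
# correlations, predicted age-class relationships, and the
# temperature-recruit table. Reads the samples written by 02_fit.R and the
# truth record from 01_simulate.R.

library(codcycle)

d <- load_dataset("results/dataset")
samples <- read.csv("results/posterior_samples.csv", check.names = FALSE)
truth <- read.csv("results/truth_series.csv")
dir.create("results", showWarnings = FALSE)

N_true <- t(as.matrix(truth[paste0("N", 1:9)]))
dimnames(N_true) <- list(age = 1:9, year = truth$year)
lat <- list(N = N_true, SSB = truth$SSB, eggs = truth$eggs,
            larvae = truth$larvae, zerogroup = truth$zerogroup,
            ages = d$ages)
class(lat) <- "latent_state"

# survival age 1 -> 4 per cohort, draw by draw (parameter correlations kept)
s14 <- survival_1to4(samples, N_true)
write.csv(s14, "results/survival_1to4.csv", row.names = FALSE)
cat(sprintf("survival age 1->4: median of cohort medians %.3f (range %.3f-%.3f)\n",
            median(s14$median), min(s14$median), max(s14$median)))

rp <- recruits_per_0group(lat)
write.csv(rp, "results/recruits_per_0group.csv", row.names = FALSE)
cat(sprintf("recruits per 0-group vs 0-group abundance: rank correlation %.2f\n",
            cor(rp$zerogroup, rp$recruits_per_0group, method = "spearman")))

v <- variance_by_stage(lat)
write.csv(data.frame(stage = names(v), variance = v),
          "results/variance_by_stage.csv", row.names = FALSE)
cat("interannual variance of log abundance by stage:\n")
print(round(v, 2))

yc <- data.frame(age = 1:4,
                 ratio = vapply(1:4, function(a) yearclass_ratio(N_true[a, ]),
                                numeric(1)))
write.csv(yc, "results/yearclass_ratios.csv", row.names = FALSE)
cat(sprintf("year-class max/min ratio: %.1f-fold at age 1, %.1f-fold at age 4\n",
            yc$ratio[1], yc$ratio[4]))

boot <- do.call(rbind, lapply(2:3, function(a) {
  r <- bootstrap_survival_correlation(d$obs$index_winter, a,
                                      n_boot = 10000, seed = a)
  data.frame(age = a, estimate = r$estimate, median = r$median,
             lower = r$ci[1], upper = r$ci[2], n_pairs = r$n_pairs)
}))
write.csv(boot, "results/bootstrap_survival_correlation.csv",
          row.names = FALSE)
cat("bootstrap abundance-survival correlations (ages 2-3):\n")
print(boot, digits = 2, row.names = FALSE)

for (a in 1:3) {
  curve <- predicted_ageclass_curve(samples, a,
                                    grid = seq(5e7, 5e9, length.out = 60))
  write.csv(curve, sprintf("results/ageclass_curve_age%d.csv", a),
            row.names = FALSE)
}

tr <- temp_recruit_table(lat, d$covars)
write.csv(tr, "results/temp_recruit.csv", row.names = FALSE)
cat("wrote derived tables under results/\n")
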