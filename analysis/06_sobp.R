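#!/usr/bin/env Rscript
# Spread-out Bragg peak irradiation: broad vaporization zone across the
# modulation span with a distal peak matching the pristine 180 mm peak.

library(ndvap)
dir.create("results/sobp", recursive = TRUE, showWarnings = FALSE)

sb <- run_experiment(experiment_config("sobp", seed = 4))
write_profile(sb$profile, "results/sobp/sobp_profile.csv")
write_profile(sb$pristine$profile, "results/sobp/pristine_profile.csv")
write_depth_dose(sb$sobp_curve, "results/sobp/sobp_depth_dose.csv")

pristine_fit <- fit_peak(sb$pristine$profile)
cat(sprintf("distal vaporization peak: %.2f mm; pristine fitted x_c: %.2f mm (diff %.2f mm)\n",
            sb$distal_peak_position, pristine_fit$x_c,
            abs(sb$distal_peak_position - pristine_fit$x_c)))
span <- sb$profile$position >= 161 & sb$profile$position <= 175
cat(sprintf("mean contrast over the modulation span: SOBP %.1f vs pristine %.1f grey\n",
            mean(sb$profile$mean_grey[span]),
            mean(sb$pristine$profile$mean_grey[span])))
cat(sprintf("distal fall50: SOBP %.2f mm, pristine %.2f mm\n",
            distal_fall50(sb$profile), distal_fall50(sb$pristine$profile)))

png("results/sobp/sobp_vs_pristine.png", 900, 500)
plot(sb$profile$position, sb$profile$mean_grey, type = "l", lwd = 2,
     xlab = "beam-axis depth (mm)", ylab = "background-subtracted grey",
     main = "SOBP vs pristine 1 Gy vaporization profiles")
lines(sb$pristine$profile$position, sb$pristine$profile$mean_grey,
      col = "red", lwd = 2)
legend("topleft", c("SOBP", "pristine 180 mm"), col = c("black", "red"), lwd = 2)
dev.off()
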