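#!/usr/bin/env Rscript
# Carbon-11 decay arithmetic for the delayed second injection: residual molar
# activity and activity after the stagger, against the 20 GBq/umol
# application limit and a weight-based dose.

library(dualtracer)
dir.create("results", showWarnings = FALSE)

rows <- do.call(rbind, lapply(c(15, 30, 45, 60), function(d) {
  fc <- feasibility_check(decay_plan(delay = d, half_life = 20,
                                     molar_activity = 100, activity = 2.0,
                                     dose_per_kg = 4.51, weight = 75))
  data.frame(delay_min = d,
             half_lives = fc$half_lives,
             molar_activity_gbq_umol = round(fc$molar_activity, 2),
             remaining_activity_mbq = round(fc$remaining_activity_mbq, 1),
             required_dose_mbq = fc$required_dose_mbq,
             pass = fc$pass)
}))
write.table(rows, "results/dose_plan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(rows, row.names = FALSE)
cat("\nAt a 45-min delay (2.25 half-lives) a 100 GBq/umol batch lands at\n")
cat("21 GBq/umol -- just above the 20 GBq/umol application limit -- and a\n")
cat("2 GBq batch still covers the 338 MBq dose of a 75-kg subject.\n")
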