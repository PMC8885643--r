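#!/usr/bin/env Rscript
# Separates one subject's dual measurements by tail extrapolation and
# subtraction, for all three staggers and both orders, and reports which
# protocols a 2TCM/tri-exponential extrapolation can actually resolve.

library(dualtracer)
dir.create("results", showWarnings = FALSE)

cohort <- make_cohort(n_pairs = 8, seed = 1)
cfg <- attr(cohort, "config")
s_har <- resample_scan(generate_single_scan(cohort[[1]], "HAR", cfg, seed = 101))
s_dasb <- resample_scan(generate_single_scan(cohort[[1]], "DASB", cfg, seed = 102))

status <- data.frame()
for (ord in list(c("HAR", "DASB"), c("DASB", "HAR"))) {
  first <- if (ord[1] == "HAR") s_har else s_dasb
  second <- if (ord[2] == "HAR") s_har else s_dasb
  for (d in c(15, 30, 45)) {
    dual <- build_dual_measurement(first, second, dual_protocol(ord[1], ord[2], d))
    sep <- separate(dual)
    tb <- sep$diagnostics$table
    status <- rbind(status, data.frame(
      order = paste(ord, collapse = "-"), stagger_min = d,
      status = sep$status, n_nonconverged = sum(!tb$converged),
      max_rel_unc_at_90 = round(max(tb$rel_unc_end), 3),
      clipped_integral_total = round(sum(sep$clipped_integral), 3)))
    if (d == 45) {
      write_tac_file(sep$est_second$tacs,
                     sprintf("results/S01_est_%s_tac.tsv", ord[2]))
    }
  }
}
write.table(status, "results/separation_status.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(status, row.names = FALSE)
cat("\nOnly the 45-min stagger separates reliably; short staggers leave the\n")
cat("first tracer's tail under-determined (flagged failed_separation).\n")
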