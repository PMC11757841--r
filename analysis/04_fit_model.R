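#!/usr/bin/env Rscript
# Fit the country-nested random-intercept logistic regression of booster
# willingness on age, gender, education, relative income, essential-worker
# status, psychological distress, intolerance of uncertainty and delay
# discounting (AuC), and compare it to the intercept-only model with a
# likelihood ratio test.

library(boosterdd)

out_dir <- "results/04_fit"
cohort_csv <- "results/03_score/cohort_scored.csv"
if (!file.exists(cohort_csv)) stop("Run analysis/03_score.R first.")

res <- pipeline_fit(cohort_csv, out_dir = out_dir)

print(res$fit)
print(res$lrt)
cat("\nCoefficient table written to", file.path(out_dir, "model_coefficients.csv"), "\n")
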