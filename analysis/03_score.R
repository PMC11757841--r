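#!/usr/bin/env Rscript
# Score the generated cohort: apply the outcome coding (vaccination 1-2 =
# vaccinated, 3-4 = not, 5 = missing; booster 0/1/2 with 2 = missing), run
# the exclusion pipeline (unvaccinated first, then missing booster answers),
# and re-standardize the psychological distress index within the analytic
# sample.

library(boosterdd)

out_dir <- "results/03_score"
cohort_csv <- "results/02_cohort/cohort.csv"
if (!file.exists(cohort_csv)) stop("Run analysis/02_generate_cohort.R first.")

scored <- pipeline_score(cohort_csv, out_dir = out_dir)

cat("Exclusion pipeline:\n")
print(scored$exclusions, row.names = FALSE)
cat(sprintf("Analytic sample: %d participants; distress index mean %.2g (sd %.2f)\n",
            nrow(scored$cohort), mean(scored$cohort$distress),
            sd(scored$cohort$distress)))

# the inter-rater agreement utility, shown on a synthetic coding table of
# two raters assigning 100 free-text reasons to six categories
set.seed(20260923)
true_cat <- sample(1:6, 100, replace = TRUE, prob = c(.25, .3, .15, .15, .1, .05))
rater2 <- ifelse(runif(100) < 0.9, true_cat, sample(1:6, 100, replace = TRUE))
tab <- table(factor(true_cat, 1:6), factor(rater2, 1:6))
ag <- rater_agreement(tab)
cat(sprintf("Synthetic rater pair: %.0f%% agreement, Cohen's kappa = %.2f\n",
            100 * ag$percent_agreement, ag$kappa))
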