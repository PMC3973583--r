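#!/usr/bin/env Rscript
# Summarize the survival assay and estimate the LC50 by the logarithmic
# trendline (OLS of mean survival fraction on ln concentration, solved at
# 50% survival); compare stocks via resistance ratios.

library(amaresist)

dr <- read_dose_response("results/synthetic/dose_response.tsv")
fit <- fit_log_trend(dr)

write_tsv(fit$summary, "results/dose_response_curve.tsv")
write_tsv(data.frame(slope = fit$slope, intercept = fit$intercept,
                             lc50 = fit$lc50, qc_pass = fit$qc_pass),
                  "results/lc50_fit.tsv")

print(fit)
cat(sprintf("true LC50 was 2.0; relative error %.1f%%\n",
            100 * abs(fit$lc50 - 2) / 2))
# printed stock comparison: resistant 2.16 vs sensitive 0.028 ug/g
cat(sprintf("resistance ratio of the published stocks: %.1f\n",
            resistance_ratio(2.16, 0.028)))
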