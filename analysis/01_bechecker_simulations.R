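#!/usr/bin/env Rscript
# Simulates the transfer-dissolution apparatus for every experimental
# condition using the published fitted rate constants: 3 paddle speeds for
# metoprolol (10 min infusion) and 3 infusion times x 3 paddle speeds for
# dipyridamole (with intestinal-phase precipitation and the ionization /
# micelle corrections to permeation). Writes the sampled time courses to
# results/bechecker_timecourses.csv.

library(bepbbm)

fx <- builtin_fixtures()
dir.create("results", showWarnings = FALSE)

conditions <- rbind(
  data.frame(drug = "metoprolol", infusion = 10, rpm = c(50, 100, 200)),
  expand.grid(drug = "dipyridamole", infusion = c(10, 20, 30),
              rpm = c(50, 100, 200), stringsAsFactors = FALSE))

all_rows <- list()
cat(sprintf("%-13s %4s %4s | %9s %9s %9s\n", "drug", "inf", "rpm",
            "diss120 %", "perm120 %", "prec120 %"))
for (i in seq_len(nrow(conditions))) {
  cn <- conditions[i, ]
  drug <- fixture_drug(fx, cn$drug)
  prot <- fixture_protocol(fx, cn$drug, cn$infusion, cn$rpm)
  par <- fixture_kinetic_params(fx, cn$drug, cn$infusion, cn$rpm)
  corr <- cn$drug == "dipyridamole"
  tc <- simulate_bechecker(prot, drug, par, dt = 0.05, sample_every = 20,
                           use_fmol = corr, use_fmic = corr)
  last <- tc[nrow(tc), ]
  cat(sprintf("%-13s %4d %4d | %8.1f%% %8.2f%% %8.1f%%\n",
              cn$drug, cn$infusion, cn$rpm,
              100 * last$dissolved_mg / prot$dose,
              100 * last$permeated_mg / prot$dose,
              100 * last$precipitated_mg / prot$dose))
  tc$drug <- cn$drug; tc$infusion_min <- cn$infusion; tc$rpm <- cn$rpm
  all_rows[[i]] <- as.data.frame(tc)
}

out <- do.call(rbind, all_rows)
write.csv(out, "results/bechecker_timecourses.csv", row.names = FALSE)
cat("\nReceiver-side permeation stays a small percent of dose in all",
    "conditions, far below the in-vivo fraction absorbed -- the motivation",
    "for translating these curves through a physiology-based model rather",
    "than reading them directly.\n")
cat("Wrote results/bechecker_timecourses.csv\n")
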