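#!/usr/bin/env Rscript
# Stage 4: exact-mass verification of the indole-isonitrile intermediate,
# 3-(2-isocyanovinyl)indole (C11H8N2): the neutral monoisotopic mass a
# HRESI-MS measurement should match, and the nominal [M-H] ion seen in
# negative-mode LC-MS.

suppressPackageStartupMessages(library(hapalocompare))

formula <- "C11H8N2"
mono <- monoisotopic_mass(formula)
mh <- nominal_ion_mz(formula, "M-H")

cat("Indole-isonitrile", formula, "\n")
cat("  expected monoisotopic mass:", sprintf("%.4f Da", mono), "\n")
cat("  nominal [M-H] ion m/z:     ", mh, "\n")

# example instrument readings scored against the expectation
for (obs in c(168.0689, 168.0685)) {
  cat(sprintf("  observed %.4f -> %.2f ppm from expected\n",
              obs, ppm_difference(obs, mono)))
}

dir.create("results/report", recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(
  list(formula = formula, monoisotopic_mass_da = mono, nominal_m_minus_h = mh),
  "results/report/mass_check.json", auto_unbox = TRUE, digits = NA)
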