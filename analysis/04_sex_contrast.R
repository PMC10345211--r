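#!/usr/bin/env Rscript
# Stage 4: sex contrast.
#
# Pairs female and male pool-2 signals per (drug, event), applies the 2:1
# IC025 dominance filter, and extracts the top sex-specific adverse events
# and the top contributing drugs.

library(vigiprof)
library(dplyr)

pool2 <- read_pool("results/pool2.tsv")
paired <- pair_signals(pool2[pool2$sex == "female", ],
                       pool2[pool2$sex == "male", ])
cls <- classify_pairs(paired, threshold = 2)
readr::write_tsv(mutate(cls, class = as.character(class)),
                 "results/sex_contrast.tsv")

cat("pair classification:\n")
print(table(cls$class))

filtered <- ratio_filter(paired, threshold = 2)
for (sx in c("female", "male")) {
  top <- top_sex_specific(filtered, sx, k = 20)
  readr::write_tsv(top$top, sprintf("results/top_ae_%s.tsv", sx))
  drugs <- top_contributing_drugs(filtered, sx, k = 10)
  readr::write_tsv(drugs, sprintf("results/top_drugs_%s.tsv", sx))
  cat(sprintf("\n%s-dominant: %d AEs with a >= 2:1 signal in both sexes\n",
              sx, nrow(top$top)))
  only <- top_sex_specific(filtered, sx, k = 20, which = "only")
  readr::write_tsv(only$top, sprintf("results/top_ae_%s_only.tsv", sx))
  cat(sprintf("top %s-only signals (absent from the other sex's pool 2):\n",
              sx))
  print(head(only$top, 5))
}
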