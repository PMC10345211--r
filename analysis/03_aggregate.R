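#!/usr/bin/env Rscript
# Stage 3: hierarchy aggregation.
#
# Sums screened signals up the toy hierarchy: ScIC025 per SOC and HLG,
# drug rankings within the top SOC, the adverse-event decomposition of the
# busiest HLG, and drug/report percentage tables.

library(vigiprof)
library(dplyr)

screened <- read_pool("results/pool1.tsv")
map <- readr::read_tsv("results/data/meddra_toy.tsv", show_col_types = FALSE)
rows <- load_reports("results/data/reports.tsv", quiet = TRUE)

sc_soc <- scic025_table(screened, map, level = "soc")
sc_hlg <- scic025_table(screened, map, level = "hlg")
readr::write_tsv(mutate(sc_soc, sex = as.character(sex)),
                 "results/scic025_soc.tsv")
readr::write_tsv(mutate(sc_hlg, sex = as.character(sex)),
                 "results/scic025_hlg.tsv")
cat("ScIC025 per SOC:\n"); print(sc_soc, n = Inf)

top_soc <- sc_soc$group[which.max(sc_soc$scic025)]
ranked <- rank_drugs(screened, map, top_soc, level = "soc", top_k = 10)
readr::write_tsv(mutate(ranked, sex = as.character(sex)),
                 "results/top_drugs_top_soc.tsv")
cat(sprintf("\ntop drugs in '%s' (by cIC025, ties alphabetical):\n", top_soc))
print(ranked, n = Inf)

# drug percentages within the top SOC (female stratum shown)
f <- screened[screened$sex == "female", ]
drugs <- unique(ranked$drug[ranked$sex == "female"])
pct <- tibble::tibble(
  drug = drugs,
  pct = vapply(drugs, function(d) drug_percentage(f, map, d, top_soc),
               numeric(1)))
cat(sprintf("\nfemale drug percentages in '%s' (top drugs):\n", top_soc))
print(arrange(pct, desc(pct)))

top_hlg <- sc_hlg$group[which.max(sc_hlg$scic025)]
dec <- decompose_group(screened, map, top_hlg, level = "hlg")
readr::write_tsv(mutate(dec, sex = as.character(sex)),
                 "results/decomposition_top_hlg.tsv")
cat(sprintf("\n'%s' decomposes into %d contributing PTs\n",
            top_hlg, dplyr::n_distinct(dec$pt)))
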