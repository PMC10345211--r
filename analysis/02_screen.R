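#!/usr/bin/env Rscript
# Stage 2: disproportionality analysis and screening.
#
# Scores every (drug, event) pair per sex (pool 1: IC, IC025, PRR, ROR)
# and screens with PRR > 2, IC025 > 0 and at least five records (pool 2).
# With the stage-1 conditions, every injected pair should pass the screen
# and almost no null pair should.

library(vigiprof)
library(dplyr)

rows <- load_reports("results/data/reports.tsv", quiet = TRUE)
inj <- readr::read_tsv("results/data/injections.tsv", show_col_types = FALSE)

strata <- split_by_sex(rows)
pool1 <- bind_rows(lapply(strata, score_all_pairs))
screened <- screen_signals(pool1, keep_all = TRUE)
pool2 <- filter(screened, in_pool2)

write_pool(screened, "results/pool1.tsv")
write_pool(pool2, "results/pool2.tsv")

cat(sprintf("pool 1: %d records (%d drugs); pool 2: %d records (%d drugs)\n",
            nrow(pool1), dplyr::n_distinct(pool1$drug),
            nrow(pool2), dplyr::n_distinct(pool2$drug)))
hit <- semi_join(pool2, inj, by = c("drug", "pt"))
expected <- sum(ifelse(inj$sex == "both", 2L, 1L))
cat(sprintf("injected (drug, pt, sex) signals recovered in pool 2: %d / %d\n",
            nrow(hit), expected))
print(arrange(select(hit, sex, drug, pt, a, ic025, prr), drug, sex),
      n = Inf)
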