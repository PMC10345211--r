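#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic report table.
#
# Emulates a curated spontaneous-report extract: 30 drugs and 150 preferred
# terms with Zipf-shaped marginals, 200,000 drug-event combinations per sex,
# and five injected drug x event signals (reporting-rate multipliers 4, 8
# and 16) whose ground truth the later stages must recover. A toy 3-SOC
# hierarchy covers the PT vocabulary.

library(vigiprof)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# both-sex signals plus one male-only and one female-only signal, so the
# sex-contrast stage has ground truth to recover
inj <- rbind(study_injections(),
             data.frame(drug = c("drug007", "drug009"),
                        pt = c("pt040", "pt050"),
                        sex = c("male", "female"), lam = 8))
cfg <- default_sim_config(n_reports = 2e5, injections = inj, seed = seed)
rows <- generate_reports(cfg)
map <- toy_hierarchy_for(cfg)

write_reports(rows, file.path(out, "reports.tsv"))
readr::write_tsv(map, file.path(out, "meddra_toy.tsv"))
readr::write_tsv(inj, file.path(out, "injections.tsv"))

cat(sprintf("simulated %d combinations (%d female, %d male) over %d drugs x %d PTs\n",
            sum(rows$count), sum(rows$count[rows$sex == "female"]),
            sum(rows$count[rows$sex == "male"]),
            length(cfg$drugs), length(cfg$pts)))
cat(sprintf("injected %d ground-truth signals, lam in {%s}\n",
            nrow(inj), paste(sort(unique(inj$lam)), collapse = ", ")))
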