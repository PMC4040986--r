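#!/usr/bin/env Rscript
# Stage 3 — single-copy marker census: completeness and contamination per
# bin (percent of the 105-marker set found, and found in > 1 copy), plus
# the >60% / <10% quality gate.

# run from the repository root: Rscript analysis/03_census.R
source("analysis/00_config.R")

inp <- file.path(RESULTS, "01_simulate")
out <- file.path(RESULTS, "03_census")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bins <- read_tsv(file.path(RESULTS, "02_bin", "bins.tsv"))
hits <- read_tsv(file.path(inp, "marker_hits.tsv"))

tab <- census_table(bins, hits,
                    min_completeness = CFG$min_completeness,
                    max_contamination = CFG$max_contamination)
write_tsv(tab, file.path(out, "census.tsv"))

print(tab, row.names = FALSE)
cat(sprintf("%d/%d bins pass the quality gate (>%g%% complete, <%g%% contaminated)\n",
            sum(tab$gate), nrow(tab), CFG$min_completeness,
            CFG$max_contamination))
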