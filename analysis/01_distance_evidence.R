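#!/usr/bin/env Rscript
# Stage 1: whole-mitogenome K2P distance evidence for the Narino cat.
# Ranks all taxa in the packaged 14-taxon distance table by divergence from
# the focal lineage and flags them against the 6-11% species band, writing
# both tables under results/.

suppressPackageStartupMessages(library(felidelim))
dir.create("results", showWarnings = FALSE)

m <- table1_fixture()
nt <- nearest_taxa(m, "Narino_cat", exclude = c("F_catus", "H_yagouaroundi"))
write.csv(nt, "results/01_narino_nearest_taxa.csv", row.names = FALSE)

tr <- threshold_report(m, "Narino_cat", threshold_band(6, 11, "mitogenome"),
                       exclude = c("F_catus", "H_yagouaroundi"))
write.csv(tr$flags, "results/01_narino_threshold_flags.csv",
          row.names = FALSE)

cat("Nearest taxa to the Narino cat (percent K2P):\n")
print(head(nt, 5), row.names = FALSE)
cat("\nBand 6-11%:", paste(names(tr$counts), tr$counts, collapse = ", "),
    "\n")
cat("\nFinding: the closest taxa sit at 5.6% (Central American and",
    "trans-Andean tigrina) and 5.8% (L. geoffroyi) - above divergences",
    "separating several accepted species pairs (2.0%, 4.4%, 5.0%), though",
    "below the 6-11% band itself.\n")
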