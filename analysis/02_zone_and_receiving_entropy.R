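#!/usr/bin/env Rscript

# Step 2: zone distribution, standard entropy by point outcome, and the
# receiving-zone entropy profile.
#
# Reads scratch/corpus.csv (run 01_generate_corpus.R first). Writes:
#   results/zone_pdf.csv            pooled strike shares per zone
#   results/standard_entropy_won_lost.csv  per-match paired entropies
#   results/receiving_profile.csv   mean receiving entropy per origin zone

suppressPackageStartupMessages(library(strikentropy))
dir.create("results", showWarnings = FALSE)

corpus <- read_stroke_log("scratch/corpus.csv")

pdf <- zone_pdf(corpus)
write.csv(data.frame(zone = 1:12, count = pdf$counts, p = pdf$p),
          "results/zone_pdf.csv", row.names = FALSE)
cat("zone shares (%): ", paste(sprintf("%d:%.1f", 1:12, 100 * pdf$p),
                               collapse = " "), "\n")
cat(sprintf("corner zones 1+4+9+12 hold %.1f%% of all strokes\n",
            100 * sum(pdf$p[c(1, 4, 9, 12)])))

std <- per_match_entropy(corpus, "won_vs_lost", "standard")
test <- paired_t_test(std$H1, std$H2)
write.csv(std, "results/standard_entropy_won_lost.csv", row.names = FALSE)
cat(sprintf("standard entropy, won vs lost strokes: %.4f vs %.4f, t(%d) = %.2f, p = %.3g\n",
            test$mean1, test$mean2, test$df, test$t, test$p_value))
cat(sprintf("mean per-match standard entropy (all strokes): %.4f\n",
            mean(vapply(split(corpus$zone, corpus$match_id),
                        function(z) standard_entropy(zone_distribution(z)),
                        numeric(1)))))

rp <- receiving_profile(corpus)
write.csv(rp$profile, "results/receiving_profile.csv", row.names = FALSE)
lo <- order(rp$profile$mean_H)[1:2]
hi <- order(-rp$profile$mean_H)[1:2]
cat(sprintf("receiving entropy: lowest in zones %s, highest in zones %s\n",
            paste(rp$profile$zone[lo], collapse = ", "),
            paste(rp$profile$zone[hi], collapse = ", ")))
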