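#!/usr/bin/env Rscript
# Step 4 — cross-disease drug overlaps and target overrepresentation.
#
# Four drug groups exist per disease pair: beneficial (indicated) and
# harmful (contraindicated or adverse-inducing, pooled) for each disease,
# with paradoxical-reaction drugs removed from the harmful side only.
# Two questions are asked: do drugs that treat one disease harm the other
# more often than chance (one-sided Fisher over the drug universe), and
# which target genes are overrepresented within each group against the
# background of all drugs with human targets (BH-corrected per group)?

suppressMessages(library(comorbnet))

bundle <- readRDS("results/bundle.rds")
cfg <- bundle$config
dA <- cfg$diseases[1]; dB <- cfg$diseases[2]

cd <- bundle$cross_drugs
cat(sprintf("%d drugs beneficial for %s and harmful for %s (p = %.3g): %s\n",
            length(cd$A_ben_B_harm), dA, dB, cd$test_AB$p,
            paste(cd$A_ben_B_harm, collapse = ", ")))
cat(sprintf("%d drugs beneficial for %s and harmful for %s (p = %.3g)\n",
            length(cd$B_ben_A_harm), dB, dA, cd$test_BA$p))
for (tag in names(bundle$drug_target_overrep)) {
  df <- bundle$drug_target_overrep[[tag]]
  sig <- df[df$significant, , drop = FALSE]
  cat(sprintf("group %s: %d drugs, %d target genes tested, %d overrepresented%s\n",
              tag, df$n[1], nrow(df), nrow(sig),
              if (nrow(sig)) paste0(": ", paste(sig$term, collapse = ", "))
              else ""))
}
cat("full tables in results/pipeline/drug_target_overrep.tsv and drug_overlap.json\n")
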