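#!/usr/bin/env Rscript
# Collate the per-run analyses into one markdown report at results/report.md.
# No numbers are computed here; everything is read back from the tables the
# earlier scripts wrote.

suppressMessages(library(pipbind))

labels <- c("I", "II", "III")
lines <- c("# Synthetic membrane-association study", "")
for (label in labels) {
  tl <- read_result_tsv(file.path("results/contacts", label, "timeline.tsv"))
  lc <- read_result_tsv(file.path("results/contacts", label,
                                  "lipid_comparison.tsv"))
  st <- read_result_tsv(file.path("results/contacts", label,
                                  "stoichiometry.tsv"))
  rt <- read_result_tsv(file.path("results/contacts", label,
                                  "residue_contacts.tsv"))
  lines <- c(lines, sprintf("## Run %s", label), "",
             sprintf("- frames: %d; bound to PIP2: %.1f%% of frames",
                     nrow(tl), 100 * mean(tl$bound)),
             sprintf("- bound to: PIP2 %.1f%%, DOPC %.1f%% of frames",
                     lc$pct_time_binding[lc$class == "PIP2"],
                     lc$pct_time_binding[lc$class == "DOPC"]),
             sprintf("- stoichiometry (%% of bound frames): %s",
                     paste(sprintf("n_P=%s: %.1f", st$n_P, st$pct),
                           collapse = ", ")),
             local({
               rt2 <- rt[rt$n_i > 0 & !is.na(rt$x_i), ]
               if (nrow(rt2) == 0) return("- top residues by x_i: (never bound)")
               sprintf("- top residues by x_i: %s",
                       paste(head(rt2$label[order(-rt2$x_i)], 6),
                             collapse = " "))
             }),
             "")
}
sel <- read_result_tsv("results/contacts/selected_residues.tsv")
refsel <- read_result_tsv("results/contacts/reference_selected_residues.tsv")
po <- read_result_tsv("results/spatial/pose_classes.tsv")
lines <- c(lines, "## Across runs", "",
           sprintf("- selected binding residues (rule: x_i > 5%% twice or > 10%% once): %s",
                   paste(sel$residue, collapse = " ")),
           sprintf("- reference matrix selection reproduces %d residues: %s",
                   nrow(refsel), paste(refsel$residue, collapse = " ")),
           "", "### Pose classes (% of bound frames)", "")
for (label in labels) {
  pr <- po[po$run == label, ]
  lines <- c(lines, sprintf("- run %s: %s", label,
                            paste(sprintf("%s %.1f", pr$pose, pr$pct),
                                  collapse = ", ")))
}
writeLines(lines, "results/report.md")
cat(lines, sep = "\n")
cat("\nreport written to results/report.md\n")
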