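#!/usr/bin/env Rscript
# Stage 3 -- per-reaction flux changes between conditions.
#
# Classifies each reaction's flux change (ratio threshold 20%, antisym-
# metric rule) for the two condition pairs of the study design: the pH
# shift (neutral vs acidic, 2 g/l succinate) and the succinate dose
# (2 vs 4 g/l at acidic pH), then groups the classes by pathway.
#
# Expects the flux solutions from 02_simulate_fluxes.R under results/.

suppressPackageStartupMessages(library(fluxgaba))

cfg <- run_config(list(output_dir = "results"))
pairs <- list(
  ph_shift = c("fluxes_neutral_2gl", "fluxes_acidic_2gl"),
  succinate_dose = c("fluxes_acidic_2gl", "fluxes_acidic_4gl"))

for (nm in names(pairs)) {
  stems <- file.path("results", pairs[[nm]])
  if (!all(file.exists(paste0(stems, ".tsv"))))
    stop("run analysis/02_simulate_fluxes.R first")
  ch <- run_compare(cfg, stems[1], stems[2], name = nm)
  sm <- summarize_by_pathway(ch, read_pathway_map(cfg$pathway_map))
  cat(sprintf("\n== %s (threshold %.0f%%) ==\n", nm, 100 * cfg$threshold))
  cols <- c("pathway", "n_reactions", "induced", "suppressed",
            "unchanged", "inverted", "de-novo", "abolished")
  print(sm[, cols], row.names = FALSE)
  for (rid in c("GLUDC", "GLUDy", "ICDHyr", "SUCOAS", "PTAr"))
    cat(sprintf("  %-7s %10.6f -> %10.6f  %s\n", rid,
                ch$flux_a[ch$reaction_id == rid],
                ch$flux_b[ch$reaction_id == rid],
                ch$class[ch$reaction_id == rid]))
}
cat("\nChange tables and pathway summaries written under results/\n")
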