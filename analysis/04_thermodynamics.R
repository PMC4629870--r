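#!/usr/bin/env Rscript
# Stage 4: in-situ Gibbs free energies of the six bundled catabolic
# reactions across the measured (temperature, time) grid; a reaction is
# "open" when dG'r clears the bioenergetic threshold.

library(thermoslurry)

out <- "results"
cfg <- default_config()
hash <- config_hash(cfg)
conc <- read_timeseries(file.path(out, "concentrations.csv"))

gtab <- do.call(rbind, lapply(reaction_table(), function(rx)
  favourability_profile(rx, conc, ph = cfg$ph,
                        threshold = cfg$gibbs_threshold)))
rownames(gtab) <- NULL
write_stage_csv(gtab, file.path(out, "gibbs.csv"), hash)

open_range <- function(rxn) {
  g <- gtab[gtab$reaction == rxn & gtab$time == 100 & gtab$open, ]
  if (nrow(g) == 0) return("closed everywhere at day 100")
  sprintf("open %g-%g C at day 100", min(g$temperature), max(g$temperature))
}
for (rxn in unique(gtab$reaction))
  message(sprintf("  %-36s %s", rxn, open_range(rxn)))
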