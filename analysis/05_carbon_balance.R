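#!/usr/bin/env Rscript
# Stage 5: convert per-process rates to CO2 generation/consumption with the
# stoichiometric standardizing factors and sum them into the net carbon
# mineralization balance, split at the 43 C critical temperature.

library(thermoslurry)

out <- "results"
cfg <- default_config()
hash <- config_hash(cfg)
agg <- utils::read.csv(file.path(out, "rates.csv"), comment.char = "#")

rates <- agg[c("process", "temperature", "start_day", "rate")]
names(rates)[3] <- "time"
bal <- net_balance(rates, split_temp = cfg$split_temp)
write_stage_csv(bal$cells, file.path(out, "balance.csv"), hash)
write_stage_csv(bal$summary, file.path(out, "balance_summary.csv"), hash)
message(sprintf(
  "mean net CO2 rate below %g C: %.0f; at/above: %.0f nmol cm-3 d-1",
  cfg$split_temp, bal$summary$mean_net_below, bal$summary$mean_net_above))

groups <- c(acetoclastic_sulphate_reduction = "sulphate reduction",
            acetoclastic_metal_reduction = "metal oxide reduction",
            acetoclastic_methanogenesis = "methanogenesis",
            methylotrophic_methanogenesis = "methanogenesis")
sh <- share_of_mineralization(rates, groups = groups)
write_stage_csv(sh, file.path(out, "mineralization_shares.csv"), hash)
for (i in seq_len(nrow(sh)))
  message(sprintf("  %-24s %5.1f%% of gross CO2 production",
                  sh$group[i], sh$share_percent[i]))
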