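#!/usr/bin/env Rscript
# Stage 6: bound the hydrogenotrophic fraction of sulphate reduction from
# the rate comparison (sulphate removal vs total acetate oxidation) and
# locate the critical temperature as a breakpoint in the net
# mineralization profile.

library(thermoslurry)

out <- "results"
cfg <- default_config()
hash <- config_hash(cfg)
agg <- utils::read.csv(file.path(out, "rates.csv"), comment.char = "#")
srr <- utils::read.csv(file.path(out, "sulphate_removal.csv"),
                       comment.char = "#")
bal <- utils::read.csv(file.path(out, "balance.csv"), comment.char = "#")

acox <- thermoslurry:::derive_acox_co2(agg)
pp <- partition_profile(srr, acox, pairing = cfg$pairing)
write_stage_csv(pp$table, file.path(out, "partition.csv"), hash)
message(sprintf(
  ">=50%% of sulphate reduction is hydrogenotrophic from %g C upward",
  pp$threshold_temp))
f60 <- pp$table$fraction_h2_min[pp$table$temperature == 60]
message(sprintf("at 60 C at least %.0f%% of sulphate reduction is non-acetate",
                100 * f60))

# critical temperature from the net mineralization balance profile
day100 <- bal[bal$time == max(bal$time), ]
bp <- detect_breakpoint(day100$temperature, day100$net, cfg$break_grid)
write_stage_csv(data.frame(break_temp = bp$break_temp,
                           improvement = round(bp$improvement, 3)),
                file.path(out, "critical_temperature.csv"), hash)
message(sprintf(
  "net mineralization (day 100) breaks at %g C (improvement %.0f%%)",
  bp$break_temp, 100 * bp$improvement))
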