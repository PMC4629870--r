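#!/usr/bin/env Rscript
# Stage 7: convert 16S rRNA gene copies to bacterial and archaeal cell
# numbers (rrnDB average copies per cell) and summarize domain shares
# across the gradient.

library(thermoslurry)

out <- "results"
cfg <- default_config()
hash <- config_hash(cfg)
qp <- utils::read.csv(file.path(out, "qpcr.csv"), comment.char = "#")

cs <- summarize_cells(qp, divisors = cfg$divisors)
write_stage_csv(cs$cells, file.path(out, "cells.csv"), hash)
write_stage_csv(cs$shares, file.path(out, "cell_shares.csv"), hash)

d100 <- cs$cells[cs$cells$time == max(cs$cells$time), ]
for (dom in c("Bacteria", "Archaea")) {
  g <- d100[d100$domain == dom, ]
  i <- which.max(g$cells_per_ml)
  message(sprintf(
    "  %-8s day-100 max %.2e cells/mL at %g C (divisor %.2f)",
    dom, g$cells_per_ml[i], g$temperature[i], g$divisor_used[i]))
}
message(sprintf("archaeal share at day 100: %.0f-%.0f%% across the gradient",
                min(cs$shares$archaeal_share_percent[
                  cs$shares$time == max(cs$shares$time)]),
                max(cs$shares$archaeal_share_percent[
                  cs$shares$time == max(cs$shares$time)])))
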