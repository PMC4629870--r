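# Output table schemas

All tables are UTF-8 CSV with "." decimal separator. Every file starts
with a three-line `#` comment block: package version, configuration hash,
column list. Temperatures are degrees C, times are days, concentrations
are uM (identically nmol cm^-3 under the 1 cm^3 = 1 mL slurry
convention), rates are nmol cm^-3 day^-1.

## concentrations.csv
`temperature, time, species, replicate, value, below_detection`
Long-format observed pool concentrations; `below_detection` marks values
censored at the species detection limit (reported at the limit).

## tracers.csv
`process, temperature, start_day, duration, timepoint_index, replicate,
added_activity, product_activity, pool, flag`
One radiotracer incubation per row; triplicates at three time points.
`flag` is `ok`, `zero_pool` or `saturated`.

## rates.csv
`process, temperature, start_day, rate, sd, n_timepoints, n_incubations,
flag`
Aggregated tracer rates: replicate means per time point, then the
unweighted mean of time-point means; `sd` is the sd of time-point means.

## sulphate_removal.csv
`process, temperature, time, rate, rate_raw, rate_sd, n`
Interval rates from consecutive concentration differences at the interval
midpoint; negative raw rates are clamped to 0 in `rate` and retained in
`rate_raw`; `rate_sd` is the propagated replicate standard error.

## true_rates.csv
`process, temperature, time, rate`
Simulator ground-truth instantaneous rates at the sampling days.

## kinetics.csv
`process, ea, ln_a, r_squared, n_points, n_excluded, q10`
Arrhenius fits (Ea in kJ mol^-1) and Q10 over the configured interval.

## breakpoints.csv / sulphate_two_regime.csv
`process, break_temp, improvement` (pipeline) or
`break_temp, ea_below, ea_above, improvement` (analysis driver).

## gibbs.csv
`reaction, temperature, time, dg_prime, ln_q, open, flag`
In-situ Gibbs energies (kJ per mol reaction); `open` marks dG'r below the
favourability threshold.

## balance.csv / balance_summary.csv
Per-(temperature, time) net CO2 rate with one signed column per process,
and the below/above split-temperature means with their ratio.

## mineralization_shares.csv
`group, co2_production, share_percent`
Group shares of gross (positive) CO2 production.

## partition.csv
`temperature, srr, acox_acetate_units, fraction_h2_min, flag`
Hydrogenotrophic lower bound of sulphate reduction per temperature;
`flag` is `ok`, `degenerate` or `below_quantification`.

## qpcr.csv / cells.csv / cell_shares.csv
`domain, temperature, time, replicate, copies_per_ml` ;
`domain, temperature, time, cells_per_ml, sd, n, divisor_used, flag` ;
`temperature, time, archaeal_share_percent`.
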