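# total acetate oxidation to CO2 (x2 standardization) from aggregated
# per-process tracer rates
derive_acox_co2 <- function(agg,
                            oxidizers = c("acetoclastic_sulphate_reduction",
                                          "acetoclastic_metal_reduction")) {
  ox <- agg[agg$process %in% oxidizers, ]
  if (nrow(ox) == 0)
    stop("derive_acox_co2: no acetate-oxidizing process rates present")
  key <- interaction(ox$temperature, ox$start_day, drop = TRUE)
  out <- do.call(rbind, lapply(split(ox, key), function(g) {
    data.frame(process = "acetate_oxidation_co2",
               temperature = g$temperature[1], time = g$start_day[1],
               rate = 2 * sum(g$rate), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order -- simulate, tracer and
#' sulphate-removal rates, Arrhenius/Q10 kinetics, Gibbs favourability,
#' carbon mineralization balance, sulphate-reduction partition, cell
#' numbers -- writing one CSV per stage into `out_dir`, every file stamped
#' with the configuration hash. Reruns with an identical configuration are
#' byte-identical. Any stage error aborts the run with the stage name and
#' removes that stage's partial outputs.
#'
#' @param config Configuration list ([default_config()] / [read_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Run report: per-stage row counts, exclusions, warnings, package
#'   version and configuration hash.
#' @export
run_pipeline <- function(config = default_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  report <- list(version = as.character(utils::packageVersion("thermoslurry")),
                 config_hash = hash, stages = list(), warnings = character())
  stage_files <- character()
  run_stage <- function(name, fun) {
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        unlink(stage_files)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        report$warnings <<- c(report$warnings,
                              paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    res
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    stage_files <<- c(stage_files, path)
    write_stage_csv(df, path, hash)
    nrow(df)
  }
  stages <- config$stages
  design <- experiment_design(temperatures = config$temperatures,
                              time_points = config$time_points,
                              replicates = config$replicates,
                              scenario = config$scenario,
                              noise_cv = config$noise_cv,
                              seed = config$seed)
  sim <- NULL
  conc <- NULL
  agg <- NULL
  srr <- NULL

  if ("simulate" %in% stages) {
    sim <- run_stage("simulate", function() simulate_slurry(design,
                                                            dt = config$dt))
    conc <- observe_concentrations(sim, design)
    report$stages$simulate <- c(
      concentrations = emit(conc, "concentrations.csv"),
      true_rates = emit(true_rates_df(sim), "true_rates.csv"))
  } else if (!is.null(config$concentrations_file)) {
    conc <- read_timeseries(config$concentrations_file)
  }

  if ("rates" %in% stages) {
    report$stages$rates <- run_stage("rates", function() {
      trc <- observe_tracers(sim, design,
                             schedule = config$tracer_schedule)
      trc <- tracer_rate(trc)
      agg <<- aggregate_rates(trc)
      srr <<- sulphate_removal_rates(conc)
      c(tracers = emit(trc, "tracers.csv"),
        rates = emit(agg, "rates.csv"),
        sulphate_removal = emit(srr, "sulphate_removal.csv"))
    })
  }

  if ("kinetics" %in% stages) {
    report$stages$kinetics <- run_stage("kinetics", function() {
      prof <- max_rate_profile(agg, time_col = "start_day")
      rows <- lapply(split(prof, prof$process), function(g) {
        # rising limb only, excluding sub-quantification tails (<5% of
        # the profile maximum)
        g <- g[g$rate >= 0.05 * max(g$rate), ]
        if (sum(g$rate > 0) < 3) return(NULL)
        rising <- g[g$temperature <= g$temperature[which.max(g$rate)], ]
        if (sum(rising$rate > 0) < 3) rising <- g
        f <- fit_arrhenius(rising)
        data.frame(process = g$process[1], ea = f$ea, ln_a = f$ln_a,
                   r_squared = f$r_squared, n_points = f$n_points,
                   n_excluded = f$n_excluded,
                   q10 = q10_from_ea(f$ea, config$q10_t1, config$q10_t2)$q10,
                   stringsAsFactors = FALSE)
      })
      kin <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      srr_prof <- max_rate_profile(srr)
      srr_prof <- srr_prof[srr_prof$rate >= 0.05 * max(srr_prof$rate), ]
      srr_prof <- srr_prof[srr_prof$temperature <=
                             srr_prof$temperature[which.max(srr_prof$rate)], ]
      two <- two_regime_fit(srr_prof, config$break_grid)
      kin <- rbind(kin, data.frame(
        process = c("sulphate_removal_below_break",
                    "sulphate_removal_above_break"),
        ea = c(two$left$ea, if (two$fallback) NA else two$right$ea),
        ln_a = c(two$left$ln_a, if (two$fallback) NA else two$right$ln_a),
        r_squared = c(two$left$r_squared,
                      if (two$fallback) NA else two$right$r_squared),
        n_points = c(two$left$n_points,
                     if (two$fallback) NA else two$right$n_points),
        n_excluded = NA, q10 = NA, stringsAsFactors = FALSE))
      attr_break <- data.frame(process = "sulphate_removal",
                               break_temp = two$break_temp,
                               improvement = two$improvement)
      c(kinetics = emit(kin, "kinetics.csv"),
        breaks = emit(attr_break, "breakpoints.csv"))
    })
  }

  if ("gibbs" %in% stages) {
    report$stages$gibbs <- run_stage("gibbs", function() {
      rxs <- reaction_table()
      gtab <- do.call(rbind, lapply(rxs, function(rx)
        favourability_profile(rx, conc, ph = config$ph,
                              threshold = config$gibbs_threshold)))
      rownames(gtab) <- NULL
      c(gibbs = emit(gtab, "gibbs.csv"))
    })
  }

  if ("balance" %in% stages) {
    report$stages$balance <- run_stage("balance", function() {
      rates <- agg[c("process", "temperature", "start_day", "rate")]
      names(rates)[3] <- "time"
      bal <- net_balance(rates, split_temp = config$split_temp)
      out <- bal$cells
      n1 <- emit(out, "balance.csv")
      n2 <- emit(bal$summary, "balance_summary.csv")
      c(balance = n1, summary = n2)
    })
  }

  if ("partition" %in% stages) {
    report$stages$partition <- run_stage("partition", function() {
      acox <- derive_acox_co2(agg)
      pp <- partition_profile(srr, acox, pairing = config$pairing)
      c(partition = emit(cbind(pp$table,
                               threshold_temp = pp$threshold_temp),
                         "partition.csv"))
    })
  }

  if ("cells" %in% stages) {
    report$stages$cells <- run_stage("cells", function() {
      qp <- observe_qpcr(sim, design)
      cs <- summarize_cells(qp, divisors = config$divisors)
      c(qpcr = emit(qp, "qpcr.csv"),
        cells = emit(cs$cells, "cells.csv"),
        shares = emit(cs$shares, "cell_shares.csv"))
    })
  }

  report
}
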