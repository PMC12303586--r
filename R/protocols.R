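#' Protocol specification
#'
#' Scripted end-to-end experiments. Available protocols:
#' \describe{
#'   \item{fig2_cellular}{Single-cell characterization: adaptation curve over
#'     10 pyramidal cells and the rheobase/probability curves under the three
#'     OXT conditions.}
#'   \item{fig3_learning}{Pre/post odor-response rates: baseline, familiar
#'     and novel presented 0.5 s each under medium OXT, the familiar odor
#'     learned for 5 s with plasticity on (under a given OXT level), then the
#'     three test conditions re-presented; repeated across instantiations and
#'     learning OXT levels, with paired pre/post t-tests.}
#'   \item{fig4_distances}{Population-vector Euclidean distances
#'     (baseline-familiar, baseline-novel, familiar-novel) pre/post learning,
#'     normalized by the mean pre-learning distance; computed from a
#'     fig3_learning result.}
#'   \item{fig5_spectra}{LFP power spectra of the 0.5 s familiar/novel test
#'     windows pre/post learning and the beta-band (12-30 Hz) power table.}
#'   \item{fig6_accumulation}{Cumulative pyramidal spike counts during long
#'     familiar vs novel presentations after learning.}
#'   \item{fig6_concentration}{Detection of low-concentration odors: mean
#'     spike counts and distance-to-baseline across concentration ratios,
#'     pre vs post learning.}
#' }
#'
#' Learning phases last 5000 ms and test phases 500 ms; test phases always
#' run under medium OXT with plasticity off, and each test phase is preceded
#' by a 250 ms blank settling period excluded from analysis.
#'
#' @param name Protocol name (see above).
#' @param n_instantiations Number of independent network instantiations.
#' @param seeds Integer seeds, one per instantiation (default `1:n + 1000`).
#' @param ... Protocol-specific options: `oxt_levels` (fig3; learning
#'   conditions, default low/medium/high), `ratios` (fig6_concentration),
#'   `present_ms` (fig6_accumulation, default 30000), `spectra_ms`
#'   (fig5_spectra presentation windows, default 4000), `test_ms`,
#'   `learn_ms`, `settle_ms`.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(name, n_instantiations = NULL, seeds = NULL, ...) {
  name <- match.arg(name, c("fig2_cellular", "fig3_learning",
                            "fig4_distances", "fig5_spectra",
                            "fig6_accumulation", "fig6_concentration"))
  if (is.null(n_instantiations))
    n_instantiations <- switch(name, fig3_learning = 10, fig4_distances = 10,
                               fig5_spectra = 4, fig6_accumulation = 5,
                               fig6_concentration = 10, 1)
  if (is.null(seeds)) seeds <- seq_len(n_instantiations) + 1000L
  if (length(seeds) != n_instantiations)
    stop("need one seed per instantiation")
  opts <- list(...)
  defaults <- list(test_ms = 500, learn_ms = 5000, settle_ms = 250,
                   spectra_ms = 4000,
                   oxt_levels = c("low", "medium", "high"),
                   ratios = c(0.02, 0.05, 0.1, 0.2, 0.4),
                   present_ms = 30000)
  for (nm in names(defaults))
    if (is.null(opts[[nm]])) opts[[nm]] <- defaults[[nm]]
  structure(c(list(name = name, n_instantiations = n_instantiations,
                   seeds = seeds), opts),
            class = "protocol_spec")
}

# one instantiation of the learning experiment; returns pre/post rate
# vectors for baseline/familiar/novel plus the per-phase records
learning_experiment <- function(seed, oxt_learn = "medium",
                                config = aon_config(),
                                settings = sim_settings(),
                                test_ms = 500, learn_ms = 5000,
                                settle_ms = 250, keep_records = FALSE) {
  set.seed(seed)
  net <- build_network(config)
  odors <- make_odor_pair(n_osn = config$populations$OSN$n)
  blank <- blank_odor(config$populations$OSN$n)
  test_phase <- function(odor, label) list(
    list(odor = blank, duration = settle_ms, oxt_level = "medium",
         plasticity = FALSE, label = paste0(label, "_settle")),
    list(odor = odor, duration = test_ms, oxt_level = "medium",
         plasticity = FALSE, label = label))
  phases <- c(
    test_phase(blank, "pre_baseline"),
    test_phase(odors$familiar, "pre_familiar"),
    test_phase(odors$novel, "pre_novel"),
    list(list(odor = odors$familiar, duration = learn_ms,
              oxt_level = oxt_learn, plasticity = TRUE, label = "learning")),
    test_phase(blank, "post_baseline"),
    test_phase(odors$familiar, "post_familiar"),
    test_phase(odors$novel, "post_novel"))
  out <- run_phases(net, phases, settings)
  keep <- c("pre_baseline", "pre_familiar", "pre_novel",
            "post_baseline", "post_familiar", "post_novel")
  rates <- lapply(out$records[keep], population_rates)
  list(seed = seed, oxt_learn = oxt_learn, rates = rates,
       odors = odors, network = out$network,
       records = if (keep_records) out$records[keep] else NULL)
}

run_fig3 <- function(spec, config, settings) {
  runs <- list()
  for (oxt in spec$oxt_levels) {
    runs[[oxt]] <- lapply(spec$seeds, learning_experiment,
                          oxt_learn = oxt, config = config,
                          settings = settings, test_ms = spec$test_ms,
                          learn_ms = spec$learn_ms,
                          settle_ms = spec$settle_ms)
  }
  rate_rows <- do.call(rbind, lapply(names(runs), function(oxt) {
    do.call(rbind, lapply(runs[[oxt]], function(r) {
      conds <- c("baseline", "familiar", "novel")
      do.call(rbind, lapply(conds, function(cd) {
        data.frame(seed = r$seed, oxt_learn = oxt, condition = cd,
                   pre = mean(r$rates[[paste0("pre_", cd)]]),
                   post = mean(r$rates[[paste0("post_", cd)]]))
      }))
    }))
  }))
  tests <- do.call(rbind, lapply(split(rate_rows,
                                       rate_rows[c("oxt_learn", "condition")]),
                                 function(d) {
    tt <- paired_rate_test(d$pre, d$post)
    data.frame(oxt_learn = d$oxt_learn[1], condition = d$condition[1],
               t = tt$statistic, p = tt$p_value,
               mean_change = tt$mean_difference,
               significant = tt$significant)
  }))
  rownames(tests) <- NULL
  list(rates = rate_rows, tests = tests, runs = runs)
}

#' Distance table from a learning-protocol result
#'
#' Euclidean distances between the baseline, familiar and novel population
#' vectors, pre and post learning, normalized per (learning condition,
#' comparison) by the mean pre-learning distance.
#'
#' @param runs The `runs` element of a `fig3_learning` protocol result.
#' @return A data.frame with columns `seed`, `oxt_learn`, `comparison`,
#'   `phase`, `distance`, `normalized`.
#' @export
distance_table <- function(runs) {
  rows <- do.call(rbind, lapply(names(runs), function(oxt) {
    do.call(rbind, lapply(runs[[oxt]], function(r) {
      cmp <- list(base_familiar = c("baseline", "familiar"),
                  base_novel = c("baseline", "novel"),
                  familiar_novel = c("familiar", "novel"))
      do.call(rbind, lapply(names(cmp), function(cn) {
        a <- cmp[[cn]][1]; b <- cmp[[cn]][2]
        data.frame(seed = r$seed, oxt_learn = oxt, comparison = cn,
                   phase = c("pre", "post"),
                   distance = c(
                     population_distance(r$rates[[paste0("pre_", a)]],
                                         r$rates[[paste0("pre_", b)]]),
                     population_distance(r$rates[[paste0("post_", a)]],
                                         r$rates[[paste0("post_", b)]])))
      }))
    }))
  }))
  rows$normalized <- NA_real_
  for (key in unique(paste(rows$oxt_learn, rows$comparison))) {
    sel <- paste(rows$oxt_learn, rows$comparison) == key
    pre_mean <- mean(rows$distance[sel & rows$phase == "pre"])
    rows$normalized[sel] <- rows$distance[sel] / pre_mean
  }
  rows
}

# spectral variant of the learning experiment: long (default 4 s) odor
# presentations flank the 5 s learning phase so the Welch estimate resolves
# the beta band; 0.5 s windows only give 2 Hz resolution over 4 sniffs
run_fig5 <- function(spec, config, settings) {
  window_ms <- spec$spectra_ms
  runs <- lapply(spec$seeds, function(seed) {
    set.seed(seed)
    net <- build_network(config)
    odors <- make_odor_pair(n_osn = config$populations$OSN$n)
    blank <- blank_odor(config$populations$OSN$n)
    ph <- list(
      list(odor = blank, duration = spec$settle_ms),
      list(odor = odors$familiar, duration = window_ms, label = "pre_familiar"),
      list(odor = blank, duration = spec$settle_ms),
      list(odor = odors$novel, duration = window_ms, label = "pre_novel"),
      list(odor = odors$familiar, duration = spec$learn_ms,
           plasticity = TRUE, label = "learning"),
      list(odor = blank, duration = spec$settle_ms),
      list(odor = odors$familiar, duration = window_ms, label = "post_familiar"),
      list(odor = blank, duration = spec$settle_ms),
      list(odor = odors$novel, duration = window_ms, label = "post_novel"))
    out <- run_phases(net, ph, settings)
    list(seed = seed, records = out$records, network = out$network)
  })
  beta <- do.call(rbind, lapply(runs, function(r) {
    do.call(rbind, lapply(c("familiar", "novel"), function(od) {
      do.call(rbind, lapply(c("pre", "post"), function(ph) {
        ps <- lfp_spectrum(r$records[[paste0(ph, "_", od)]]$lfp,
                           dt = settings$dt)
        data.frame(seed = r$seed, odor = od, phase = ph,
                   beta_power = band_power(ps, 12, 30),
                   peak_hz = spectrum_peak(ps))
      }))
    }))
  }))
  fit <- stats::aov(beta_power ~ odor * phase, data = beta)
  list(beta = beta, anova = summary(fit), runs = runs)
}

run_fig6_accumulation <- function(spec, config, settings) {
  curves <- do.call(rbind, lapply(spec$seeds, function(seed) {
    set.seed(seed)
    net <- build_network(config)
    odors <- make_odor_pair(n_osn = config$populations$OSN$n)
    learned <- run_phases(net, list(
      list(odor = odors$familiar, duration = spec$learn_ms,
           oxt_level = "medium", plasticity = TRUE)), settings)
    s <- settings
    s$duration <- spec$present_ms
    s$plasticity <- FALSE
    state0 <- learned$records[["1"]]$state
    rec_f <- run_simulation(learned$network, odors$familiar, s, state0)
    rec_n <- run_simulation(learned$network, odors$novel, s, state0)
    rbind(cbind(accumulate_spikes(rec_f), odor = "familiar", seed = seed),
          cbind(accumulate_spikes(rec_n), odor = "novel", seed = seed))
  }))
  curves
}

#' Concentration series on a given network
#'
#' Presents concentration-scaled versions of an odor (each preceded by a
#' blank settling period) plus a blank reference, and reports the mean
#' pyramidal spike count and the Euclidean distance of the population vector
#' to baseline activity for every concentration ratio.
#'
#' @param network A built (possibly learned) [build_network()] network.
#' @param odor The full-concentration [odor_stimulus()].
#' @param ratios Concentration ratios in `(0, 1]`.
#' @param settings A [sim_settings()] (plasticity is forced off).
#' @param test_ms,settle_ms Test and settling durations, ms.
#' @return A data.frame with columns `ratio`, `mean_count`,
#'   `dist_to_baseline`.
#' @export
concentration_series <- function(network, odor, ratios,
                                 settings = sim_settings(),
                                 test_ms = 500, settle_ms = 250) {
  if (any(ratios <= 0 | ratios > 1)) stop("ratios must lie in (0, 1]")
  blank <- blank_odor(length(odor$activation))
  settings$plasticity <- FALSE
  run_test <- function(stim) {
    out <- run_phases(network, list(
      list(odor = blank, duration = settle_ms, oxt_level = "medium"),
      list(odor = stim, duration = test_ms, oxt_level = "medium",
           label = "test")), settings)
    population_rates(out$records[["test"]])
  }
  base_rates <- run_test(blank)
  do.call(rbind, lapply(ratios, function(rt) {
    rates <- run_test(scale_concentration(odor, rt))
    data.frame(ratio = rt,
               mean_count = mean(rates) * test_ms / 1000,
               dist_to_baseline = population_distance(rates, base_rates))
  }))
}

run_fig6_concentration <- function(spec, config, settings) {
  do.call(rbind, lapply(spec$seeds, function(seed) {
    set.seed(seed)
    net <- build_network(config)
    odors <- make_odor_pair(n_osn = config$populations$OSN$n)
    pre <- concentration_series(net, odors$familiar, spec$ratios, settings,
                                spec$test_ms, spec$settle_ms)
    learned <- run_phases(net, list(
      list(odor = odors$familiar, duration = spec$learn_ms,
           oxt_level = "medium", plasticity = TRUE)), settings)
    post <- concentration_series(learned$network, odors$familiar,
                                 spec$ratios, settings, spec$test_ms,
                                 spec$settle_ms)
    rbind(cbind(pre, phase = "pre", seed = seed),
          cbind(post, phase = "post", seed = seed))
  }))
}

#' Run a scripted protocol
#'
#' Executes the named protocol across its instantiations (each a fresh
#' network built from `config` under its own seed) and returns the analysis
#' tables; see [protocol_spec()] for the available protocols.
#'
#' @param spec A [protocol_spec()].
#' @param config An [aon_config()].
#' @param settings Base [sim_settings()] (learning rate, weight cap, dt).
#' @return A list of class `protocol_result` with `name`, `seeds`, `tables`
#'   (protocol-specific data.frames) and any protocol-specific extras.
#' @export
run_protocol <- function(spec, config = aon_config(),
                         settings = sim_settings()) {
  stopifnot(inherits(spec, "protocol_spec"))
  out <- switch(spec$name,
    fig2_cellular = {
      ad <- pyr_adaptation_experiment(n_cells = 10, seed = spec$seeds[1])
      rb <- rheobase_curve(amplitudes = seq(1, 5, by = 1),
                           n_repeats = 10, seed = spec$seeds[1] + 1)
      list(tables = list(adaptation = ad$curve, rheobase = rb),
           correlation = ad$correlation)
    },
    fig3_learning = {
      r <- run_fig3(spec, config, settings)
      list(tables = list(rates = r$rates, tests = r$tests), runs = r$runs)
    },
    fig4_distances = {
      r <- run_fig3(spec, config, settings)
      list(tables = list(distances = distance_table(r$runs),
                         rates = r$rates), runs = r$runs)
    },
    fig5_spectra = {
      r <- run_fig5(spec, config, settings)
      list(tables = list(beta = r$beta), anova = r$anova, runs = r$runs)
    },
    fig6_accumulation = list(
      tables = list(accumulation = run_fig6_accumulation(spec, config,
                                                         settings))),
    fig6_concentration = list(
      tables = list(concentration = run_fig6_concentration(spec, config,
                                                           settings)))
  )
  structure(c(list(name = spec$name, seeds = spec$seeds, spec = spec),
              out),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("protocol_result '%s' (%d instantiation(s))\n", x$name,
              length(x$seeds)))
  for (nm in names(x$tables))
    cat(sprintf("  $tables$%s: %d rows\n", nm, nrow(x$tables[[nm]])))
  invisible(x)
}

#' Aggregate protocol results into one tidy table
#'
#' Stacks the metric tables of one or more protocol results into a single
#' long data.frame (`protocol`, `table`, metric columns), deterministic
#' given identical inputs.
#'
#' @param results A list of [run_protocol()] results (possibly empty).
#' @return A data.frame with one row per metric value.
#' @export
summarize_protocols <- function(results) {
  if (!length(results))
    return(data.frame(protocol = character(0), table = character(0),
                      metric = character(0), value = numeric(0)))
  do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(names(r$tables), function(tn) {
      tab <- r$tables[[tn]]
      num <- names(tab)[vapply(tab, is.numeric, TRUE)]
      do.call(rbind, lapply(num, function(cn) {
        data.frame(protocol = r$name, table = tn, metric = cn,
                   value = mean(tab[[cn]], na.rm = TRUE))
      }))
    }))
  }))
}
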