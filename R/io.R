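#' Export a simulation record as tabular text
#'
#' Writes the spike raster as three-column text (`t_ms`, `population`,
#' `index`), the LFP as two-column text (`t_ms`, `mv`), and the current
#' Pyr->Pyr weight matrix as dense matrix text, each with a one-line
#' format-version header.
#'
#' @param record A [run_simulation()] record.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_sim_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- record$spikes
  spike_file <- file.path(dir, "spikes.tsv")
  con <- file(spike_file, "w")
  writeLines("# aonsim spikes v1", con)
  utils::write.table(data.frame(t_ms = sp$t, population = sp$pop,
                                index = sp$id),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  lfp_file <- file.path(dir, "lfp.tsv")
  con <- file(lfp_file, "w")
  writeLines("# aonsim lfp v1", con)
  utils::write.table(data.frame(t_ms = record$times, mv = record$lfp),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  w <- record$network$synapses$Pyr_Pyr$W
  if (!is.null(w)) {
    wf <- file.path(dir, "weights_pyr_pyr.tsv")
    con <- file(wf, "w")
    writeLines("# aonsim weights v1", con)
    utils::write.table(w, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  invisible(dir)
}

#' Read back an exported simulation record
#'
#' @param dir Directory written by [write_sim_record()].
#' @return A list with `spikes` (data.frame `t`, `pop`, `id`), `lfp`
#'   (numeric), `times` (ms) and, if present, `weights` (matrix).
#' @export
read_sim_record <- function(dir) {
  sp <- utils::read.table(file.path(dir, "spikes.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
  lf <- utils::read.table(file.path(dir, "lfp.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#")
  out <- list(spikes = data.frame(t = sp$t_ms, pop = sp$population,
                                  id = sp$index),
              lfp = lf$mv, times = lf$t_ms)
  wf <- file.path(dir, "weights_pyr_pyr.tsv")
  if (file.exists(wf))
    out$weights <- as.matrix(utils::read.table(wf, sep = "\t",
                                               comment.char = "#"))
  out
}

#' Write / read a network configuration as structured text
#'
#' Key/value text with one `[section]` per population and synapse class plus
#' a `[global]` section, round-trippable via [read_aon_config()].
#'
#' @param config An [aon_config()].
#' @param file Output path.
#' @return The path (write) or the reconstructed `aon_config` (read).
#' @export
write_aon_config <- function(config, file) {
  lines <- c("# aonsim config v1", "[global]",
             sprintf("jitter_fraction = %g", config$jitter_fraction),
             sprintf("respiration_hz = %g", config$respiration_hz),
             sprintf("osn_gain = %g", config$osn_gain),
             sprintf("osn_baseline = %g", config$osn_baseline),
             sprintf("mc_coupling = %g", config$mc_coupling),
             sprintf("et_surround = %s", config$et_surround),
             "[adaptation]",
             sprintf("a_ahc = %g", config$adaptation$a_ahc),
             sprintf("e_ahp = %g", config$adaptation$e_ahp),
             sprintf("tau_ca = %g", config$adaptation$tau_ca),
             sprintf("ca_increment = %g", config$adaptation$ca_increment))
  for (nm in names(config$populations)) {
    p <- config$populations[[nm]]
    lines <- c(lines, sprintf("[population %s]", nm),
               sprintf("n = %d", p$n), sprintf("tau = %g", p$tau),
               sprintf("v_rest = %g", p$v_rest),
               sprintf("theta_min = %g", p$theta_min),
               sprintf("theta_max = %g", p$theta_max),
               sprintf("compartments = %d", p$compartments))
  }
  for (nm in names(config$synapses)) {
    s <- config$synapses[[nm]]
    lines <- c(lines, sprintf("[synapse %s]", nm),
               sprintf("pre = %s", s$pre), sprintf("post = %s", s$post),
               sprintf("w_mean = %g", s$w_mean),
               sprintf("e_n = %g", s$e_n),
               sprintf("tau1 = %g", s$tau1), sprintf("tau2 = %g", s$tau2),
               sprintf("p = %s", as.character(s$p)),
               sprintf("post_compartment = %s", s$post_compartment),
               sprintf("relative_to_rest = %s", s$relative_to_rest),
               sprintf("plastic = %s", s$plastic),
               sprintf("sign = %s", s$sign))
  }
  writeLines(lines, file)
  invisible(file)
}

parse_kv <- function(lines) {
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}

#' @rdname write_aon_config
#' @export
read_aon_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  heads <- grep("^\\[", lines)
  sections <- list()
  for (i in seq_along(heads)) {
    end <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    nm <- gsub("^\\[|\\]$", "", lines[heads[i]])
    sections[[nm]] <- parse_kv(lines[(heads[i] + 1):end])
  }
  g <- sections[["global"]]
  ad <- sections[["adaptation"]]
  cfg <- aon_config(
    n = as.integer(sections[["population OSN"]]$n),
    jitter_fraction = as.numeric(g$jitter_fraction),
    respiration_hz = as.numeric(g$respiration_hz),
    osn_gain = as.numeric(g$osn_gain),
    osn_baseline = as.numeric(g$osn_baseline),
    mc_coupling = as.numeric(g$mc_coupling),
    et_surround = as.logical(g$et_surround),
    adaptation = adaptation_spec(as.numeric(ad$a_ahc), as.numeric(ad$e_ahp),
                                 as.numeric(ad$tau_ca),
                                 as.numeric(ad$ca_increment)))
  for (nm in names(sections)) {
    if (grepl("^population ", nm)) {
      p <- sections[[nm]]
      key <- sub("^population ", "", nm)
      cfg$populations[[key]] <- population_spec(
        key, as.integer(p$n), as.numeric(p$tau), as.numeric(p$v_rest),
        as.numeric(p$theta_min), as.numeric(p$theta_max),
        as.integer(p$compartments))
    } else if (grepl("^synapse ", nm)) {
      s <- sections[[nm]]
      key <- sub("^synapse ", "", nm)
      pnum <- suppressWarnings(as.numeric(s$p))
      cfg$synapses[[key]] <- synapse_spec(
        s$pre, s$post, as.numeric(s$w_mean), as.numeric(s$e_n),
        as.numeric(s$tau1), as.numeric(s$tau2),
        if (is.na(pnum)) s$p else pnum,
        post_compartment = s$post_compartment,
        relative_to_rest = as.logical(s$relative_to_rest),
        plastic = as.logical(s$plastic), sign = s$sign)
    }
  }
  cfg
}
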