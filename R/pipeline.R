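#' Pipeline configuration
#'
#' Bundles every stage's parameters plus I/O locations into one object
#' that round-trips losslessly through YAML or JSON, so that a recorded
#' configuration and seed reproduce byte-identical outputs.
#'
#' @param detection A [detection_config()].
#' @param terminal A [terminal_filter_config()].
#' @param model A [model_params()] (used by the simulation stages).
#' @param read_sim A [read_sim_params()].
#' @param terminal_sim A [terminal_sim_params()] or `NULL`.
#' @param rho Variant re-association probability for the processivity
#'   stage.
#' @param min_runs Survival-curve tail cutoff (see
#'   [survival_from_runs()]).
#' @param n_units Array size for the WGS simulation stage.
#' @param wgs_fastq,terminal_fastq Optional input FASTQ paths; when a
#'   simulation stage runs, its output feeds the analysis stages.
#' @param output_dir Directory for all reports.
#' @param seed Master seed for the simulation stages.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `telovar_pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            terminal = terminal_filter_config(),
                            model = model_params(0.9, 0.4),
                            read_sim = read_sim_params(n_reads = 1000L),
                            terminal_sim = NULL,
                            rho = 0.5,
                            min_runs = 5L,
                            n_units = 50000L,
                            wgs_fastq = NULL,
                            terminal_fastq = NULL,
                            output_dir = ".",
                            seed = 1L,
                            log_level = "info") {
  check_prob(rho, "rho")
  check_count(min_runs, "min_runs")
  check_count(n_units, "n_units")
  structure(list(
    detection = detection, terminal = terminal, model = model,
    read_sim = read_sim, terminal_sim = terminal_sim,
    rho = rho, min_runs = as.integer(min_runs),
    n_units = as.integer(n_units),
    wgs_fastq = wgs_fastq, terminal_fastq = terminal_fastq,
    output_dir = output_dir, seed = as.integer(seed),
    log_level = log_level
  ), class = "telovar_pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON.  Any field of [pipeline_config()] may
#' be given; omitted fields take their defaults.
#'
#' @param path Configuration file path.
#' @return A `telovar_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$detection))
    args$detection <- do.call(detection_config, raw$detection)
  if (!is.null(raw$terminal))
    args$terminal <- do.call(terminal_filter_config, raw$terminal)
  if (!is.null(raw$model)) args$model <- do.call(model_params, raw$model)
  if (!is.null(raw$read_sim))
    args$read_sim <- do.call(read_sim_params, raw$read_sim)
  if (!is.null(raw$terminal_sim)) {
    ts <- raw$terminal_sim
    ts$permutation_weights <- unlist(ts$permutation_weights)
    args$terminal_sim <- do.call(terminal_sim_params, ts)
  }
  for (f in c("rho", "min_runs", "n_units", "wgs_fastq", "terminal_fastq",
              "output_dir", "seed", "log_level"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration file
#'
#' @param config A `telovar_pipeline_config`.
#' @param path Output path; format chosen by extension (`.yml`/`.yaml`
#'   for YAML, anything else JSON).
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  if (!is.null(config$terminal_sim) &&
      is.function(config$terminal_sim$tail_length_distribution))
    stop("a functional tail_length_distribution cannot be written to a ",
         "config file; use an integer vector of tail lengths", call. = FALSE)
  plain <- strip_classes(config)
  if (!is.null(plain$terminal_sim))
    plain$terminal_sim$permutation_weights <-
      as.list(plain$terminal_sim$permutation_weights)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(plain, path)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order and writes TSV and
#' JSON reports, a log with per-stage read counts and rejection
#' tallies, and a provenance block (configuration echo and MD5, seed,
#' package version).  Available stages: `"simulate_wgs"`,
#' `"simulate_terminal"`, `"composition"`, `"processivity"`,
#' `"terminal"`.  Outputs are byte-identical for identical
#' configuration and seed.
#'
#' @param config A `telovar_pipeline_config`.
#' @param stages Character vector of stage names.
#' @return Invisibly, a named list of the written report paths.
#' @export
run_pipeline <- function(config,
                         stages = c("composition", "processivity")) {
  known <- c("simulate_wgs", "simulate_terminal",
             "composition", "processivity", "terminal")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "), call. = FALSE)
  order <- known[known %in% stages]
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$output_dir, f)
  log_lines <- character()
  logmsg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (identical(config$log_level, "info")) message(line)
  }
  written <- list()
  wgs_path <- config$wgs_fastq
  term_path <- config$terminal_fastq

  for (stage in order) {
    switch(stage,
      simulate_wgs = {
        arr <- simulate_telomere_array(config$model, config$n_units,
                                       seed = config$seed)
        rs <- config$read_sim
        rs$seed <- config$seed
        sim <- simulate_wgs_reads(arr, rs)
        wgs_path <- outp("simulated_wgs.fastq.gz")
        write_fastq(sim$reads, wgs_path)
        write_array_truth(arr, outp("array_truth.tsv"))
        written$simulated_wgs <- wgs_path
        logmsg("[simulate_wgs] ", length(sim$reads), " reads from ",
               config$n_units, " units -> ", basename(wgs_path))
      },
      simulate_terminal = {
        if (is.null(config$terminal_sim))
          stop("simulate_terminal requires config$terminal_sim",
               call. = FALSE)
        ts <- config$terminal_sim
        ts$seed <- config$seed
        sim <- simulate_terminal_reads(ts)
        term_path <- outp("simulated_terminal.fastq.gz")
        write_fastq(sim$reads, term_path)
        written$simulated_terminal <- term_path
        logmsg("[simulate_terminal] ", length(sim$reads), " reads -> ",
               basename(term_path))
      },
      composition = {
        reads <- pipeline_reads(wgs_path, "composition")
        comp <- telomere_composition(reads, config$detection)
        if (comp$n_reads_telomeric == 0L)
          logmsg("[composition] warning: no telomeric reads detected")
        write_composition_report(comp, outp("composition.tsv"),
                                 outp("composition.json"))
        runs <- telomere_runs_from_reads(reads, config$detection)
        write_runlengths_report(runs, outp("runlengths.tsv"))
        written$composition <- outp("composition.tsv")
        written$runlengths <- outp("runlengths.tsv")
        logmsg("[composition] ", comp$n_reads_telomeric, "/",
               comp$n_reads_total, " telomeric reads, ",
               comp$bases_considered, " bases considered")
      },
      processivity = {
        reads <- pipeline_reads(wgs_path, "processivity")
        est <- estimate_processivity(reads, config$detection,
                                     rho = config$rho,
                                     min_runs = config$min_runs)
        write_processivity_report(est, outp("processivity.tsv"),
                                  outp("processivity.json"))
        written$processivity <- outp("processivity.tsv")
        for (cls in c("wt", "var")) {
          e <- est[[cls]]
          logmsg("[processivity] ", cls, ": ",
                 if (inherits(e, "processivity_error")) e$error
                 else sprintf("p_x = %.4f (p_add = %.4f, %d points)",
                              e$p_x, e$p_add, e$n_points_fit))
        }
      },
      terminal = {
        reads <- pipeline_reads(term_path, "terminal")
        spec <- suppressWarnings(terminal_spectrum(reads, config$terminal))
        write_terminal_report(spec, outp("terminal_spectrum.tsv"),
                              outp("terminal_spectrum.json"))
        written$terminal <- outp("terminal_spectrum.tsv")
        logmsg("[terminal] ", spec$n_pass, "/", spec$n_total,
               " passing reads; rejections: ",
               paste(names(spec$rejections), spec$rejections,
                     sep = "=", collapse = ", "))
      }
    )
  }

  writeLines(log_lines, outp("pipeline_log.txt"))
  # the config echo omits the output location so that identical
  # scientific configurations give byte-identical provenance anywhere
  cfg_echo <- strip_classes(config)
  cfg_echo$output_dir <- NULL
  prov <- list(
    tool = "telovar",
    version = as.character(utils::packageVersion("telovar")),
    seed = config$seed,
    stages = order,
    config = cfg_echo
  )
  cfg_tmp <- outp("provenance_config.json")
  jsonlite::write_json(prov$config, cfg_tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  prov$config_md5 <- unname(tools::md5sum(cfg_tmp))
  file.remove(cfg_tmp)
  jsonlite::write_json(prov, outp("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  written$provenance <- outp("provenance.json")
  written$log <- outp("pipeline_log.txt")
  invisible(written)
}

# drop S3 classes from nested config lists so yaml/jsonlite see plain lists
strip_classes <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else {
    x
  }
}

pipeline_reads <- function(path, stage) {
  if (is.null(path))
    stop("stage '", stage, "' has no input FASTQ (set wgs_fastq/",
         "terminal_fastq or run the matching simulation stage)",
         call. = FALSE)
  read_fastq(path)
}

# ---- report writers ---------------------------------------------------

fmt_frac <- function(x) ifelse(is.na(x), ".", format(x, digits = 15))

write_composition_report <- function(comp, tsv, json) {
  df <- data.frame(
    n_reads_total = comp$n_reads_total,
    n_reads_telomeric = comp$n_reads_telomeric,
    bases_considered = comp$bases_considered,
    bases_wt = comp$bases_wt, bases_var = comp$bases_var,
    bases_other = comp$bases_other,
    frac_wt = fmt_frac(comp$frac_wt), frac_var = fmt_frac(comp$frac_var),
    frac_other = fmt_frac(comp$frac_other),
    frac_wt_repeats = fmt_frac(comp$frac_wt_repeats),
    frac_var_repeats = fmt_frac(comp$frac_var_repeats)
  )
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(comp), json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(tsv)
}

write_runlengths_report <- function(runs, tsv) {
  utils::write.table(as.data.frame(runs), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv)
}

write_processivity_report <- function(est, tsv, json) {
  rows <- lapply(c("wt", "var"), function(cls) {
    e <- est[[cls]]
    if (inherits(e, "processivity_error"))
      data.frame(class = cls, slope = ".", intercept = ".", r_squared = ".",
                 p_add = ".", p_x = ".", rho_used = ".", n_points_fit = ".",
                 clamped = ".", error = e$error)
    else
      data.frame(class = cls, slope = fmt_frac(e$slope),
                 intercept = fmt_frac(e$intercept),
                 r_squared = fmt_frac(e$r_squared),
                 p_add = fmt_frac(e$p_add), p_x = fmt_frac(e$p_x),
                 rho_used = fmt_frac(e$rho_used),
                 n_points_fit = e$n_points_fit,
                 clamped = tolower(e$clamped), error = ".")
  })
  utils::write.table(do.call(rbind, rows), tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(lapply(unclass(est), unclass), json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(tsv)
}

write_terminal_report <- function(spec, tsv, json) {
  rot <- terminal_rotations()
  df <- data.frame(
    permutation = c(names(spec$counts), "other"),
    class = c(rep(c("wt", "var"), each = 6L), "other"),
    count = c(unname(spec$counts), spec$other_count),
    within_class_fraction = fmt_frac(c(
      unname(spec$within_class_fractions$wt),
      unname(spec$within_class_fractions$var), NA_real_))
  )
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- unclass(spec)
  out$calls <- NULL
  out$within_class_fractions <- lapply(out$within_class_fractions, as.list)
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(tsv)
}
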