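#' Default pipeline configuration
#'
#' Returns the full configuration list used by [run_all()]. Defaults
#' mirror the experimental design the pipeline emulates: a peroxide dose
#' series at 1, 2.5, 5 and 10 mM with 2 replicates, a 3-replicate
#' endogenous-stress (complex III inhibition) arm modeled as an effective
#' dose on the same axis, and the standard aggregation thresholds
#' (presence 2-of-2 peroxide / 2-of-3 endogenous, fold 2, CV 0.5,
#' dispersion 30 points, class bounds 2 and 5, ratio cap 20).
#'
#' @param seed Integer seed propagated to every stochastic stage.
#' @return Named list (see source for the documented key set).
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    doses = c(1, 2.5, 5, 10),
    ama_dose = 2,
    isotop_replicates = 2L,
    ama_replicates = 3L,
    oxicat_replicates = 3L,
    noise_cv = 0.2,
    dropout_rate = 0.05,
    fold_threshold = 2,
    cv_threshold = 0.5,
    sd_threshold = 30,
    class_bounds = c(2, 5),
    cap = 20,
    min_delta = 20
  )
}

#' Validate a pipeline configuration
#'
#' @param config List as from [default_config()] (possibly modified).
#' @return The config, invisibly, or an error naming the offending key.
#' @export
validate_config <- function(config) {
  need <- names(default_config())
  missing <- setdiff(need, names(config))
  if (length(missing) > 0L) {
    stop(sprintf("config missing key '%s'", missing[1L]), call. = FALSE)
  }
  pos <- c("fold_threshold", "cv_threshold", "sd_threshold", "cap",
           "noise_cv", "min_delta")
  for (key in pos) {
    if (key == "noise_cv") {
      if (config[[key]] < 0) {
        stop(sprintf("config key '%s' must be >= 0", key), call. = FALSE)
      }
    } else if (config[[key]] <= 0) {
      stop(sprintf("config key '%s' must be positive", key), call. = FALSE)
    }
  }
  if (any(config$doses < 0) || is.unsorted(config$doses, strictly = TRUE)) {
    stop("config doses must be non-negative and sorted ascending",
         call. = FALSE)
  }
  if (any(c(config$isotop_replicates, config$ama_replicates,
            config$oxicat_replicates) < 1L)) {
    stop("replicate counts must be >= 1", call. = FALSE)
  }
  if (length(config$class_bounds) != 2L ||
      config$class_bounds[1] <= 1 ||
      config$class_bounds[2] <= config$class_bounds[1]) {
    stop("class_bounds must be increasing and above 1", call. = FALSE)
  }
  invisible(config)
}

#' Read a JSON configuration file, filling unset keys from the defaults
#'
#' @param path JSON file with any subset of the [default_config()] keys.
#' @param seed Optional seed override (e.g. from a CLI flag; flags win).
#' @return Validated config list.
#' @export
read_config <- function(path, seed = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(config))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown config key '%s'", unknown[1L]), call. = FALSE)
    }
    config[names(user)] <- user
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  config
}

#' Run the full pipeline: simulate, aggregate, filter, classify, annotate
#'
#' Executes every stage on a protein FASTA and annotation table and writes
#' all stage TSVs plus a JSON run manifest (config echo, package version,
#' seed) to `outdir`. Identical config and seed give byte-identical
#' outputs. On error, partial outputs created by this run are removed.
#'
#' @param config Validated configuration list ([default_config()] /
#'   [read_config()]).
#' @param fasta Path to a protein FASTA file.
#' @param annotations Path to an annotation TSV ([read_annotations()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the output paths.
#' @export
run_all <- function(config, fasta, annotations, outdir) {
  validate_config(config)
  if (!file.exists(fasta)) {
    stop(sprintf("missing input: FASTA '%s'", fasta), call. = FALSE)
  }
  if (!file.exists(annotations)) {
    stop(sprintf("missing input: annotation table '%s'", annotations),
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(created), add = TRUE)
  emit <- function(x, name, schema) {
    path <- file.path(outdir, name)
    write_stage_tsv(x, path, schema)
    created <<- c(created, path)
    path
  }

  ann <- read_annotations(annotations)
  proteins <- read_fasta(fasta)
  sites <- cysteine_sites(proteins)
  truth <- simulate_truth(sites, seed = config$seed)
  paths <- list()
  paths$truth <- emit(truth, "truth.tsv", "truth_record")

  doses <- stats::setNames(config$doses,
                           sprintf("H2O2_%gmM", config$doses))
  iso_obs <- simulate_isotop(
    truth, doses, n_replicates = config$isotop_replicates,
    noise_cv = config$noise_cv, dropout_rate = config$dropout_rate,
    seed = config$seed + 1L, cap = config$cap
  )
  paths$isotop_observations <-
    emit(iso_obs, "isotop_observations.tsv", "ratio_observation")
  for (cond in names(doses)) {
    sub <- iso_obs[iso_obs$condition == cond, , drop = FALSE]
    emit(sub, sprintf("isotop_observations_%s.tsv", cond),
         "ratio_observation")
  }

  ama_obs <- simulate_isotop(
    truth, c(AMA = config$ama_dose),
    n_replicates = config$ama_replicates, noise_cv = config$noise_cv,
    dropout_rate = config$dropout_rate, seed = config$seed + 2L,
    cap = config$cap
  )
  paths$ama_observations <-
    emit(ama_obs, "ama_observations.tsv", "ratio_observation")

  iso_sum <- aggregate_replicates(iso_obs,
                                  required_k = config$isotop_replicates,
                                  of_n = config$isotop_replicates)
  iso_sum <- filter_changed(iso_sum, config$fold_threshold,
                            config$cv_threshold)
  ama_sum <- aggregate_replicates(ama_obs, required_k = 2L,
                                  of_n = config$ama_replicates)
  ama_sum <- filter_changed(ama_sum, config$fold_threshold,
                            config$cv_threshold)
  mito <- filter_mitochondrial(rbind(iso_sum, ama_sum), ann)
  paths$site_summaries <-
    emit(mito$summaries, "site_summaries.tsv", "site_summary")

  med <- median_summary(mito$summaries)
  paths$medians <- emit(med, "condition_medians.tsv", "condition_median")

  classes <- classify_sites(
    mito$summaries[mito$summaries$condition %in% names(doses), ,
                   drop = FALSE],
    doses, class_bounds = config$class_bounds
  )
  paths$classes <- emit(classes, "sensitivity_classes.tsv",
                        "sensitivity_class")

  oxi_obs <- simulate_oxicat(
    truth, c(control = 0, AMA = config$ama_dose),
    n_replicates = config$oxicat_replicates, noise_cv = config$noise_cv,
    dropout_rate = config$dropout_rate, seed = config$seed + 3L,
    cap = config$cap
  )
  paths$oxicat_observations <-
    emit(oxi_obs, "oxicat_observations.tsv", "ratio_observation")
  oxi <- aggregate_oxidation(oxidation_from_observations(oxi_obs),
                             required_k = 2L,
                             of_n = config$oxicat_replicates,
                             sd_threshold = config$sd_threshold)
  paths$oxidation_records <-
    emit(oxi, "oxidation_records.tsv", "oxidation_record")
  delta <- delta_oxidation(
    retained(oxi[oxi$condition == "control", , drop = FALSE]),
    retained(oxi[oxi$condition == "AMA", , drop = FALSE]),
    min_delta = config$min_delta
  )
  paths$delta_oxidation <-
    emit(delta, "delta_oxidation.tsv", "delta_oxidation")

  bins <- bin_pathways(
    mito$summaries[mito$summaries$condition ==
                     names(doses)[which.max(doses)], , drop = FALSE],
    ann, high_threshold = config$class_bounds[2]
  )
  paths$pathway_bins <- emit(bins, "pathway_bins.tsv", "pathway_bin")

  manifest <- list(
    package = "cysredox",
    version = as.character(utils::packageVersion("cysredox")),
    seed = config$seed,
    config = config,
    mito_report = mito$report,
    n_sites = nrow(sites)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  created <- c(created, manifest_path)
  paths$manifest <- manifest_path
  ok <- TRUE
  invisible(paths)
}

# minimal flag parser: --key value pairs after the subcommand
.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      stop(sprintf("unexpected argument '%s'", args[i]), call. = FALSE)
    }
    if (i == length(args)) {
      stop(sprintf("flag '%s' is missing a value", args[i]), call. = FALSE)
    }
    flags[[substring(args[i], 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (the full pipeline), `simulate`, `isotop`,
#' `oxicat`, `annotate`, `report`. Common flags: `--seed`, `--config`
#' (JSON), `--outdir`; `run-all` and `simulate` additionally need
#' `--fasta` and `--annotations`. Flags override config-file values.
#' Stage subcommands read the versioned TSVs a previous stage wrote, so
#' stage-by-stage invocation reproduces `run-all` exactly.
#'
#' @param args Character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status, invisibly (0 on success).
#' @export
cys_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cysredox <run-all|simulate|isotop|oxicat|annotate|report>",
    "[--seed N] [--config file.json] [--outdir dir]",
    "[--fasta f] [--annotations a] [--observations tsv]"
  )
  if (length(args) == 0L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1L]
  flags <- .parse_flags(args[-1L])
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
  config <- read_config(flags$config, seed = seed)
  outdir <- if (!is.null(flags$outdir)) flags$outdir else "cysredox_out"
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[cysredox] ", fmt), ...))
  }
  t0 <- Sys.time()
  switch(cmd,
    "run-all" = {
      paths <- run_all(config, flags$fasta, flags$annotations, outdir)
      log_stage("run-all wrote %d outputs to %s in %.1fs",
                length(paths), outdir,
                as.numeric(difftime(Sys.time(), t0, units = "secs")))
    },
    "simulate" = {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      sites <- cysteine_sites(read_fasta(flags$fasta))
      truth <- simulate_truth(sites, seed = config$seed)
      write_stage_tsv(truth, file.path(outdir, "truth.tsv"),
                      "truth_record")
      doses <- stats::setNames(config$doses,
                               sprintf("H2O2_%gmM", config$doses))
      obs <- simulate_isotop(truth, doses,
                             n_replicates = config$isotop_replicates,
                             noise_cv = config$noise_cv,
                             dropout_rate = config$dropout_rate,
                             seed = config$seed + 1L, cap = config$cap)
      write_stage_tsv(obs, file.path(outdir, "isotop_observations.tsv"),
                      "ratio_observation")
      log_stage("simulate wrote %d observation rows", nrow(obs))
    },
    "isotop" = {
      obs <- read_stage_tsv(flags$observations, "ratio_observation")
      summ <- aggregate_replicates(obs,
                                   required_k = config$isotop_replicates,
                                   of_n = config$isotop_replicates)
      summ <- filter_changed(summ, config$fold_threshold,
                             config$cv_threshold)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_stage_tsv(summ, file.path(outdir, "site_summaries.tsv"),
                      "site_summary")
      log_stage("isotop wrote %d site summaries", nrow(summ))
    },
    "oxicat" = {
      obs <- read_stage_tsv(flags$observations, "ratio_observation")
      oxi <- aggregate_oxidation(oxidation_from_observations(obs),
                                 required_k = 2L,
                                 of_n = config$oxicat_replicates,
                                 sd_threshold = config$sd_threshold)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_stage_tsv(oxi, file.path(outdir, "oxidation_records.tsv"),
                      "oxidation_record")
      log_stage("oxicat wrote %d oxidation records", nrow(oxi))
    },
    "annotate" = {
      summ <- read_stage_tsv(flags$observations, "site_summary")
      ann <- read_annotations(flags$annotations)
      mito <- filter_mitochondrial(summ, ann)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_stage_tsv(mito$summaries,
                      file.path(outdir, "site_summaries_mito.tsv"),
                      "site_summary")
      log_stage("annotate retained %d rows (%d proteins, %d sites)",
                nrow(mito$summaries), mito$report$n_proteins,
                mito$report$n_sites)
    },
    "report" = {
      summ <- read_stage_tsv(flags$observations, "site_summary")
      med <- median_summary(summ)
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      write_stage_tsv(med, file.path(outdir, "condition_medians.tsv"),
                      "condition_median")
      log_stage("report wrote medians for %d conditions", nrow(med))
    },
    {
      message(usage)
      return(invisible(1L))
    }
  )
  invisible(0L)
}
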