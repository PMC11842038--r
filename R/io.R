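# File formats and the end-to-end pipeline driver.
#
# Numeric payloads round-trip losslessly: matrices are written as
# tab-separated text at full double precision (%.17g) with a JSON sidecar
# carrying units and provenance (seed, parameters). Units are explicit in
# every sidecar because the pipeline mixes uV, dB SPL and dB HL.

#' Write / read an epoch set
#'
#' The epochs-by-samples matrix is stored as `<prefix>.tsv` at full double
#' precision and the metadata (sampling rate, polarity labels, units, seed)
#' as `<prefix>.json`. The round trip is bit-identical.
#'
#' @param epochs an [epoch_set()].
#' @param prefix path prefix without extension.
#' @return `write_epoch_set` returns the two paths invisibly;
#'   `read_epoch_set` returns the `epoch_set`.
#' @export
write_epoch_set <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  lines <- apply(epochs$data, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, tsv)
  jsonlite::write_json(
    list(format = "epoch_set", units = "uV",
         sample_rate_hz = epochs$fs,
         epoch_duration_s = epochs$epoch_duration,
         n_epochs = nrow(epochs$data), n_samples = ncol(epochs$data),
         polarity = epochs$polarity,
         seed = attr(epochs, "seed"),
         package_version = as.character(utils::packageVersion("ramefr"))),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' @rdname write_epoch_set
#' @export
read_epoch_set <- function(prefix) {
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(js$format, "epoch_set"))
    stop("not an epoch_set sidecar: ", prefix, ".json")
  data <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  if (nrow(data) != js$n_epochs || ncol(data) != js$n_samples)
    stop("epoch matrix dimensions disagree with the sidecar")
  out <- epoch_set(data, js$sample_rate_hz, js$polarity)
  attr(out, "seed") <- js$seed
  out
}

#' Write / read a DPOAE growth function as CSV
#'
#' Columns `L2_dB`, `Ldc_dB`, `Ldc_sd_dB`.
#'
#' @param growth a [dp_growth()].
#' @param path CSV path.
#' @param f2,ratio probe frequency and primary ratio used when reading.
#' @export
write_growth_csv <- function(growth, path) {
  stopifnot(inherits(growth, "dp_growth"))
  utils::write.csv(data.frame(L2_dB = growth$L2, Ldc_dB = growth$Ldc_mean,
                              Ldc_sd_dB = growth$Ldc_sd),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path, f2 = 4000, ratio = 1.2) {
  df <- utils::read.csv(path)
  need <- c("L2_dB", "Ldc_dB", "Ldc_sd_dB")
  if (!all(need %in% names(df)))
    stop("growth CSV must have columns: ", paste(need, collapse = ", "))
  dp_growth(df$L2_dB, df$Ldc_dB, df$Ldc_sd_dB, f2 = f2, ratio = ratio)
}

#' Write / read a cohort table as CSV
#'
#' Validates group labels against the fixed set
#' `yNH, yNH_excluded, oNH, oHI` and rejects duplicated subject ids or
#' non-finite values.
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("subject", "group") %in% names(df)))
    stop("cohort CSV must have subject and group columns")
  bad <- setdiff(unique(df$group), cohort_groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$subject)) stop("duplicated subject ids")
  num <- df[vapply(df, is.numeric, logical(1))]
  if (!all(vapply(num, function(c) all(is.finite(c)), logical(1))))
    stop("non-finite values in cohort table")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write stimulus samples with a JSON sidecar of the spec
#'
#' Samples are written as one value per line at full double precision;
#' the sidecar records the complete [stimulus_spec()] plus the linear
#' pressure scale.
#'
#' @param stim a `stimulus`.
#' @param prefix path prefix without extension.
#' @export
write_stimulus <- function(stim, prefix) {
  stopifnot(inherits(stim, "stimulus"))
  writeLines(sprintf("%.17g", stim$samples), paste0(prefix, ".txt"))
  jsonlite::write_json(c(list(format = "stimulus", scale_pa = stim$scale),
                         unclass(stim$spec)),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Default pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]; every stochastic stage
#' receives a sub-seed derived from the global seed. Defaults are sized for a
#' quick demonstration run; the measurement-scale values (1000 epochs, 200
#' bootstrap runs) are the stage-function defaults.
#'
#' @param seed global seed.
#' @param n_epochs epochs per synthetic EFR recording.
#' @param n_draws epochs per bootstrap draw.
#' @param n_boot EFR bootstrap runs.
#' @param dp_n_boot DPOAE bootstrap draws.
#' @param cohort_n_per_group optional override of every cohort group size.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_epochs = 200, n_draws = 200,
                            n_boot = 50, dp_n_boot = 200,
                            cohort_n_per_group = NULL) {
  structure(list(seed = seed, n_epochs = n_epochs, n_draws = n_draws,
                 n_boot = n_boot, dp_n_boot = dp_n_boot,
                 cohort_n_per_group = cohort_n_per_group),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Executes stimulus synthesis and level matching, synthetic EFR estimation
#' for the SAM- and RAM-like ground truths, DPOAE growth simulation and
#' threshold extraction, cohort generation and the headline statistics
#' (EFR-SRT correlation, two-predictor regression with commonality
#' decomposition), writing JSON reports and a run manifest stamped with the
#' seed, a config checksum and the package version.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest list, invisibly; side effect: JSON files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # stage 1: stimuli and level matching
  sam <- synthesize_sam(stimulus_spec(kind = "sam"))
  ram <- synthesize_ram(stimulus_spec(kind = "ram", level = NA))
  matched <- match_peak_to_peak(sam, ram)
  stim_report <- list(sam_level_db_spl = sam$spec$level,
                      ram_matched_level_db_spl = matched$matched_level,
                      ram_scale = matched$scale,
                      level_offset_db = matched$level_offset)

  # stage 2: synthetic EFR recordings and the bootstrapped marker
  truths <- list(
    sam = efr_ground_truth(amplitudes = c(0.065, 0.01, 0.004, 0.002, 0.001)),
    ram = efr_ground_truth(amplitudes = c(0.18, 0.09, 0.04, 0.015, 0.006)))
  efr_report <- lapply(seq_along(truths), function(i) {
    ep <- generate_epochs(truths[[i]], noise_model(),
                          n_epochs = config$n_epochs,
                          seed = derive_seed(seed, i))
    fit <- efr_fit(ep, n_draws = config$n_draws, n_boot = config$n_boot,
                   seed = derive_seed(seed, 10 + i))
    list(amplitude_uv = fit$amplitude, sd_uv = fit$bootstrap_sd,
         ptn_uv = fit$ptn, phases_rad = fit$phases,
         true_half_pp = {
           w <- reconstruct_waveform(truths[[i]]$amplitudes,
                                     truths[[i]]$phases, 120, 16384, 0.5)
           (max(w) - min(w)) / 2
         })
  })
  names(efr_report) <- names(truths)

  # stage 3: DPOAE growth and threshold
  growth <- generate_dp_growth(c(-25 - 42 * 1.1, 1.1), noise_sd = 0.8,
                               seed = derive_seed(seed, 21))
  dp <- dpoae_fit(growth, n_boot = config$dp_n_boot,
                  seed = derive_seed(seed, 22))
  dp_report <- list(th_dp_db_spl = dp$th_dp, sd_db = dp$sd,
                    n_valid = dp$n_valid, criterion_db_spl = dp$criterion)

  # stage 4: cohort and headline statistics
  cohort <- generate_cohort(n_per_group = config$cohort_n_per_group,
                            seed = derive_seed(seed, 31))
  corr <- correlation_auto(cohort$efr_ram, cohort$srt_sin_hp)
  reg <- fit_linear_models(cohort, "srt_sin_hp", c("efr_ram", "th_a"))
  com <- commonality(cohort$srt_sin_hp, cohort[c("efr_ram", "th_a")])
  stats_report <- list(
    efr_ram_vs_srt_sin_hp = corr[c("method", "estimate", "n", "p")],
    regression = list(adj_r_squared = reg$adj_r_squared,
                      f = reg$f_statistic, df = reg$df,
                      vif = as.list(reg$vif),
                      durbin_watson = reg$durbin_watson),
    commonality = list(component = as.character(com$component),
                       r2 = com$r2, pct_of_total = com$pct_of_total,
                       total_r2 = attr(com, "total_r2")))

  reports <- list(stimuli = stim_report, efr = efr_report,
                  dpoae = dp_report, statistics = stats_report)
  for (nm in names(reports))
    jsonlite::write_json(reports[[nm]], file.path(out_dir, paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(seed = seed,
                   config = unclass(config),
                   config_hash = config_hash(unclass(config)),
                   package_version = as.character(utils::packageVersion("ramefr")),
                   outputs = file.path(out_dir, paste0(names(reports), ".json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, reports))
}
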