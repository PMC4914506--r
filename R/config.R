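#' Pipeline configuration with study defaults
#'
#' All numeric constants of the processing pipeline and the interaction
#' controller, keyed by name. Defaults are the values of the study design this
#' package implements: 5 kHz acquisition decimated to 25 Hz with a 4 Hz
#' anti-alias cutoff, 1 s classification windows, slope-feature segments of
#' 400 ms every 120 ms, 8 xDAWN pseudo-channels, an SVM complexity grid
#' 10^0..10^-6 with 5-fold internal cross-validation, ISI bounds 5-35 s in
#' 5 s steps around a 25 s preset with a two-in-a-row trigger, a 13 s response
#' timeout, 15 s training-latency cutoff, 1.1 s message presentation, +-5 s
#' jitter for fixed-ISI runs, a 0.1-30 Hz ERP band with -0.1..1.0 s epochs,
#' +-100 uV artifact bound and a 0.3-0.7 s positive-peak window.
#'
#' @param ... named overrides of any listed constant.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fs_raw = 5000, fs_dec = 25, anti_alias_cutoff = 4,
    window_s = 1.0, seg_len_s = 0.4, seg_step_s = 0.12,
    n_pseudo = 8, complexity_exponents = 0:-6, cv_folds = 5,
    isi_preset = 25, isi_min = 5, isi_max = 35, isi_step = 5,
    streak_len = 2, response_timeout = 13, training_latency_cutoff = 15,
    presentation_s = 1.1, jitter_s = 5,
    erp_band = c(0.1, 30), erp_window = c(-0.1, 1.0),
    artifact_abs_uv = 100, peak_window = c(0.3, 0.7),
    dc_time_constant = 2
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  assert_that(length(bad) == 0, "unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  assert_that(cfg$isi_min <= cfg$isi_preset && cfg$isi_preset <= cfg$isi_max,
              "need isi_min <= isi_preset <= isi_max")
  assert_that(cfg$isi_step > 0, "isi_step must be > 0")
  assert_that(cfg$streak_len >= 1, "streak_len must be >= 1")
  assert_that(cfg$seg_len_s > 0 && cfg$seg_step_s > 0, "segment grid must be positive")
  last_start <- cfg$seg_step_s * floor((cfg$window_s - cfg$seg_len_s) / cfg$seg_step_s + 1e-9)
  assert_that(cfg$seg_len_s + last_start <= cfg$window_s + 1e-9,
              "segment grid exceeds the classification window")
  assert_that(cfg$erp_band[1] > 0 && cfg$erp_band[1] < cfg$erp_band[2],
              "invalid ERP band")
  assert_that(cfg$artifact_abs_uv > 0, "artifact bound must be positive")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Keys present in the file override the defaults of [pipeline_config()];
#' everything else keeps its default. Invariants are re-checked.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file of key-value overrides.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(over)) over <- list()
  do.call(pipeline_config, as.list(over))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}
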