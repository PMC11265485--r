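# Orchestration: simulate/load -> ROI metrics -> NPS -> TTF -> dose model,
# with deterministic, table-based reporting.

#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: a simulation design, a fixture
#' directory, or a DICOM directory.
#'
#' @param design `NULL`, or a list describing a simulation:
#'   `models` (named list of [noise_model()]s), `doses`, `repeats`,
#'   `n_slices`, `thickness`; missing entries default to the study design
#'   (5 doses 5-25 mGy, 3 repeats, 40 slices of 2.5 mm).
#' @param fixture_dir,dicom_dir alternative input sources.
#' @param layout phantom geometry, default [ctiq_layout()].
#' @param baseline algorithm label for relative CNR / percent differences.
#' @param reference algorithm for the dose-reduction model.
#' @param d_ref reference dose (mGy) for the dose-reduction model.
#' @param ttf_dose dose level analyzed for TTF (`NULL`: highest available).
#' @param nps_roi_size NPS ROI side, pixels.
#' @param ntd_rois see [stack_metrics()].
#' @param out_dir output directory for report tables.
#' @param seed master seed for all randomness in the run.
#' @return An object of class `ctiq_config`.
#' @export
ctiq_config <- function(design = NULL, fixture_dir = NULL, dicom_dir = NULL,
                        layout = ctiq_layout(), baseline = "FBP",
                        reference = "IR50", d_ref = 25, ttf_dose = NULL,
                        nps_roi_size = 32, ntd_rois = "insert",
                        out_dir = tempfile("ctiq_run_"), seed = 1) {
  sources <- c(!is.null(design), !is.null(fixture_dir), !is.null(dicom_dir))
  if (sum(sources) != 1)
    stop("exactly one input source (design, fixture_dir or dicom_dir) required")
  if (!is.null(design)) {
    defaults <- list(models = ctiq_study_models(layout$pixel_spacing),
                     doses = c(5, 10, 15, 20, 25), repeats = 3,
                     n_slices = 40, thickness = 2.5)
    for (f in names(defaults))
      if (is.null(design[[f]])) design[[f]] <- defaults[[f]]
  }
  structure(list(design = design, fixture_dir = fixture_dir,
                 dicom_dir = dicom_dir, layout = layout, baseline = baseline,
                 reference = reference, d_ref = d_ref, ttf_dose = ttf_dose,
                 nps_roi_size = nps_roi_size, ntd_rois = ntd_rois,
                 out_dir = out_dir, seed = seed),
            class = "ctiq_config")
}

#' Load a run configuration from YAML
#'
#' Scalars map directly onto [ctiq_config()] arguments; a `design` block may
#' give `doses`, `repeats`, `n_slices`, `thickness` and a `models` list of
#' [noise_model()] argument sets.
#'
#' @param path YAML file.
#' @return A `ctiq_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  layout <- if (is.null(y$layout)) ctiq_layout() else
    do.call(ctiq_layout, y$layout)
  design <- y$design
  if (!is.null(design$models))
    design$models <- stats::setNames(
      lapply(design$models, function(m) do.call(noise_model, m)),
      vapply(design$models, `[[`, character(1), "label"))
  args <- y[setdiff(names(y), c("layout", "design"))]
  do.call(ctiq_config, c(list(design = design, layout = layout), args))
}

#' List and sanity-check the stacks in an input directory
#'
#' Finds raw + JSON fixtures (`*.json` with a matching `*.raw`) and DICOM
#' series (subdirectories containing `*.dcm`), reads their metadata, and
#' rejects mixed pixel spacings within an (algorithm, dose, thickness)
#' analysis group, naming the offending scans.
#'
#' @param dir input directory.
#' @return A manifest data frame (zero rows, with a warning, if empty).
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  rows <- list()
  for (js in sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))) {
    if (!file.exists(sub("\\.json$", ".raw", js))) next
    st <- read_fixture(js)
    rows[[length(rows) + 1]] <- data.frame(
      scan_id = st$scan_id, format = "fixture", path = js,
      algorithm = st$algorithm, dose = st$dose_ctdi,
      thickness = st$slice_thickness, spacing = st$pixel_spacing,
      n_slices = n_slices(st), stringsAsFactors = FALSE)
  }
  for (sub in sort(list.dirs(dir, recursive = FALSE))) {
    if (!length(list.files(sub, pattern = "\\.dcm$"))) next
    st <- read_dicom(sub)
    rows[[length(rows) + 1]] <- data.frame(
      scan_id = st$scan_id, format = "dicom", path = sub,
      algorithm = st$algorithm, dose = st$dose_ctdi,
      thickness = st$slice_thickness, spacing = st$pixel_spacing,
      n_slices = n_slices(st), stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no stacks found in ", dir)
    return(data.frame(scan_id = character(), format = character(),
                      path = character(), algorithm = character(),
                      dose = numeric(), thickness = numeric(),
                      spacing = numeric(), n_slices = integer(),
                      stringsAsFactors = FALSE))
  }
  manifest <- do.call(rbind, rows)
  grp <- interaction(manifest$algorithm, manifest$dose, manifest$thickness,
                     drop = TRUE)
  for (g in levels(grp)) {
    sub_m <- manifest[grp == g, ]
    if (length(unique(sub_m$spacing)) > 1)
      stop("inconsistent pixel spacing within analysis group ", g, ": ",
           paste(sub_m$scan_id, collapse = ", "))
  }
  manifest
}

load_stack <- function(row) {
  if (row$format == "fixture") read_fixture(row$path) else read_dicom(row$path)
}

#' Run the full image-quality pipeline
#'
#' Simulates (or loads) every scan, computes per-slice ROI metrics, the
#' per-condition aggregates with relative CNR against the baseline, NPS
#' curves with average frequency and percent difference versus baseline, TTF
#' at one dose level with f50 and percent difference, and the dose-reduction
#' table against the reference algorithm. All tables are written as CSV/JSON
#' under `config$out_dir`; the run is deterministic given `config$seed`.
#'
#' @param config a [ctiq_config()].
#' @param quiet suppress per-stage messages.
#' @return A `ctiq_report` list: `manifest`, `metrics`, `aggregate`,
#'   `nps_table`, `nps_curves`, `ttf_table`, `dose_table`, `provenance`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ctiq_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  layout <- config$layout

  # --- stage 1: acquire ------------------------------------------------
  t0 <- Sys.time()
  if (!is.null(config$design)) {
    d <- config$design
    stacks <- simulate_design(layout, d$models, d$doses, d$repeats,
                              d$n_slices, d$thickness, seed = config$seed)
    manifest <- attr(stacks, "manifest")
    manifest$format <- "simulated"
  } else {
    dir <- config$fixture_dir %||% config$dicom_dir
    manifest <- validate_inputs(dir)
    if (!nrow(manifest)) stop("stage acquire: no input stacks in ", dir)
    stacks <- lapply(seq_len(nrow(manifest)), function(i)
      load_stack(manifest[i, ]))
    names(stacks) <- manifest$scan_id
  }
  say("acquire: %d stacks, %d images (%.1f s)", nrow(manifest),
      sum(manifest$n_slices), as.numeric(Sys.time() - t0, units = "secs"))

  if (!config$baseline %in% manifest$algorithm)
    stop("baseline algorithm '", config$baseline, "' not present in the data")
  if (!config$reference %in% manifest$algorithm)
    stop("reference algorithm '", config$reference, "' not present in the data")

  rois <- roi_set(layout)

  # --- stage 2: ROI metrics --------------------------------------------
  t0 <- Sys.time()
  metrics <- do.call(rbind, lapply(stacks, function(st)
    stack_metrics(st, rois, ntd_rois = config$ntd_rois)))
  rownames(metrics) <- NULL
  agg <- aggregate_metrics(metrics, baseline = config$baseline)
  say("metrics: %d slice rows, %d aggregate cells (%.1f s)", nrow(metrics),
      nrow(agg), as.numeric(Sys.time() - t0, units = "secs"))

  # --- stage 3: NPS -----------------------------------------------------
  t0 <- Sys.time()
  conds <- unique(manifest[, c("algorithm", "dose", "thickness")])
  nps_rows <- list(); nps_curves <- list()
  for (i in seq_len(nrow(conds))) {
    ids <- manifest$scan_id[manifest$algorithm == conds$algorithm[i] &
                              manifest$dose == conds$dose[i] &
                              manifest$thickness == conds$thickness[i]]
    res <- tryCatch(
      estimate_nps(stacks[ids], layout, roi_size = config$nps_roi_size),
      error = function(e) stop("stage nps failed for scans ",
                               paste(ids, collapse = ", "), ": ",
                               conditionMessage(e)))
    nps_rows[[i]] <- data.frame(algorithm = conds$algorithm[i],
                                dose = conds$dose[i],
                                thickness = conds$thickness[i],
                                f_avg = res$f_avg,
                                total_power = res$total_power,
                                stringsAsFactors = FALSE)
    nps_curves[[i]] <- data.frame(algorithm = conds$algorithm[i],
                                  dose = conds$dose[i],
                                  thickness = conds$thickness[i],
                                  freq = res$freq_axis, nps = res$nps1d,
                                  nnps = res$nnps1d, stringsAsFactors = FALSE)
  }
  nps_table <- do.call(rbind, nps_rows)
  base_favg <- nps_table$f_avg[nps_table$algorithm == config$baseline]
  names(base_favg) <- paste(nps_table$dose[nps_table$algorithm == config$baseline],
                            nps_table$thickness[nps_table$algorithm == config$baseline])
  key <- paste(nps_table$dose, nps_table$thickness)
  nps_table$pct_vs_baseline <- 100 * (nps_table$f_avg / base_favg[key] - 1)
  say("nps: %d conditions (%.1f s)", nrow(nps_table),
      as.numeric(Sys.time() - t0, units = "secs"))

  # --- stage 4: TTF -----------------------------------------------------
  t0 <- Sys.time()
  ttf_dose <- config$ttf_dose %||% max(manifest$dose)
  ttf_rows <- list()
  for (alg in unique(manifest$algorithm)) {
    ids <- manifest$scan_id[manifest$algorithm == alg &
                              manifest$dose == ttf_dose]
    if (!length(ids)) next
    per_scan <- lapply(ids, function(id) tryCatch(
      estimate_ttf(stacks[[id]], layout),
      error = function(e) stop("stage ttf failed for scan ", id, ": ",
                               conditionMessage(e))))
    avg <- ttf_average(per_scan)
    ttf_rows[[alg]] <- data.frame(algorithm = alg, dose = ttf_dose,
                                  f50 = as.numeric(avg$f50),
                                  contrast = avg$contrast,
                                  stringsAsFactors = FALSE)
  }
  ttf_table <- do.call(rbind, ttf_rows)
  rownames(ttf_table) <- NULL
  base_f50 <- ttf_table$f50[ttf_table$algorithm == config$baseline]
  ttf_table$pct_vs_baseline <- 100 * (ttf_table$f50 / base_f50 - 1)
  say("ttf: %d algorithms at %g mGy (%.1f s)", nrow(ttf_table), ttf_dose,
      as.numeric(Sys.time() - t0, units = "secs"))

  # --- stage 5: dose model ---------------------------------------------
  t0 <- Sys.time()
  scan_noise <- stats::aggregate(noise ~ scan_id + algorithm + dose + thickness,
                                 metrics, mean)
  fits <- lapply(split(scan_noise, scan_noise$algorithm), function(d)
    if (nrow(d) >= 3) fit_noise_dose(d$dose, d$noise, d$algorithm[1]) else NULL)
  fits <- Filter(Negate(is.null), fits)
  dose_rows <- list()
  if (config$reference %in% names(fits)) {
    for (alg in setdiff(names(fits), config$reference)) {
      dr <- dose_reduction(fits[[alg]], fits[[config$reference]], config$d_ref)
      dose_rows[[alg]] <- data.frame(
        test = alg, reference = config$reference, d_ref = config$d_ref,
        d_equiv = dr$d_equiv, delta = dr$delta, percent = dr$percent,
        percent_rounded = round(dr$percent), ci_low = dr$ci95[1],
        ci_high = dr$ci95[2], p = dr$p, stringsAsFactors = FALSE)
    }
  }
  dose_table <- do.call(rbind, dose_rows)
  rownames(dose_table) <- NULL
  say("dose model: %d comparisons vs %s (%.1f s)",
      if (is.null(dose_table)) 0L else nrow(dose_table), config$reference,
      as.numeric(Sys.time() - t0, units = "secs"))

  # --- stage 6: write reports ------------------------------------------
  wcsv <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(out, f), row.names = FALSE)
  wcsv(manifest, "manifest.csv")
  wcsv(metrics, "metrics_per_slice.csv")
  wcsv(agg, "metrics_aggregate.csv")
  wcsv(do.call(rbind, nps_curves), "nps_curves.csv")
  wcsv(nps_table, "nps_summary.csv")
  wcsv(ttf_table, "ttf_summary.csv")
  wcsv(dose_table, "dose_reduction.csv")
  config_json <- file.path(out, "config.json")
  jsonlite::write_json(serialize_config(config), config_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  provenance <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(config_json)),
                     package_version = as.character(utils::packageVersion("ctiq")),
                     n_stacks = nrow(manifest),
                     n_images = sum(manifest$n_slices))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(nps = nps_table, ttf = ttf_table,
                            dose_reduction = dose_table),
                       file.path(out, "summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")

  structure(list(manifest = manifest, metrics = metrics, aggregate = agg,
                 nps_table = nps_table,
                 nps_curves = do.call(rbind, nps_curves),
                 ttf_table = ttf_table, dose_table = dose_table,
                 provenance = provenance, out_dir = out),
            class = "ctiq_report")
}

# config as plain lists for JSON provenance (noise models flattened)
serialize_config <- function(config) {
  x <- unclass(config)
  if (!is.null(x$design))
    x$design$models <- lapply(x$design$models, unclass)
  x$layout <- unclass(x$layout)
  x
}

#' @export
print.ctiq_report <- function(x, ...) {
  cat("ctiq pipeline report\n")
  cat(sprintf("  %d stacks / %d images; outputs in %s\n",
              nrow(x$manifest), x$provenance$n_images, x$out_dir))
  cat(sprintf("  aggregate cells: %d; NPS conditions: %d; TTF algorithms: %d; dose comparisons: %d\n",
              nrow(x$aggregate), nrow(x$nps_table),
              if (is.null(x$ttf_table)) 0L else nrow(x$ttf_table),
              if (is.null(x$dose_table)) 0L else nrow(x$dose_table)))
  invisible(x)
}
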