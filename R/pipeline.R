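#' Pipeline configuration
#'
#' Validated bundle of every setting the end-to-end analysis needs. Unknown
#' names are rejected with a message naming the offending key, so typos in
#' config files fail early rather than silently using a default.
#'
#' @param ... named settings overriding the defaults:
#' \describe{
#'   \item{synthetic}{a [synthetic_spec()] (the simulated study), or `NULL`
#'     to supply `dtg` and `composition` directly to [run_pipeline()].}
#'   \item{test_fraction}{held-out fraction for the shuffle split (0.25).}
#'   \item{models}{non-empty subset of PLS/SVR/GPR/MLR/RF/SNN.}
#'   \item{components}{component subset to model (`NULL` = all).}
#'   \item{max_latent, cv_folds}{PLS latent-variable selection settings.}
#'   \item{vip_threshold, vip_min_run, vip_merge_gap}{interval extraction
#'     settings in VIP units / degC / degC.}
#'   \item{refit_components}{components for the interval-restricted refit
#'     comparison (`NULL` = first three modelled components).}
#'   \item{n_bins}{bins for the content density distributions (20).}
#'   \item{seed}{master seed for split and stochastic fits.}
#' }
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    synthetic = synthetic_spec(),
    test_fraction = 0.25,
    models = c("PLS", "SVR", "GPR", "MLR", "RF", "SNN"),
    components = NULL,
    max_latent = 30,
    cv_folds = 10,
    vip_threshold = 1,
    vip_min_run = 2,
    vip_merge_gap = 5,
    refit_components = NULL,
    n_bins = 20,
    seed = 1L)
  override <- list(...)
  if (length(override) && (is.null(names(override)) || any(names(override) == "")))
    stop("all config settings must be named")
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(override)) cfg[nm] <- list(override[[nm]])
  if (!length(cfg$models))
    stop("config error: empty model list")
  all_models <- c("PLS", "SVR", "GPR", "MLR", "RF", "SNN")
  if (!all(cfg$models %in% all_models))
    stop("unknown model(s): ",
         paste(setdiff(cfg$models, all_models), collapse = ", "))
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1)
    stop("test_fraction must be strictly between 0 and 1")
  if (cfg$vip_threshold <= 0) stop("vip_threshold must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar settings are taken from the file and validated by
#' [pipeline_config()]; a `synthetic` block, if present, may override the
#' scalar fields of the default [synthetic_spec()] (component definitions
#' stay at their defaults).
#'
#' @param path `.yml`/`.yaml` or `.json` file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    syn_known <- c("n_samples", "curve_noise_sd", "curve_noise_corr",
                   "replicate_noise_sd", "assay_noise_rel", "seed")
    unknown <- setdiff(names(raw$synthetic), syn_known)
    if (length(unknown))
      stop("unknown synthetic config key(s): ", paste(unknown, collapse = ", "))
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  }
  do.call(pipeline_config, raw)
}

#' Run the end-to-end analysis
#'
#' Executes the full sequence: simulate (or accept provided data),
#' preprocess, descriptive composition statistics, model fitting and
#' evaluation, VIP screening with interval extraction, and the
#' interval-restricted refit comparison. Deterministic for a fixed config:
#' rerunning yields identical tables. A component whose screening or
#' evaluation fails is reported with a warning and the remaining components
#' continue.
#'
#' @param config a [pipeline_config()].
#' @param dtg optional precomputed DTG matrix (samples x temperatures, with
#'   a `"temperature"` attribute); required if `config$synthetic` is `NULL`.
#' @param composition optional composition table aligned with `dtg`.
#' @return object of class `report_bundle`: list with elements
#'   `composition`, `dtg`, `density`, `correlation`, `high_pairs`, `split`,
#'   `evaluation`, `vip`, `intervals`, `intervals_compact`, `refit` and
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), dtg = NULL,
                         composition = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$synthetic) && (is.null(dtg) || is.null(composition)))
    stop("no synthetic spec in config: supply dtg and composition")

  if (!is.null(config$synthetic)) {
    composition <- generate_composition(config$synthetic)
    curves <- generate_dtg_curves(composition, config$synthetic)
    dtg <- dtg_matrix(curves)
  }
  comps <- config$components %||% setdiff(names(composition), "sample_id")

  density <- density_distribution(composition, n_bins = config$n_bins)
  corr <- correlation_matrix(composition)
  pairs <- high_correlation_pairs(corr, threshold = 0.9)

  split <- split_dataset(nrow(dtg), config$test_fraction, seed = config$seed)
  evaluation <- evaluate_all(dtg, composition, components = comps,
                             models = config$models, split = split,
                             max_A = config$max_latent,
                             cv_folds = config$cv_folds, seed = config$seed)

  temps <- attr(dtg, "temperature")
  vip <- list(); intervals <- list()
  for (comp in comps) {
    res <- tryCatch({
      y <- composition[[comp]]
      A <- select_n_latent(dtg[split$train, , drop = FALSE], y[split$train],
                           max_A = config$max_latent,
                           cv_folds = config$cv_folds, seed = config$seed)
      m <- fit_pls(dtg[split$train, , drop = FALSE], y[split$train], ncomp = A)
      prof <- vip_scores(m, temps)
      list(prof = prof,
           iv = extract_intervals(prof, threshold = config$vip_threshold,
                                  min_run = config$vip_min_run,
                                  merge_gap = config$vip_merge_gap))
    }, error = function(e) {
      warning("VIP screening failed for ", comp, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    vip[[comp]] <- res$prof
    intervals[[comp]] <- res$iv
  }

  refit_comps <- config$refit_components %||% utils::head(names(intervals), 3)
  refit <- list()
  for (comp in intersect(refit_comps, names(intervals))) {
    refit[[comp]] <- tryCatch(
      refit_and_compare(dtg, composition[[comp]], intervals[[comp]], split,
                        max_A = config$max_latent,
                        cv_folds = config$cv_folds, seed = config$seed),
      error = function(e) {
        warning("restricted refit failed for ", comp, ": ",
                conditionMessage(e))
        NULL
      })
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("pyrocal")),
    seed = config$seed,
    n_samples = nrow(dtg),
    n_grid = ncol(dtg),
    models = config$models,
    config_digest = unname(config_digest(config)))
  structure(list(composition = composition, dtg = dtg, density = density,
                 correlation = corr, high_pairs = pairs, split = split,
                 evaluation = evaluation, vip = vip, intervals = intervals,
                 intervals_compact = vapply(intervals, format_intervals, ""),
                 refit = refit, provenance = provenance),
            class = "report_bundle")
}

config_digest <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(config), file = tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d samples x %d grid points; %d evaluation row(s); %d interval set(s)\n",
              if (is.null(x$dtg)) 0L else nrow(x$dtg),
              if (is.null(x$dtg)) 0L else ncol(x$dtg),
              if (is.null(x$evaluation)) 0L else nrow(x$evaluation),
              length(x$intervals)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the stage outputs as CSV/JSON plus a human-readable summary, then a
#' manifest listing every file with its MD5 checksum.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the manifest data frame (`file`, `md5`).
#' @export
write_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("output directory not writable: ", out_dir)
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$composition))
    emit("composition.csv", function(p) write_composition_csv(bundle$composition, p))
  if (!is.null(bundle$dtg))
    emit("dtg_matrix.csv", function(p) write_dtg_csv(bundle$dtg, p))
  if (!is.null(bundle$correlation))
    emit("correlation.csv", function(p)
      utils::write.csv(bundle$correlation, p, row.names = TRUE))
  if (!is.null(bundle$high_pairs))
    emit("high_correlation_pairs.csv", function(p)
      utils::write.csv(bundle$high_pairs, p, row.names = FALSE))
  if (!is.null(bundle$density))
    emit("density.json", function(p)
      jsonlite::write_json(bundle$density, p, digits = NA))
  if (!is.null(bundle$evaluation))
    emit("evaluation.csv", function(p)
      utils::write.csv(bundle$evaluation, p, row.names = FALSE))
  if (length(bundle$vip)) {
    vip_df <- do.call(rbind, lapply(names(bundle$vip), function(nm)
      data.frame(component = nm,
                 temperature_C = bundle$vip[[nm]]$temperature,
                 vip = bundle$vip[[nm]]$vip)))
    emit("vip_profiles.csv", function(p)
      utils::write.csv(vip_df, p, row.names = FALSE))
  }
  if (length(bundle$intervals)) {
    iv_df <- do.call(rbind, lapply(names(bundle$intervals), function(nm) {
      iv <- bundle$intervals[[nm]]
      if (!nrow(iv)) return(NULL)
      data.frame(component = nm, t_lo = iv$t_lo, t_hi = iv$t_hi)
    }))
    emit("intervals.json", function(p)
      jsonlite::write_json(iv_df, p, digits = NA))
    emit("intervals.txt", function(p)
      writeLines(paste(names(bundle$intervals_compact),
                       bundle$intervals_compact, sep = "\t"), p))
  }
  if (length(bundle$refit)) {
    refit_df <- do.call(rbind, lapply(names(bundle$refit), function(nm)
      cbind(data.frame(component = nm), bundle$refit[[nm]]$comparison)))
    emit("refit_comparison.csv", function(p)
      utils::write.csv(refit_df, p, row.names = FALSE))
  }
  emit("provenance.json", function(p)
    jsonlite::write_json(bundle$provenance, p, auto_unbox = TRUE, digits = NA))
  emit("summary.txt", function(p) writeLines(report_summary(bundle), p))

  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

report_summary <- function(bundle) {
  lines <- c(sprintf("pyrocal report: %d samples, %d grid points",
                     if (is.null(bundle$dtg)) 0L else nrow(bundle$dtg),
                     if (is.null(bundle$dtg)) 0L else ncol(bundle$dtg)),
             sprintf("seed %s, config %s",
                     bundle$provenance$seed %||% "-",
                     bundle$provenance$config_digest %||% "-"))
  if (!is.null(bundle$evaluation) && nrow(bundle$evaluation)) {
    lines <- c(lines, "", "model evaluation (test R2 by model, median over components):")
    med <- tapply(bundle$evaluation$r2_test, bundle$evaluation$model, stats::median)
    lines <- c(lines, sprintf("  %-4s %6.3f", names(med), med))
  }
  if (length(bundle$intervals_compact)) {
    lines <- c(lines, "", "characteristic temperature intervals (VIP > threshold):")
    lines <- c(lines, sprintf("  %-24s %s", names(bundle$intervals_compact),
                              bundle$intervals_compact))
  }
  lines
}

#' Read key report tables back from disk
#'
#' Inverse of [write_report()] for the tabular artifacts, used to verify
#' that reports round-trip.
#'
#' @param out_dir directory written by [write_report()].
#' @return list with whichever of `composition`, `dtg`, `evaluation`,
#'   `intervals`, `manifest` exist on disk.
#' @export
read_report <- function(out_dir) {
  out <- list()
  rd <- function(name, reader) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) reader(p) else NULL
  }
  out$composition <- rd("composition.csv", read_composition_csv)
  out$dtg <- rd("dtg_matrix.csv", read_dtg_csv)
  out$evaluation <- rd("evaluation.csv", function(p) utils::read.csv(p))
  out$intervals <- rd("intervals.json", function(p)
    jsonlite::read_json(p, simplifyVector = TRUE))
  out$manifest <- rd("manifest.csv", function(p) utils::read.csv(p))
  out[!vapply(out, is.null, logical(1))]
}
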