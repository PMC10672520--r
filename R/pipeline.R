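#' Run the full analysis pipeline from a config
#'
#' Orchestrates segment -> metrics -> correlate -> distance -> shuffle for
#' one recording and writes a spreadsheet report with CSV mirrors plus a
#' manifest. Reruns with the same config and seed produce byte-identical
#' CSV outputs. A single global `seed` is fanned out to fixed stage-local
#' offsets so toggling one stage does not perturb another's randomness.
#'
#' Config keys (YAML file or nested list; all optional unless noted):
#' \describe{
#'   \item{input}{`store:` zarr directory, or `traces_csv:` (+
#'     `positions_csv:`), or `synthetic:` with [synth_config()] fields.
#'     Required.}
#'   \item{fps}{Frame rate for store/CSV inputs (default 20).}
#'   \item{segmentation}{`wnd_size`, `warm`, `cold`, `mode`.}
#'   \item{metrics}{`interval_s`, `nsd_threshold`.}
#'   \item{correlation}{`method`, `lag`, `threshold`.}
#'   \item{distance}{`enabled`, `kind`, `weighted`.}
#'   \item{shuffle}{`enabled`, `ratio`, `num_of_shuffles`.}
#'   \item{out}{Output directory (required).}
#'   \item{seed}{Integer seed recorded in every output.}
#'   \item{plots}{Write PNG figures (default off).}
#' }
#'
#' @param config Path to a YAML config file, or an equivalent nested list.
#' @return Invisible list with the computed objects (`recording`, `mask`,
#'   `corr`, metric tables, ...) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- config
  if (is.null(cfg$out)) stop("config needs an 'out' directory")
  if (is.null(cfg$input)) stop("config needs an 'input' section")
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L
  fps_in <- if (!is.null(cfg$fps)) cfg$fps else 20

  sg <- do.call(seg_params, cfg$segmentation %||% list())
  mc <- do.call(metric_config, cfg$metrics %||% list())
  corr_method <- cfg$correlation$method %||% "active"
  corr_lag <- cfg$correlation$lag %||% 0L
  corr_threshold <- cfg$correlation$threshold %||% 0.3
  dist_on <- isTRUE(cfg$distance$enabled)
  shuf_on <- isTRUE(cfg$shuffle$enabled)

  rec <- load_input(cfg$input, fps_in, seed)
  if (dist_on && is.null(rec$positions))
    stop("distance analysis requires positions, but the input has none")

  mask <- segment_recording(rec, sg)
  br <- burst_rate(mask)
  nsr <- network_spike_rate(mask, mc)
  nsp <- network_spike_peak(mask, mc)
  nsd <- network_spike_duration(mask, mc)
  corr <- suppressWarnings(
    pearson_matrix(rec, mask, method = corr_method, lag = corr_lag))
  nd <- network_degree(corr)
  conn <- connectivity(corr, corr_threshold)
  clus <- correlation_clusters(corr)
  cs <- correlation_summary(corr)

  tables <- list(
    intervals = interval_table(mask),
    burst_rate = br,
    nsr = nsr,
    nsp = nsp,
    summary = data.frame(
      metric = c("nsd_pct", "mean_corr", "corr_range", "n_units",
                 "n_frames", "fps"),
      value = c(nsd, cs$mean, cs$range, n_units(rec), n_frames(rec),
                fps(rec))),
    correlation = corr_as_table(corr),
    degree = nd,
    connectivity = conn,
    clusters = clus)

  result <- list(recording = rec, mask = mask, corr = corr,
                 burst_rate = br, nsr = nsr, nsp = nsp, nsd = nsd,
                 degree = nd, connectivity = conn, clusters = clus)

  if (dist_on) {
    dk <- cfg$distance$kind %||% "euclidean"
    dep <- correlation_vs_distance(rec, mask, corr, kind = dk,
                                   weighted = isTRUE(cfg$distance$weighted))
    tables$rho <- dep$per_unit
    tables$pair_distances <- dep$pairs
    tables$dependence_summary <- data.frame(
      metric = c("fluorescence_vs_rho_r", "active_ratio_vs_rho_r",
                 "corr_vs_distance_r", "d0_px"),
      value = c(dep$fluorescence_r, dep$active_ratio_r,
                dep$corr_distance_r, dep$d0))
    result$distance <- dep
  }

  if (shuf_on) {
    scfg <- shuffle_config(ratio = cfg$shuffle$ratio %||% 1,
                           num_of_shuffles = cfg$shuffle$num_of_shuffles %||% 10L,
                           seed = seed + 1000L)
    method <- if (corr_method %in% c("active", "full", "active_acc"))
      corr_method else "active"
    surr <- shuffle_network(mask, scfg)
    cmp <- compare_metrics(mask, surr, method = method, cfg = mc)
    tables$shuffle <- cmp
    tables$shuffle_summary <- attr(cmp, "summary")
    result$shuffle <- cmp
  }

  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  files <- write_report(tables, file.path(cfg$out, "report.xlsx"))

  if (isTRUE(cfg$plots)) {
    png_path <- file.path(cfg$out, "raster.png")
    grDevices::png(png_path, width = 900, height = 600)
    plot_raster(mask); grDevices::dev.off()
    files <- c(files, png_path)
    if (!is.null(rec$positions)) {
      cp <- file.path(cfg$out, "correlation_map.png")
      grDevices::png(cp, width = 700, height = 700)
      plot_correlation_map(corr, rec$positions, corr_threshold)
      grDevices::dev.off()
      files <- c(files, cp)
    }
  }

  manifest <- list(config = config, seed = seed,
                   package = list(name = "miniact",
                                  version = as.character(
                                    utils::packageVersion("miniact"))))
  yaml::write_yaml(manifest, file.path(cfg$out, "manifest.yaml"))
  result$files <- c(files, file.path(cfg$out, "manifest.yaml"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_input <- function(input, fps, seed) {
  if (!is.null(input$synthetic)) {
    args <- input$synthetic
    if (is.null(args$seed)) args$seed <- seed
    return(generate_recording(do.call(synth_config, args))$recording)
  }
  if (!is.null(input$store))
    return(read_labeled_store(input$store,
                              trace_var = input$trace_var %||% "C",
                              footprint_var = input$footprint_var %||% "A",
                              fps = fps))
  if (!is.null(input$traces_csv))
    return(read_table(input$traces_csv, input$positions_csv, fps))
  stop("input must provide 'store', 'traces_csv' or 'synthetic'")
}

corr_as_table <- function(corr) {
  ids <- attr(corr, "unit_ids")
  df <- as.data.frame(unclass(corr)[, , drop = FALSE])
  names(df) <- paste0("u", ids)
  cbind(data.frame(unit_id = ids), df)
}

#' Embed several recordings in the PCA metric plane
#'
#' Convenience wrapper: computes the standard feature vector
#' ([recording_features()]) for each recording/mask pair, assembles the
#' feature matrix and embeds it with [pca_embed()].
#'
#' @param recs Named list of [recording()] objects.
#' @param params A [seg_params()] used for all recordings.
#' @param cfg A [metric_config()].
#' @param ... Passed to [recording_features()].
#' @return List with `features` (the [assemble_features()] object) and
#'   `embedding` (the [pca_embed()] result).
#' @export
embed_recordings <- function(recs, params = seg_params(),
                             cfg = metric_config(), ...) {
  stopifnot(length(recs) >= 2L)
  feats <- lapply(recs, function(r)
    recording_features(r, segment_recording(r, params), cfg, ...))
  fm <- assemble_features(feats)
  list(features = fm, embedding = pca_embed(fm))
}
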