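#' Pipeline configuration
#'
#' A flat key set covering every stage, with defaults equal to the published
#' analysis parameters: trim 1.5-20 kDa, SNR 6, peak half-window 7, binning
#' tolerance 0.001, minimum frequency 0.05, pattern frequency 0.8, Ward-2D on
#' Euclidean distances with 10,000 bootstrap replicates per scale, NMDS on
#' Bray-Curtis with k = 2, 999 permutations. Round-trips through YAML
#' without loss.
#'
#' @param input_dir directory of ASCII spectra with `manifest.csv`.
#' @param out_dir output directory.
#' @param seed pipeline-level seed; per-stage seeds are derived from it.
#' @param ... overrides for any configuration key.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL, seed = 1L, ...) {
  cfg <- list(
    input_dir = input_dir, out_dir = out_dir, seed = as.integer(seed),
    # preprocessing
    sqrt_transform = TRUE, sg_half_window = 10L, sg_polyorder = 3L,
    snip_iterations = 100L, snip_decreasing = TRUE, tic_target = 1,
    trim_low = 1500, trim_high = 20000,
    # peaks and features
    snr_threshold = 6, peak_half_window = 7L, bin_tolerance_rel = 0.001,
    min_frequency = 0.05, pattern_min_frequency = 0.8,
    # clustering support
    mb_scale_min = 0.5, mb_scale_max = 1.4, mb_scale_step = 0.1,
    mb_replicates = 10000L, mb_resample = "features",
    # ordination and tests
    nmds_k = 2L, nmds_restarts = 10L, nmds_distance = "bray",
    dda_on_hellinger = TRUE, n_perm = 999L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop_msg("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return for the reader, a `pipeline_config`; the writer returns `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

proc_params_of <- function(cfg) {
  processing_params(
    sqrt_transform = cfg$sqrt_transform, sg_half_window = cfg$sg_half_window,
    sg_polyorder = cfg$sg_polyorder, snip_iterations = cfg$snip_iterations,
    snip_decreasing = cfg$snip_decreasing, tic_target = cfg$tic_target,
    trim_range = c(cfg$trim_low, cfg$trim_high),
    snr_threshold = cfg$snr_threshold, peak_half_window = cfg$peak_half_window,
    bin_tolerance_rel = cfg$bin_tolerance_rel, min_frequency = cfg$min_frequency,
    pattern_min_frequency = cfg$pattern_min_frequency)
}

#' Run the full discrimination pipeline
#'
#' Fixed stage order: read -> preprocess (trim, sqrt, smooth, SNIP, TIC) ->
#' peak detection -> binning -> frequency filter -> Hellinger -> Ward
#' clustering with AU/BP -> DDA feature ranking -> NMDS -> dispersion
#' homogeneity -> PERMANOVA -> peak patterns. Every output file carries a
#' provenance header (config hash, seed); the log records per-stage counts.
#' With a single species label the statistical stages are refused with an
#' error, but the preprocessing outputs are still written.
#'
#' @param config a [pipeline_config()] (needs `input_dir` unless `spectra`
#'   is given).
#' @param spectra optional list of [raw_spectrum()] objects, bypassing
#'   `input_dir`.
#' @return invisible list: `feature_matrix` (Hellinger), `dendrogram`,
#'   `ranking`, `ordination`, `dispersion`, `permanova`, `patterns`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), spectra = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_msg("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  provenance <- function() {
    tmp <- tempfile(fileext = ".yml")
    hashed <- config
    hashed$input_dir <- hashed$out_dir <- NULL  # hash parameters, not paths
    write_pipeline_config(hashed, tmp)
    hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    c(sprintf("config_md5: %s", hash), sprintf("seed: %d", config$seed),
      sprintf("spectrotype: %s", as.character(utils::packageVersion("spectrotype"))))
  }
  prov <- provenance()

  if (is.null(spectra)) {
    if (is.null(config$input_dir)) stop_msg("config needs input_dir (or pass spectra)")
    spectra <- stage("read", read_spectra(config$input_dir))
  }
  note("read %d spectra", length(spectra))
  params <- proc_params_of(config)

  pre <- stage("preprocess", lapply(spectra, preprocess_spectrum, params = params))
  peaks <- stage("peaks", lapply(pre, detect_peaks,
                                 snr_threshold = params$snr_threshold,
                                 half_window = params$peak_half_window))
  note("detected peaks per spectrum: median %d",
       as.integer(median(vapply(peaks, function(p) length(p$masses), 0L))))
  binned <- stage("binning", bin_peaks(peaks, params$bin_tolerance_rel))
  note("%d bins before frequency filter", length(binned$bin_masses))
  fm <- stage("features", build_feature_matrix(binned, params$min_frequency))
  note("feature matrix %d x %d (dropped %d low-frequency columns)",
       nrow(fm), ncol(fm), length(binned$bin_masses) - ncol(fm))
  hm <- stage("hellinger", hellinger(fm))
  if (!is.null(out))
    write_feature_matrix(hm, file.path(out, "feature_matrix.csv"), comment = prov)

  labels <- attr(hm, "species")
  if (length(unique(labels[!is.na(labels)])) < 2L) {
    stop_msg(paste0("statistics stages refused: need >= 2 species labels ",
                    "(preprocessing outputs%s written)"),
             if (is.null(out)) " not" else "")
  }

  mbp <- mb_params(scales = seq(config$mb_scale_min, config$mb_scale_max,
                                by = config$mb_scale_step),
                   replicates = config$mb_replicates,
                   seed = derive_seed(config$seed, "bootstrap"),
                   resample = config$mb_resample)
  dend <- stage("cluster", au_bp(hm, mbp))
  note("dendrogram: %d edges, min AU %.1f", length(dend$au), min(dend$au))
  dda_m <- if (isTRUE(config$dda_on_hellinger)) hm else fm
  ranking <- stage("dda", dda_rank(dda_m, labels))
  d_ord <- stage("distance", if (config$nmds_distance == "bray") bray_curtis(hm)
                 else euclidean_distances(hm))
  ordn <- stage("nmds", nmds(d_ord, k = config$nmds_k,
                             n_restarts = config$nmds_restarts,
                             seed = derive_seed(config$seed, "nmds")))
  note("NMDS stress-1 = %.4f", ordn$stress)
  disp <- stage("dispersion", dispersion_homogeneity(d_ord, labels))
  perm <- stage("permanova", permanova(d_ord, labels, n_perm = config$n_perm,
                                       seed = derive_seed(config$seed, "permanova")))
  note("dispersion F = %.3f (p = %.4g); PERMANOVA F = %.3f (p = %.4g)",
       disp$statistic, disp$p_value, perm$statistic, perm$p_value)
  pat <- stage("patterns", peak_patterns(hm, params$pattern_min_frequency, labels))

  if (!is.null(out)) {
    write_newick(dend, file.path(out, "dendrogram.nwk"))
    rk <- data.frame(feature = colnames(ranking$scores),
                     t(ranking$scores)[, , drop = FALSE],
                     rank_stat = ranking$rank_stat,
                     rank = match(seq_along(ranking$rank_stat), ranking$order),
                     check.names = FALSE)
    writeLines(c(paste0("# ", prov),
                 paste(colnames(rk), collapse = ",")),
               file.path(out, "feature_ranking.csv"))
    write.table(rk, file.path(out, "feature_ranking.csv"), sep = ",",
                row.names = FALSE, col.names = FALSE, append = TRUE, quote = FALSE)
    ocsv <- data.frame(id = rownames(ordn$points), label = labels,
                       ordn$points, check.names = FALSE)
    writeLines(c(paste0("# ", prov), sprintf("# stress: %.6f", ordn$stress),
                 paste(c("id", "label", sprintf("axis%d", seq_len(ncol(ordn$points)))),
                       collapse = ",")),
               file.path(out, "nmds.csv"))
    write.table(ocsv, file.path(out, "nmds.csv"), sep = ",", row.names = FALSE,
                col.names = FALSE, append = TRUE, quote = FALSE)
    pat_df <- data.frame(species = rownames(pat), pat, check.names = FALSE)
    write.csv(pat_df, file.path(out, "peak_patterns.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(dispersion = list(F = disp$statistic, p = disp$p_value),
           permanova = list(F = perm$statistic, p = perm$p_value,
                            n_permutations = perm$n_permutations),
           nmds = list(stress = ordn$stress, k = config$nmds_k,
                       converged = ordn$converged),
           counts = list(spectra = nrow(hm), features = ncol(hm)),
           provenance = as.list(setNames(sub(".*: ", "", prov),
                                         sub(":.*", "", prov)))),
      file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out, "pipeline.log"))
  }
  invisible(list(feature_matrix = hm, dendrogram = dend, ranking = ranking,
                 ordination = ordn, dispersion = disp, permanova = perm,
                 patterns = pat, log = log_lines))
}
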