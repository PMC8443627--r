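#' Configuration of a full pipeline run
#'
#' @param sim A [sim_config()] used when no input tables are given.
#' @param taxon_table,metadata Optional paths to input TSVs; when supplied
#'   the dataset is loaded instead of simulated.
#' @param presence_threshold Presence threshold for loaded counts.
#' @param methods STR construction methods to run.
#' @param unit Span unit for the STR fits (`"censuses"` or `"days"`).
#' @param include_span1 Include single-census points in the STR fits.
#' @param n_rand Raup-Crick randomizations (default 1000).
#' @param null_weighting Raup-Crick null weighting.
#' @param seed Top-level seed; per-stage streams are derived from it
#'   (simulation uses `seed`, island-level Raup-Crick streams use
#'   `seed + 10000 + island index`) and recorded in the run summary.
#' @param out_dir Optional output directory for the TSV bundle.
#' @param verbose Log stage progress to standard error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), taxon_table = NULL,
                       metadata = NULL, presence_threshold = 1L,
                       methods = c("MW", "CMW", "EPW"),
                       unit = c("censuses", "days"), include_span1 = TRUE,
                       n_rand = 1000L,
                       null_weighting = c("occurrence", "equiprobable"),
                       seed = 1L, out_dir = NULL, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!length(methods)) stop("select at least one STR method")
  structure(list(sim = sim, taxon_table = taxon_table, metadata = metadata,
                 presence_threshold = presence_threshold,
                 methods = methods, unit = match.arg(unit),
                 include_span1 = include_span1, n_rand = as.integer(n_rand),
                 null_weighting = match.arg(null_weighting),
                 seed = as.integer(seed), out_dir = out_dir,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

stage_log <- function(cfg, ...) {
  if (cfg$verbose) message("[islandSTR] ", ...)
  invisible(NULL)
}

reg_row <- function(r, ...) {
  data.frame(..., slope = r$slope, intercept = r$intercept,
             R2 = r$r_squared, F = r$f_statistic, df1 = r$df_num,
             df2 = r$df_den, p = r$p_value, n = r$n)
}

fit_row <- function(f) {
  data.frame(island_id = f$island_id, method = f$method,
             c = f$coefficient_c, exponent = f$exponent, R2 = f$r_squared,
             F = f$f_statistic, df1 = f$df_num, df2 = f$df_den,
             p = f$p_value, n_points = f$n_points)
}

#' Run the full analysis pipeline
#'
#' Simulates or loads the archipelago, builds the selected STR curves,
#' fits per-island power laws, compares exponents across methods (one-way
#' ANOVA and cross-method regressions), fits the species-area and
#' species-volume relationships, regresses turnover on island volume and
#' on series duration (and on mean sequencing depth when counts are
#' available), computes within-island Raup-Crick similarities, classifies
#' census pairs into ecological processes, and regresses process
#' frequencies on volume. When `config$out_dir` is set, all tables plus a
#' `run_summary.json` are written; identical configs and seeds give
#' byte-identical bundles.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `result_bundle` with the dataset and
#'   all result tables.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config

  stage_log(cfg, "stage=dataset seed=", cfg$seed)
  dataset <- if (!is.null(cfg$taxon_table)) {
    read_archipelago(cfg$taxon_table, cfg$metadata, cfg$presence_threshold)
  } else {
    generate_archipelago(cfg$sim, seed = cfg$seed)
  }
  isl_ids <- names(dataset$islands)

  stage_log(cfg, "stage=str methods=", paste(cfg$methods, collapse = ","))
  curves <- build_str(dataset, methods = cfg$methods)
  str_curves <- str_table(curves)

  stage_log(cfg, "stage=fit unit=", cfg$unit)
  fits <- list()
  for (isl in isl_ids)
    for (m in cfg$methods)
      fits[[paste(isl, m)]] <- fit_power_law(
        curves[[isl]][[m]], unit = cfg$unit,
        include_span1 = cfg$include_span1)
  str_fits <- do.call(rbind, lapply(fits, fit_row))
  rownames(str_fits) <- NULL
  w_of <- function(m)
    stats::setNames(str_fits$exponent[str_fits$method == m],
                    str_fits$island_id[str_fits$method == m])[isl_ids]

  method_comparisons <- NULL
  method_regressions <- NULL
  if (length(cfg$methods) > 1L) {
    prs <- utils::combn(cfg$methods, 2L, simplify = FALSE)
    method_comparisons <- do.call(rbind, lapply(prs, function(pr) {
      cmpr <- compare_exponent_sets(w_of(pr[1L]), w_of(pr[2L]), labels = pr)
      data.frame(method_a = pr[1L], method_b = pr[2L],
                 mean_a = cmpr$means[1L], sd_a = cmpr$sds[1L],
                 mean_b = cmpr$means[2L], sd_b = cmpr$sds[2L],
                 F = cmpr$f_statistic, df1 = cmpr$df_num,
                 df2 = cmpr$df_den, eta2 = cmpr$eta_squared,
                 p = cmpr$p_value)
    }))
    method_regressions <- do.call(rbind, lapply(prs, function(pr) {
      reg_row(regress_pairs(w_of(pr[1L]), w_of(pr[2L]), labels = pr),
              x_method = pr[1L], y_method = pr[2L])
    }))
    rownames(method_comparisons) <- rownames(method_regressions) <- NULL
  }

  stage_log(cfg, "stage=island-size")
  island_summaries <- do.call(rbind, lapply(isl_ids, function(isl)
    island_size_summary(dataset$islands[[isl]],
                        dataset$metadata[dataset$metadata$island_id == isl,
                                         , drop = FALSE])))
  size_fits <- rbind(
    cbind(predictor = "area_cm2",
          fit_row(fit_power_law(island_summaries$area_mean,
                                island_summaries$richness_mean))[, -(1:2)]),
    cbind(predictor = "volume_ml",
          fit_row(fit_power_law(island_summaries$volume_mean,
                                island_summaries$richness_mean))[, -(1:2)]))

  vols <- island_summaries$volume_mean
  w_size_regressions <- do.call(rbind, lapply(cfg$methods, function(m)
    reg_row(regress_pairs(vols, w_of(m), log_x = TRUE,
                          labels = c("log10_volume", "w")), method = m)))

  durations <- vapply(dataset$islands, function(ts) max(ts$census_days), 0)
  robustness_regressions <- do.call(rbind, lapply(cfg$methods, function(m)
    reg_row(regress_pairs(durations[isl_ids], w_of(m),
                          labels = c("duration_days", "w")),
            method = m, predictor = "duration_days")))
  depths <- vapply(dataset$islands, function(ts)
    if (is.null(ts$counts)) NA_real_ else mean(colSums(ts$counts)), 0)
  if (!anyNA(depths)) {
    robustness_regressions <- rbind(
      robustness_regressions,
      do.call(rbind, lapply(cfg$methods, function(m)
        reg_row(regress_pairs(depths[isl_ids], w_of(m),
                              labels = c("mean_depth", "w")),
                method = m, predictor = "mean_depth"))))
  }
  rownames(robustness_regressions) <- NULL

  stage_log(cfg, "stage=raup-crick n_rand=", cfg$n_rand,
            " seed_base=", cfg$seed + 10000L)
  rc <- raup_crick_archipelago(dataset, n_rand = cfg$n_rand,
                               seed = cfg$seed + 10000L,
                               null_weighting = cfg$null_weighting)
  rc_pairs <- do.call(rbind, lapply(rc, function(r)
    cbind(island_id = r$island_id, r$pairs)))
  rownames(rc_pairs) <- NULL

  stage_log(cfg, "stage=classify")
  process_freq <- do.call(rbind, lapply(rc, classify_processes))
  class(process_freq) <- "data.frame"
  rownames(process_freq) <- NULL
  process_size_regressions <- do.call(rbind, lapply(
    c(HD = "pct_HD", DL = "pct_DL", drift = "pct_drift"),
    function(col) reg_row(
      regress_pairs(vols, process_freq[[col]], log_x = TRUE,
                    labels = c("log10_volume", col)),
      process = col)))
  rownames(process_size_regressions) <- NULL

  tables <- list(str_curves = str_curves, str_fits = str_fits,
                 island_summaries = island_summaries,
                 size_fits = size_fits,
                 w_size_regressions = w_size_regressions,
                 robustness_regressions = robustness_regressions,
                 rc_pairs = rc_pairs, process_freq = process_freq,
                 process_size_regressions = process_size_regressions)
  if (!is.null(method_comparisons))
    tables <- c(tables, list(method_comparisons = method_comparisons,
                             method_regressions = method_regressions))

  bundle <- structure(c(list(dataset = dataset, config = cfg), tables),
                      class = "result_bundle")
  if (!is.null(cfg$out_dir)) {
    stage_log(cfg, "stage=write out_dir=", cfg$out_dir)
    run_info <- list(
      package = "islandSTR",
      version = as.character(utils::packageVersion("islandSTR")),
      seed = cfg$seed, rc_seed_base = cfg$seed + 10000L,
      methods = cfg$methods, unit = cfg$unit, n_rand = cfg$n_rand,
      null_weighting = cfg$null_weighting,
      simulated = is.null(cfg$taxon_table),
      sim = if (is.null(cfg$taxon_table)) unclass(cfg$sim) else NULL)
    write_results(tables, cfg$out_dir, run_info = run_info)
  }
  invisible(bundle)
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates per-method mean scaling exponents, per-island process
#' frequencies with archipelago-wide means, and the island-size regression
#' lines. Every number is recomputed from the bundle's tables.
#'
#' @param bundle A `result_bundle` from [run_all()].
#' @return The report, invisibly, as a character vector of lines (also
#'   printed).
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  need <- c("str_fits", "process_freq", "w_size_regressions")
  miss <- setdiff(need, names(bundle))
  if (length(miss)) stop("incomplete bundle, missing: ",
                         paste(miss, collapse = ", "))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("islandSTR run report")
  add("=====================")
  add("Temporal scaling exponents (w), per STR method:")
  for (m in unique(bundle$str_fits$method)) {
    w <- bundle$str_fits$exponent[bundle$str_fits$method == m]
    add("  %-3s  mean w = %.3f +/- %.3f  (range %.3f-%.3f, n = %d)",
        m, mean(w), stats::sd(w), min(w), max(w), length(w))
  }
  pf <- bundle$process_freq
  add("Ecological process frequencies (%% of census pairs):")
  add("  homogenizing dispersal  mean %.1f +/- %.1f%%",
      mean(pf$pct_HD), stats::sd(pf$pct_HD))
  add("  drift                   mean %.1f +/- %.1f%%",
      mean(pf$pct_drift), stats::sd(pf$pct_drift))
  add("  dispersal limitation    mean %.1f +/- %.1f%%",
      mean(pf$pct_DL), stats::sd(pf$pct_DL))
  for (i in seq_len(nrow(pf)))
    add("    %s: HD %.1f%%, drift %.1f%%, DL %.1f%% (%d pairs)",
        pf$island_id[i], pf$pct_HD[i], pf$pct_drift[i], pf$pct_DL[i],
        pf$n_pairs[i])
  add("Turnover vs island volume (w ~ log10 V):")
  wr <- bundle$w_size_regressions
  for (i in seq_len(nrow(wr)))
    add("  %-3s  slope = %.4g, R2 = %.2f, F(%d,%d) = %.3g, p = %.3g",
        wr$method[i], wr$slope[i], wr$R2[i], wr$df1[i], wr$df2[i],
        wr$F[i], wr$p[i])
  if (!is.null(bundle$size_fits)) {
    add("Species-size power laws:")
    sf <- bundle$size_fits
    for (i in seq_len(nrow(sf)))
      add("  S ~ %-9s  exponent z = %.3f, R2 = %.2f, p = %.3g",
          sf$predictor[i], sf$exponent[i], sf$R2[i], sf$p[i])
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
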