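#' End-to-end synthetic analysis: simulate, decompose, classify, survive
#'
#' Runs the full workflow on generated data: simulate a matched pair
#' with planted structure and linked outcomes, compute the GSVD, rank
#' components by tumor exclusivity and significance, classify segments
#' and patients against the selected pattern, test the pattern and batch
#' components against the GC and sequencer covariates, and stratify
#' survival (KM medians, log-rank, Cox with and without stage). All
#' randomness flows from `config$seed`, so a rerun with the same config
#' reproduces every output, including the summary JSON, byte for byte.
#'
#' @param config A [synthetic_config()].
#' @param theta_min,p_min Component selection thresholds
#'   (see [rank_components()]).
#' @param corr_cutoff,t_mad,min_probes Classification thresholds
#'   (see [classify_patients()] and [classify_segments()]).
#' @param min_pfs Optional PFS threshold in months; when not `NULL` the
#'   survival stage runs on [pfs_subset()] records.
#' @param platinum_only Restrict the survival stage to platinum-treated
#'   patients.
#' @param with_stage Also fit the bivariate Cox model with ordinal stage.
#' @param out_dir Optional output directory; when given, writes the
#'   component table, classifications, segment calls, KM/Cox tables and
#'   a machine-readable `summary.json` echoing every threshold used.
#' @return A list with elements `pair`, `truth`, `clinical`, `fit`,
#'   `ranking`, `classification`, `segment_calls`, `associations`,
#'   `km`, `logrank`, `cox` (+`cox_stage` when requested) and `summary`.
#' @export
run_end_to_end <- function(config = synthetic_config(),
                           theta_min = 0.2, p_min = 0.01,
                           corr_cutoff = 0.35, t_mad = 1, min_probes = 30,
                           min_pfs = NULL, platinum_only = FALSE,
                           with_stage = FALSE, out_dir = NULL) {
  sim <- generate_matched_pair(config)
  clinical <- generate_survival(sim$truth, config)

  fit <- compute_gsvd(sim$pair)
  ranking <- rank_components(fit, theta_min = theta_min, p_min = p_min)
  sel <- selected_component(ranking)
  if (!length(sel)) stop("pipeline stage `rank`: no selected component")

  pattern <- fit$U1[, sel]
  correlations <- correlate_patients(pattern, sim$pair$tumor)
  classification <- classify_patients(correlations, fit$Vt[sel, ],
                                      corr_cutoff = corr_cutoff)

  segment_calls <- classify_segments(pattern, sim$pair$tumor$bins,
                                     sim$truth$segments,
                                     t_mad = t_mad, min_probes = min_probes)

  high_idx <- which(classification$high_by_correlation)
  associations <- dplyr::bind_rows(
    dplyr::mutate(
      covariate_association(pattern, sim$pair$tumor$bins$gc),
      target = "selected_pattern", covariate = "gc", .before = 1),
    dplyr::mutate(
      covariate_association(fit$Vt[sel, ], sim$truth$batch_tumor, high_idx),
      target = "selected_coefficients", covariate = "tumor_batch", .before = 1)
  )

  records <- clinical
  if (platinum_only) records <- dplyr::filter(records, .data$platinum)
  if (!is.null(min_pfs)) records <- pfs_subset(records, min_pfs)
  grp <- ifelse(classification$high_by_correlation, "high", "low")
  names(grp) <- classification$patient
  records <- records[records$patient_id %in% names(grp), , drop = FALSE]

  # a null-ish classification can leave one group empty: survival
  # outputs are then reported as missing rather than failing the run
  two_groups <- length(unique(grp[records$patient_id])) == 2
  km <- km_curves(records, grp)
  lr <- if (two_groups) logrank(records, grp) else
    tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                   n1 = nrow(records), n2 = 0L,
                   events = as.integer(sum(records$os_event)))
  cox <- if (two_groups) cox_fit(records, grp[records$patient_id] == "high") else NULL
  cox_stage <- if (with_stage && two_groups) {
    cox_fit(records, grp[records$patient_id] == "high", with_stage = TRUE)
  } else NULL

  med <- km_medians(km)
  summary <- list(
    thresholds = list(theta_min = theta_min, p_min = p_min,
                      corr_cutoff = corr_cutoff,
                      coeff_cutoff = attr(classification, "coeff_cutoff"),
                      t_mad = t_mad, min_probes = min_probes,
                      min_pfs = min_pfs, platinum_only = platinum_only,
                      seed = config$seed),
    selected_component = sel,
    selected_theta = fit$theta[sel],
    n_high_by_correlation = sum(classification$high_by_correlation),
    n_high_by_coefficient = sum(classification$high_by_coefficient),
    high_set_overlap = attr(classification, "overlap"),
    km_median_high = if ("high" %in% med$group)
      med$median_months[med$group == "high"] else NA_real_,
    km_median_low = if ("low" %in% med$group)
      med$median_months[med$group == "low"] else NA_real_,
    logrank_p = lr$p_value,
    hazard_ratio = if (is.null(cox)) NA_real_ else tidy(cox)$hazard_ratio[1],
    concordance = if (is.null(cox)) NA_real_ else glance(cox)$concordance
  )

  out <- list(pair = sim$pair, truth = sim$truth, clinical = clinical,
              fit = fit, ranking = ranking, classification = classification,
              segment_calls = segment_calls, associations = associations,
              km = km, logrank = lr, cox = cox, cox_stage = cox_stage,
              summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tidy(fit), file.path(out_dir, "components.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(classification),
                     file.path(out_dir, "classification.tsv"), progress = FALSE)
    readr::write_tsv(segment_calls, file.path(out_dir, "segment_calls.tsv"),
                     progress = FALSE)
    readr::write_tsv(tibble::as_tibble(km), file.path(out_dir, "km.tsv"),
                     progress = FALSE)
    readr::write_tsv(tidy(cox), file.path(out_dir, "cox.tsv"), progress = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(out)
}

#' Read a run configuration from YAML
#'
#' Thin wrapper mapping a YAML file onto [synthetic_config()] fields
#' plus the pipeline thresholds, for the command-line entry point.
#'
#' @param path Path to a YAML file; keys under `simulate:` go to
#'   [synthetic_config()], keys under `thresholds:` to
#'   [run_end_to_end()].
#' @return A list with `config` and `thresholds`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulate %||% list()
  if (!is.null(sim_args$pattern_blocks)) {
    sim_args$pattern_blocks <- dplyr::bind_rows(sim_args$pattern_blocks)
  }
  cfg <- do.call(synthetic_config, sim_args)
  thr <- y$thresholds %||% list()
  ok <- c("theta_min", "p_min", "corr_cutoff", "t_mad", "min_probes",
          "min_pfs", "platinum_only", "with_stage")
  bad <- setdiff(names(thr), ok)
  if (length(bad)) stop("unknown threshold key(s): ", paste(bad, collapse = ", "))
  list(config = cfg, thresholds = thr)
}
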