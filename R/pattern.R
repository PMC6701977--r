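#' Rank GSVD components by tumor exclusivity and significance
#'
#' A component is *exclusive* to the tumor dataset when its angular
#' distance `theta_a` is at least `theta_min` (near `+pi/4` means the
#' normal-dataset coefficient is negligible), and *significant* in a
#' dataset when its fraction of that dataset's total squared
#' generalized singular value, `P_{i,a} = sigma_{i,a}^2 / sum_b
#' sigma_{i,b}^2`, is at least `p_min`. The selected component is the
#' most exclusive (max `theta`) among those significant in the tumor
#' dataset — the candidate tumor-exclusive alteration pattern.
#' Components in a degenerate ratio group share their flags, since the
#' decomposition is unique only up to rotation there.
#'
#' @param fit A `gsvd_fit`, or a `tensor_gsvd_fit` (its row-mode GSVD is
#'   ranked).
#' @param theta_min Exclusivity threshold in radians (default 0.2).
#' @param p_min Significance threshold on the squared-value fraction
#'   (default 0.01).
#' @return A `component_ranking`: a tibble with one row per component
#'   (`component`, `theta`, `ratio`, `significance1`, `significance2`,
#'   `exclusive_to_1`, `exclusive_to_2`, `significant_in_1`,
#'   `significant_in_2`, `selected`) carrying the thresholds and the
#'   selected index as attributes.
#' @export
rank_components <- function(fit, theta_min = 0.2, p_min = 0.01) {
  if (inherits(fit, "tensor_gsvd_fit")) fit <- fit$row_mode
  stopifnot(inherits(fit, "gsvd_fit"))
  df <- tidy(fit)
  df$exclusive_to_1 <- df$theta >= theta_min
  df$exclusive_to_2 <- df$theta <= -theta_min
  df$significant_in_1 <- df$significance1 >= p_min
  df$significant_in_2 <- df$significance2 >= p_min
  # degenerate groups share flags: any member qualifying flags the group
  for (g in fit$degenerate_groups) {
    for (fl in c("exclusive_to_1", "exclusive_to_2",
                 "significant_in_1", "significant_in_2")) {
      df[[fl]][g] <- any(df[[fl]][g])
    }
  }
  cand <- which(df$significant_in_1)
  if (!length(cand)) {
    warning("no component is significant in the tumor dataset at p_min = ", p_min)
    selected <- integer(0)
  } else {
    selected <- cand[which.max(df$theta[cand])]
  }
  df$selected <- df$component %in% selected
  structure(df,
            class = c("component_ranking", class(df)),
            selected = selected, theta_min = theta_min, p_min = p_min)
}

#' Selected component index of a ranking
#'
#' @param ranking A `component_ranking`.
#' @return The selected component index (integer, possibly empty).
#' @export
selected_component <- function(ranking) {
  attr(ranking, "selected")
}

#' Call segment genotypes against chromosome-arm medians
#'
#' Classifies each predefined segment as amplified, unaltered or deleted
#' in a copy-number pattern (a basis vector over bins), based on the
#' difference between the segment's median and its chromosome arm's
#' median, measured in units of the pattern's median absolute deviation
#' (MAD, unscaled) over all bins of the covered arms. Segments
#' represented by too few probes are kept in the output but flagged as
#' not retained.
#'
#' @param pattern Numeric vector over bins (e.g. a tumor column basis
#'   vector of the selected component).
#' @param bins The bin table the pattern is indexed by (`chrom`,
#'   `start`, `end`, optional `n_probes`).
#' @param segments Segment tibble from [read_segments()] (`chrom`,
#'   `start`, `end`, `label`, `arm`). Arm assignment of a *bin* is taken
#'   from the arm whose segments' chromosome it falls on; alternatively
#'   supply `bin_arms`.
#' @param bin_arms Optional character vector assigning every bin to an
#'   arm; when absent, bins are assigned to the arm of any segment-free
#'   region by chromosome matching against `segments`.
#' @param t_mad Call threshold in MAD units (default 1): amplified iff
#'   `delta_in_mads > t_mad`, deleted iff `< -t_mad`.
#' @param min_probes Retention filter: retained iff `n_probes > min_probes`
#'   (default 30).
#' @return A tibble with one row per segment: `label`, `arm`,
#'   `n_probes`, `segment_median`, `arm_median`, `mad`, `delta_in_mads`,
#'   `call` (factor: deleted/unaltered/amplified) and `retained`.
#' @export
classify_segments <- function(pattern, bins, segments, bin_arms = NULL,
                              t_mad = 1, min_probes = 30) {
  bins <- tibble::as_tibble(bins)
  stopifnot(length(pattern) == nrow(bins))
  if (!("n_probes" %in% names(bins))) bins$n_probes <- 1L

  if (is.null(bin_arms)) {
    chrom_arm <- unique(segments[c("chrom", "arm")])
    multi <- chrom_arm$chrom[duplicated(chrom_arm$chrom)]
    if (length(multi)) {
      stop("chromosome(s) ", paste(unique(multi), collapse = ", "),
           " map to several arms; supply `bin_arms` explicitly")
    }
    bin_arms <- chrom_arm$arm[match(bins$chrom, chrom_arm$chrom)]
  }
  stopifnot(length(bin_arms) == nrow(bins))

  covered <- !is.na(bin_arms)
  mad_all <- stats::mad(pattern[covered], constant = 1)
  arm_medians <- tapply(pattern[covered], bin_arms[covered], stats::median)

  rows <- purrr::pmap(segments, function(chrom, start, end, label, arm, ...) {
    in_seg <- bins$chrom == chrom & bins$start < end & bins$end > start
    if (!any(in_seg)) {
      stop("segment `", label, "` maps to no bins")
    }
    seg_median <- stats::median(pattern[in_seg])
    arm_median <- unname(arm_medians[[arm]])
    delta <- (seg_median - arm_median) / mad_all
    tibble::tibble(
      label = label, arm = arm,
      n_probes = sum(bins$n_probes[in_seg]),
      segment_median = seg_median, arm_median = arm_median,
      mad = mad_all, delta_in_mads = delta,
      call = if (delta > t_mad) "amplified"
             else if (delta < -t_mad) "deleted" else "unaltered"
    )
  })
  out <- dplyr::bind_rows(rows)
  out$call <- factor(out$call, levels = c("deleted", "unaltered", "amplified"))
  out$retained <- out$n_probes > min_probes
  out
}

#' Spearman correlation of each patient's tumor profile with a pattern
#'
#' Rank correlation is invariant under any strictly monotone transform
#' of the pattern; ties receive average ranks. A constant patient
#' profile has no defined rank correlation and yields `NA`.
#'
#' @param pattern Numeric vector over the tumor bins.
#' @param tumor A `profile_matrix` (or plain matrix) of tumor profiles.
#' @return A named numeric vector, one Spearman correlation per patient.
#' @export
correlate_patients <- function(pattern, tumor) {
  vals <- if (inherits(tumor, "profile_matrix")) tumor$values else as.matrix(tumor)
  stopifnot(length(pattern) == nrow(vals))
  out <- suppressWarnings(
    stats::cor(pattern, vals, method = "spearman")[1, ]
  )
  names(out) <- colnames(vals)
  out
}

#' Classify patients by pattern correlation and coefficient
#'
#' A patient carries the pattern phenotype when the Spearman correlation
#' of their tumor profile with the pattern exceeds `corr_cutoff`
#' (default 0.35), or when their superposition coefficient (entry of the
#' selected component's row basis vector) exceeds the coefficient
#' cutoff obtained by scaling `corr_cutoff` by the Euclidean (Frobenius)
#' norm of the correlation vector. Because the row basis vector has
#' unit norm while the correlation vector does not, the default scaling
#' divides by that norm (`scaling = "divide"`); `"multiply"` is
#' available as the alternative reading.
#'
#' @param correlations Length-`L` vector from [correlate_patients()].
#' @param coefficients Length-`L` vector of superposition coefficients
#'   (selected row of `Vt`).
#' @param corr_cutoff Correlation cutoff (default 0.35).
#' @param scaling `"divide"` (default) or `"multiply"`.
#' @return A `pattern_classification` tibble with per-patient
#'   `coefficient`, `correlation`, `high_by_coefficient`,
#'   `high_by_correlation`; attributes `corr_cutoff`, `coeff_cutoff` and
#'   `overlap` (shared high calls as a fraction of the smaller high set).
#' @export
classify_patients <- function(correlations, coefficients, corr_cutoff = 0.35,
                              scaling = c("divide", "multiply")) {
  scaling <- match.arg(scaling)
  stopifnot(length(correlations) == length(coefficients))
  if (all(is.na(correlations))) {
    stop("all correlations are missing; cannot classify")
  }
  frob <- sqrt(sum(correlations^2, na.rm = TRUE))
  coeff_cutoff <- if (scaling == "divide") corr_cutoff / frob else corr_cutoff * frob

  high_corr <- !is.na(correlations) & correlations > corr_cutoff
  high_coef <- coefficients > coeff_cutoff
  n_shared <- sum(high_corr & high_coef)
  smaller <- min(sum(high_corr), sum(high_coef))
  overlap <- if (smaller > 0) n_shared / smaller else NA_real_

  ids <- names(correlations)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(correlations))
  out <- tibble::tibble(
    patient = ids,
    coefficient = unname(coefficients),
    correlation = unname(correlations),
    high_by_coefficient = unname(high_coef),
    high_by_correlation = unname(high_corr)
  )
  structure(out,
            class = c("pattern_classification", class(out)),
            corr_cutoff = corr_cutoff, coeff_cutoff = coeff_cutoff,
            scaling = scaling, overlap = overlap)
}

#' Associate a basis vector with an experimental covariate
#'
#' Used to attribute components to experimental rather than biological
#' sources (e.g. GC-content artifacts of PCR-amplified sequencing, or
#' sequencer batch effects). For a numeric covariate, Pearson and
#' Spearman correlations are reported, plus a two-sided
#' Mann-Whitney-Wilcoxon (MWW) test of the covariate between the high
#' and low patient sets when `high_set` is given. For a two-level
#' categorical covariate, the MWW test compares the basis-vector entries
#' between the two groups, and when `high_set` is given a hypergeometric
#' upper-tail P-value tests over-enrichment of each category in the
#' high set.
#'
#' The MWW test uses the exact null distribution when both groups have
#' at most 25 observations and there are no ties, and the
#' normal approximation with tie correction otherwise.
#'
#' @param vector Basis vector (one entry per patient or per bin).
#' @param covariate Numeric vector, or factor/character labels, same
#'   length as `vector`.
#' @param high_set Optional integer/logical index of "high" entries.
#' @return A one-row tibble (numeric covariate) or one row per category
#'   (categorical): correlations and/or `mww_p`, `hypergeom_p`.
#' @export
covariate_association <- function(vector, covariate, high_set = NULL) {
  stopifnot(length(vector) == length(covariate))
  n <- length(vector)
  if (is.logical(high_set)) high_set <- which(high_set)

  if (is.numeric(covariate)) {
    mww <- NA_real_
    if (!is.null(high_set) && length(high_set) >= 1 && length(high_set) < n) {
      mww <- mww_p(covariate[high_set], covariate[-high_set])
    }
    return(tibble::tibble(
      covariate_type = "numeric",
      pearson = stats::cor(vector, covariate, use = "complete.obs"),
      spearman = stats::cor(vector, covariate, method = "spearman",
                            use = "complete.obs"),
      mww_p = mww
    ))
  }

  covariate <- as.factor(covariate)
  levs <- levels(covariate)
  rows <- lapply(levs, function(lv) {
    in_grp <- covariate == lv
    mww <- if (sum(in_grp) >= 1 && sum(!in_grp) >= 1) {
      mww_p(vector[in_grp], vector[!in_grp])
    } else NA_real_
    hyp <- NA_real_
    if (!is.null(high_set) && length(high_set) >= 1) {
      k_overlap <- sum(high_set %in% which(in_grp))
      # upper tail: that many or more category members in the high set
      hyp <- stats::phyper(k_overlap - 1, sum(in_grp), n - sum(in_grp),
                           length(high_set), lower.tail = FALSE)
    }
    tibble::tibble(covariate_type = "categorical", category = lv,
                   n_category = sum(in_grp), mww_p = mww, hypergeom_p = hyp)
  })
  dplyr::bind_rows(rows)
}

# two-sided MWW P: exact when both groups <= 25 and tie-free, else
# normal approximation with tie correction and continuity correction
mww_p <- function(x, y) {
  exact <- length(x) <= 25 && length(y) <= 25 && !any(duplicated(c(x, y)))
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}
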