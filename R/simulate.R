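#' Configuration for the synthetic matched-profile generator
#'
#' The generator emulates the structure of patient-matched tumor and
#' normal relative copy-number datasets at desk scale: a planted
#' tumor-exclusive alteration pattern (a contiguous loss over 45% of the
#' bins plus a gain over 25%, the analog of a chromosome-arm loss
#' combined with an arm gain) carried by a subset of patients; shared
#' germline-like variation present in both datasets with common patient
#' loadings; a GC-content artifact (per-bin spikes proportional to the
#' centered GC fraction, with a near-constant patient loading) placed in
#' *both* datasets; dataset-exclusive sequencer batch offsets (each
#' dataset's patients are assigned to sequencers independently of the
#' other's); and i.i.d. Gaussian measurement noise. Survival follows an
#' exponential proportional-hazards model in which carrying the pattern
#' multiplies the baseline hazard.
#'
#' @param K1,K2 Numbers of tumor and normal bins (default 600 each).
#' @param L Number of patients (default 100).
#' @param M Number of platforms for tensor generation (default 2).
#' @param carrier_fraction Fraction of patients carrying the planted
#'   pattern (default 0.2).
#' @param pattern_amplitude Copy-number amplitude of the planted blocks
#'   (default 1).
#' @param pattern_blocks Data frame (`start_frac`, `end_frac`, `sign`)
#'   defining the planted blocks as bin fractions; default one loss over
#'   \[0, 0.45) and one gain over \[0.55, 0.80).
#' @param shared_rank,shared_amplitude Number and per-bin scale of shared
#'   variation components (defaults 3 and 0.5).
#' @param gc_amplitude Scale of the GC artifact (default 0.5; 0 disables).
#' @param batch_amplitude Per-bin scale of the sequencer offsets
#'   (default 0.5, half the planted pattern amplitude: a sequencer
#'   offset is smaller than a one-copy change; 0 disables).
#' @param platform_gains Optional length-`M` platform gain vector for
#'   tensor generation; default evenly spaced in \[0.95, 1.05\].
#' @param noise_sd Gaussian noise standard deviation (default 0.25).
#' @param baseline_hazard Baseline event rate per month (default
#'   `log(2)/36`, a 36-month median for non-carriers).
#' @param hazard_ratio True carrier hazard ratio (default 3).
#' @param censoring_rate Expected fraction of censored records under the
#'   baseline hazard (default 0.3; 0 disables censoring).
#' @param seed Integer seed; all randomness in the generators flows from
#'   it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(K1 = 600, K2 = 600, L = 100, M = 2,
                             carrier_fraction = 0.2, pattern_amplitude = 1,
                             pattern_blocks = NULL,
                             shared_rank = 3, shared_amplitude = 0.5,
                             gc_amplitude = 0.5, batch_amplitude = 0.5,
                             platform_gains = NULL, noise_sd = 0.25,
                             baseline_hazard = log(2) / 36, hazard_ratio = 3,
                             censoring_rate = 0.3, seed = 1L) {
  if (is.null(pattern_blocks)) {
    pattern_blocks <- tibble::tibble(
      start_frac = c(0, 0.55), end_frac = c(0.45, 0.80), sign = c(-1, 1)
    )
  }
  stopifnot(carrier_fraction >= 0, carrier_fraction < 1, noise_sd > 0,
            L * M <= K1, L * M <= K2)
  structure(
    list(K1 = K1, K2 = K2, L = L, M = M,
         carrier_fraction = carrier_fraction,
         pattern_amplitude = pattern_amplitude,
         pattern_blocks = tibble::as_tibble(pattern_blocks),
         shared_rank = shared_rank, shared_amplitude = shared_amplitude,
         gc_amplitude = gc_amplitude, batch_amplitude = batch_amplitude,
         platform_gains = platform_gains, noise_sd = noise_sd,
         baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# run code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic planted pattern over K bins (no randomness: the planted
# structure is fixed by the config, only noise/assignments vary by seed)
planted_pattern <- function(config, K) {
  p <- numeric(K)
  for (i in seq_len(nrow(config$pattern_blocks))) {
    b <- config$pattern_blocks[i, ]
    lo <- floor(b$start_frac * K) + 1
    hi <- floor(b$end_frac * K)
    p[lo:hi] <- b$sign * config$pattern_amplitude
  }
  p
}

# segment/arm table describing the planted blocks, in bin coordinates
planted_segments <- function(config, K) {
  blocks <- config$pattern_blocks
  tibble::tibble(
    chrom = "bin",
    start = floor(blocks$start_frac * K),
    end = floor(blocks$end_frac * K),
    label = sprintf("block%d", seq_len(nrow(blocks))),
    arm = "binp"
  )
}

#' Generate a synthetic matched tumor/normal pair with ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `pair` (a `matched_pair` whose bin
#'   tables carry the simulated GC fractions) and `truth` (planted
#'   pattern vector, carrier indicator, GC covariates, batch labels,
#'   planted-segment table and the config).
#' @export
generate_matched_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    parts <- simulate_parts(config)
    tumor_mat <- parts$signal1 + matrix(stats::rnorm(config$K1 * config$L,
                                                     sd = config$noise_sd),
                                        config$K1)
    normal_mat <- parts$signal2 + matrix(stats::rnorm(config$K2 * config$L,
                                                      sd = config$noise_sd),
                                         config$K2)
    build_pair_output(config, parts, tumor_mat, normal_mat)
  })
}

# planted signal (everything except noise) shared by the matrix and
# tensor generators; drawn under the caller-controlled seed
simulate_parts <- function(config) {
  K1 <- config$K1; K2 <- config$K2; L <- config$L
  n_carrier <- round(config$carrier_fraction * L)
  carrier <- rep(FALSE, L)
  if (n_carrier > 0) carrier[sample.int(L, n_carrier)] <- TRUE

  pattern1 <- planted_pattern(config, K1)
  gc1 <- stats::runif(K1, 0.3, 0.7)
  gc2 <- stats::runif(K2, 0.3, 0.7)
  gc_loading <- 1 + stats::rnorm(L, sd = 0.1)

  signal1 <- outer(pattern1, as.numeric(carrier))
  signal2 <- matrix(0, K2, L)
  if (config$gc_amplitude > 0) {
    signal1 <- signal1 + config$gc_amplitude * outer(gc1 - mean(gc1), gc_loading)
    signal2 <- signal2 + config$gc_amplitude * outer(gc2 - mean(gc2), gc_loading)
  }
  for (j in seq_len(config$shared_rank)) {
    w <- stats::rnorm(L)
    signal1 <- signal1 + outer(stats::rnorm(K1, sd = config$shared_amplitude), w)
    signal2 <- signal2 + outer(stats::rnorm(K2, sd = config$shared_amplitude), w)
  }
  batch1 <- sample(c("sequencerA", "sequencerB"), L, replace = TRUE)
  batch2 <- sample(c("sequencerA", "sequencerB"), L, replace = TRUE)
  if (config$batch_amplitude > 0) {
    z1 <- (batch1 == "sequencerB") - mean(batch1 == "sequencerB")
    z2 <- (batch2 == "sequencerB") - mean(batch2 == "sequencerB")
    signal1 <- signal1 + outer(stats::rnorm(K1, sd = config$batch_amplitude), z1)
    signal2 <- signal2 + outer(stats::rnorm(K2, sd = config$batch_amplitude), z2)
  }
  list(signal1 = signal1, signal2 = signal2, carrier = carrier,
       pattern1 = pattern1, gc1 = gc1, gc2 = gc2,
       batch_tumor = batch1, batch_normal = batch2)
}

build_pair_output <- function(config, parts, tumor_mat, normal_mat) {
  patients <- sprintf("P%03d", seq_len(config$L))
  mk_bins <- function(K, gc) {
    tibble::tibble(chrom = "bin", start = seq_len(K) - 1L, end = seq_len(K),
                   n_probes = 1L, gc = gc)
  }
  pair <- structure(
    list(
      tumor = profile_matrix(mk_bins(config$K1, parts$gc1), tumor_mat, patients),
      normal = profile_matrix(mk_bins(config$K2, parts$gc2), normal_mat, patients)
    ),
    class = "matched_pair"
  )
  truth <- list(
    pattern1 = parts$pattern1,
    carrier = stats::setNames(parts$carrier, patients),
    gc_tumor = parts$gc1, gc_normal = parts$gc2,
    batch_tumor = stats::setNames(parts$batch_tumor, patients),
    batch_normal = stats::setNames(parts$batch_normal, patients),
    segments = planted_segments(config, config$K1),
    config = config
  )
  list(pair = pair, truth = truth)
}

#' Generate a synthetic matched tensor pair over platforms
#'
#' Each platform contributes one `K x L` slice sharing the planted
#' signal, scaled by a platform gain near 1 (evenly spaced in
#' \[0.95, 1.05\]), plus platform-independent noise. With `M = 1` this
#' reduces to [generate_matched_pair()].
#'
#' @param config A [synthetic_config()] with `M >= 1`.
#' @return A list with `tpair` (a `matched_tensor_pair`) and `truth`
#'   (as in [generate_matched_pair()], plus `platform_gains`).
#' @export
generate_matched_tensor_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  M <- config$M
  with_seed(config$seed, {
    parts <- simulate_parts(config)
    gains <- config$platform_gains %||%
      (if (M == 1) 1 else seq(0.95, 1.05, length.out = M))
    stopifnot(length(gains) == M)
    D1 <- array(0, dim = c(config$K1, config$L, M))
    D2 <- array(0, dim = c(config$K2, config$L, M))
    for (m in seq_len(M)) {
      D1[, , m] <- gains[m] * parts$signal1 +
        matrix(stats::rnorm(config$K1 * config$L, sd = config$noise_sd), config$K1)
      D2[, , m] <- gains[m] * parts$signal2 +
        matrix(stats::rnorm(config$K2 * config$L, sd = config$noise_sd), config$K2)
    }
    patients <- sprintf("P%03d", seq_len(config$L))
    platforms <- sprintf("platform%d", seq_len(M))
    truth <- list(
      pattern1 = parts$pattern1,
      carrier = stats::setNames(parts$carrier, patients),
      gc_tumor = parts$gc1, gc_normal = parts$gc2,
      batch_tumor = stats::setNames(parts$batch_tumor, patients),
      batch_normal = stats::setNames(parts$batch_normal, patients),
      platform_gains = gains,
      segments = planted_segments(config, config$K1),
      config = config
    )
    list(tpair = matched_tensor_pair(D1, D2, patients, platforms), truth = truth)
  })
}

#' Generate survival records linked to carrier status
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio^carrier`; censoring times are
#' independent exponentials calibrated so the expected censored fraction
#' under the baseline hazard equals `censoring_rate` (no censoring when
#' the rate is 0). Progression-free survival is a random fraction of
#' overall survival, and stage is drawn independently of carrier status,
#' so the pattern and stage are independent predictors by construction.
#'
#' @param truth Ground truth from [generate_matched_pair()] (only the
#'   `carrier` field is used), or a logical carrier vector.
#' @param config A [synthetic_config()]; the survival fields and `seed`
#'   are used (the survival stream is offset from the profile stream).
#' @return A tibble of survival records (see [read_clinical()]).
#' @export
generate_survival <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  carrier <- if (is.list(truth)) truth$carrier else truth
  carrier <- as.logical(carrier)
  n <- length(carrier)
  ids <- names(carrier)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  with_seed(config$seed + 104729L, {
    h <- config$baseline_hazard * ifelse(carrier, config$hazard_ratio, 1)
    event_t <- stats::rexp(n, rate = h)
    if (config$censoring_rate > 0) {
      cr <- config$censoring_rate
      cens_t <- stats::rexp(n, rate = config$baseline_hazard * cr / (1 - cr))
    } else {
      cens_t <- rep(Inf, n)
    }
    os <- pmin(event_t, cens_t)
    tibble::tibble(
      patient_id = ids,
      os_months = os,
      os_event = event_t <= cens_t,
      pfs_months = os * stats::runif(n, 0.2, 0.9),
      stage = sample(1:4, n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2)),
      platinum = stats::runif(n) < 0.3,
      pfs_exceeds_os = FALSE
    )
  })
}
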