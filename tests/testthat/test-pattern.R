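test_that("component ranking flags exclusivity and significance", {
  fit <- compute_gsvd(matched_pair_from_matrices(diag(c(2, 1)), diag(2)))
  rk <- rank_components(fit, theta_min = 0.2, p_min = 0.01)
  expect_true(rk$exclusive_to_1[1])
  expect_false(rk$exclusive_to_1[2])
  expect_equal(selected_component(rk), 1L)
  expect_equal(sum(rk$significance1), 1, tolerance = 1e-12)

  same <- compute_gsvd(matched_pair_from_matrices(diag(3), diag(3)))
  rk0 <- rank_components(same, theta_min = 0.05)
  expect_false(any(rk0$exclusive_to_1))
  expect_false(any(rk0$exclusive_to_2))
})

test_that("selected component recovers a planted pattern", {
  cfg <- synthetic_config(seed = 101)
  sim <- generate_matched_pair(cfg)
  fit <- compute_gsvd(sim$pair)
  rk <- rank_components(fit)
  sel <- selected_component(rk)
  expect_length(sel, 1)
  expect_gte(abs(cor(fit$U1[, sel], sim$truth$pattern1)), 0.9)
})

test_that("segment calls follow the MAD rule on a constructed pattern", {
  # arm baseline 0 with alternating +/-0.1 texture; up- and down-shifted
  # segment masses balance (60 bins each), so the arm median stays 0 and
  # the unscaled MAD stays 0.1 exactly after planting the shifts
  K <- 400
  pattern <- rep(c(0.1, -0.1), K / 2)
  bins <- tibble::tibble(chrom = "chr6", start = seq_len(K) - 1L,
                         end = seq_len(K), n_probes = 1L)
  segments <- tibble::tibble(
    chrom = "chr6",
    start = c(0L, 60L, 120L, 180L, 220L),
    end = c(40L, 80L, 160L, 200L, 240L),
    label = c("up", "up_small", "down", "down_small", "flat"), arm = "6p"
  )
  shifted <- pattern
  shifted[1:40] <- shifted[1:40] + 0.35        # +3.5 MADs, 40 probes
  shifted[61:80] <- shifted[61:80] + 0.35      # +3.5 MADs but only 20 probes
  shifted[121:160] <- shifted[121:160] - 0.35  # -3.5 MADs, 40 probes
  shifted[181:200] <- shifted[181:200] - 0.35  # -3.5 MADs, 20 probes

  calls <- classify_segments(shifted, bins, segments, t_mad = 3, min_probes = 30)
  expect_equal(calls$mad, rep(0.1, 5), tolerance = 1e-12)
  expect_equal(calls$arm_median, rep(0, 5), tolerance = 1e-12)
  expect_equal(calls$delta_in_mads, c(3.5, 3.5, -3.5, -3.5, 0), tolerance = 1e-12)
  expect_equal(as.character(calls$call),
               c("amplified", "amplified", "deleted", "deleted", "unaltered"))
  expect_equal(calls$retained, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(calls$n_probes, c(40, 20, 40, 20, 20))

  # segment median equal to the arm median -> unaltered at any threshold
  flat <- classify_segments(pattern, bins, segments[5, ], t_mad = 0.5)
  expect_equal(as.character(flat$call), "unaltered")
})

test_that("segment calls are invariant under a constant pattern shift", {
  set.seed(51)
  K <- 120
  pattern <- rnorm(K)
  bins <- tibble::tibble(chrom = "chrA", start = seq_len(K) - 1L, end = seq_len(K))
  segments <- tibble::tibble(chrom = "chrA", start = c(0L, 50L),
                             end = c(30L, 90L), label = c("s1", "s2"),
                             arm = "armA")
  a <- classify_segments(pattern, bins, segments)
  b <- classify_segments(pattern + 5.7, bins, segments)
  expect_equal(a$call, b$call)
  expect_equal(a$delta_in_mads, b$delta_in_mads, tolerance = 1e-12)

  none <- tibble::tibble(chrom = "chrB", start = 0L, end = 10L,
                         label = "ghost", arm = "armA")
  expect_error(classify_segments(pattern, bins, none), "ghost")
})

test_that("patient correlations are Spearman with an independent oracle", {
  set.seed(61)
  K <- 40
  pattern <- rnorm(K)
  profiles <- cbind(pattern,                      # identical ranks
                    rev(sort(pattern))[rank(pattern)],  # reversed ranks
                    rnorm(K), rnorm(K))
  colnames(profiles) <- paste0("P", 1:4)
  cors <- correlate_patients(pattern, profiles)
  expect_equal(unname(cors[1]), 1)
  expect_equal(unname(cors[2]), -1)
  # brute-force oracle: rank then Pearson
  for (j in 3:4) {
    expect_equal(unname(cors[j]),
                 cor(rank(pattern), rank(profiles[, j])), tolerance = 1e-12)
  }
  # invariance under strictly monotone transform of the pattern
  expect_equal(correlate_patients(exp(2 * pattern), profiles), cors,
               tolerance = 1e-12)
  # constant column undefined
  prof0 <- cbind(P1 = rep(1, K))
  expect_true(is.na(correlate_patients(pattern, prof0)[1]))
})

test_that("patient classification applies both cutoffs and reports overlap", {
  cls <- classify_patients(c(0.5, 0.2, 0.4), c(0.1, 0.1, 0.1),
                           corr_cutoff = 0.35)
  expect_equal(which(cls$high_by_correlation), c(1L, 3L))

  # Euclidean norm 2 -> coefficient cutoff 0.35 / 2 = 0.175
  corr <- c(sqrt(2), sqrt(2), 0)
  cls2 <- classify_patients(corr, c(0.2, 0.15, 0.1))
  expect_equal(attr(cls2, "coeff_cutoff"), 0.175)
  expect_equal(which(cls2$high_by_coefficient), 1L)
  cls2m <- classify_patients(corr, c(0.8, 0.6, 0.1), scaling = "multiply")
  expect_equal(attr(cls2m, "coeff_cutoff"), 0.7)

  # flags reproducible from stored cutoffs
  expect_equal(cls2$high_by_correlation,
               cls2$correlation > attr(cls2, "corr_cutoff"))
  expect_equal(cls2$high_by_coefficient,
               cls2$coefficient > attr(cls2, "coeff_cutoff"))
  expect_error(classify_patients(c(NA_real_, NA_real_), c(1, 2)), "missing")
})

test_that("high sets by correlation and coefficient recover planted carriers", {
  cfg <- synthetic_config(seed = 103)
  sim <- generate_matched_pair(cfg)
  fit <- compute_gsvd(sim$pair)
  sel <- selected_component(rank_components(fit))
  cors <- correlate_patients(fit$U1[, sel], sim$pair$tumor)
  cls <- classify_patients(cors, fit$Vt[sel, ])
  truth <- unname(sim$truth$carrier)
  expect_gte(balanced_accuracy(cls$high_by_correlation, truth), 0.9)
  expect_gte(balanced_accuracy(cls$high_by_coefficient, truth), 0.9)
  expect_gte(attr(cls, "overlap"), 0.85)
})

test_that("covariate association computes correlations, MWW and hypergeometric", {
  # numeric covariate equal to the vector itself
  v <- c(0.3, -1, 2, 0.5, -0.2, 1.4)
  num <- covariate_association(v, v)
  expect_equal(num$pearson, 1)
  expect_equal(num$spearman, 1)

  # identical distribution across both groups -> two-sided MWW P = 1
  vec <- rep(c(1, 2, 3), 2)
  grp <- rep(c("a", "b"), each = 3)
  assoc <- covariate_association(vec, grp)
  expect_equal(assoc$mww_p, rep(1, 2))

  # hypergeometric oracle: high set identical to a category of size k
  # drawn from n -> upper-tail P = 1 / choose(n, k)
  n <- 8; k <- 3
  labels <- rep(c("x", "y"), c(k, n - k))
  ha <- covariate_association(rnorm(n), labels, high_set = 1:k)
  expect_equal(ha$hypergeom_p[ha$category == "x"], 1 / choose(n, k),
               tolerance = 1e-12)

  # exact MWW on small tie-free groups agrees with enumeration:
  # complete separation of 3 vs 3 gives P = 2 * 1/choose(6,3) = 0.1
  sep <- covariate_association(c(1, 2, 3, 10, 11, 12), rep(c("lo", "hi"), each = 3))
  expect_equal(sep$mww_p, rep(0.1, 2), tolerance = 1e-12)
})

test_that("GC artifact stays shared while batch effects are dataset-exclusive", {
  cfg <- synthetic_config(seed = 107)
  sim <- generate_matched_pair(cfg)
  fit <- compute_gsvd(sim$pair)
  rk <- rank_components(fit)
  sel <- selected_component(rk)
  # selected tumor-exclusive pattern not driven by the GC covariate
  expect_lt(abs(cor(fit$U1[, sel], sim$pair$tumor$bins$gc)), 0.3)
  # a remaining near-pi/4 component carries the tumor sequencer batch
  cand <- setdiff(which(rk$theta > pi / 4 - 0.35), sel)
  p_batch <- min(vapply(cand, function(a) {
    covariate_association(fit$Vt[a, ], sim$truth$batch_tumor)$mww_p[1]
  }, numeric(1)))
  expect_lt(p_batch, 0.01)
})
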