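#' Generalized singular value decomposition of a matched pair
#'
#' Factorizes the tumor and normal matrices simultaneously as
#' `D_i = U_i %*% diag(sigma_i) %*% Vt`, `i = 1, 2`, with dataset-specific
#' column-wise orthonormal `U_i`, positive generalized singular values
#' `sigma_i`, and a shared invertible factor whose transpose `Vt` is
#' row-normalized. Components are ordered by decreasing
#' `sigma1/sigma2`, the ratio that measures how much a component belongs
#' to the tumor rather than the normal dataset; the angular distance
#' `theta = atan(sigma1/sigma2) - pi/4` maps that ratio into
#' `(-pi/4, pi/4)` (near `+pi/4`: tumor-exclusive; near `0`: shared;
#' near `-pi/4`: normal-exclusive).
#'
#' The factorization is computed stably: a thin QR of the stacked matrix
#' `rbind(D1, D2)` followed by the cosine-sine decomposition of the
#' partitioned orthonormal factor. The row norms of the raw shared
#' factor are absorbed equally into both diagonal cores, which leaves
#' every ratio and angle unchanged and makes `Vt` row-normalized. Signs
#' are fixed per component so the largest-magnitude entry of each row of
#' `Vt` is positive.
#'
#' @param pair A `matched_pair` (or anything [matched_pair_from_matrices()]
#'   accepts via `tumor`/`normal` matrices).
#' @param rank_tol Relative rank tolerance: each input must have smallest
#'   singular value `> rank_tol` times its largest.
#' @return A `gsvd_fit` with fields `U1`, `U2`, `sigma1`, `sigma2`, `Vt`,
#'   `theta`, `ratios`, `significance1`, `significance2` (fractions
#'   `sigma_i^2 / sum(sigma_i^2)`), `degenerate_groups` (component index
#'   groups with near-equal ratios, where the decomposition is unique
#'   only up to rotation), and the patient identifiers.
#' @export
compute_gsvd <- function(pair, rank_tol = 1e-10) {
  stopifnot(inherits(pair, "matched_pair"))
  D1 <- pair$tumor$values
  D2 <- pair$normal$values
  L <- ncol(D1)
  for (i in 1:2) {
    Di <- if (i == 1) D1 else D2
    nm <- c("tumor", "normal")[i]
    if (ncol(Di) > nrow(Di)) {
      stop("dataset `", nm, "` has more patients (", ncol(Di),
           ") than bins (", nrow(Di), "); need L <= K")
    }
    d <- svd(Di, nu = 0, nv = 0)$d
    if (d[length(d)] <= rank_tol * d[1]) {
      stop("dataset `", nm, "` is rank deficient (relative smallest ",
           "singular value ", format(d[length(d)] / d[1], digits = 3),
           " <= rank_tol)")
    }
  }

  qrS <- qr(rbind(D1, D2), LAPACK = TRUE)
  Q <- qr.Q(qrS)
  R <- qr.R(qrS)[, order(qrS$pivot), drop = FALSE]
  Q1 <- Q[seq_len(nrow(D1)), , drop = FALSE]
  Q2 <- Q[-seq_len(nrow(D1)), , drop = FALSE]

  # cosine-sine decomposition of the partitioned orthonormal factor:
  # Q1 = P1 C W', Q2 W = U2 S with C^2 + S^2 = I
  sv <- svd(Q1)
  P1 <- sv$u
  cc <- pmin(sv$d, 1)
  W <- sv$v
  X <- Q2 %*% W
  ss <- sqrt(colSums(X^2))
  U2 <- sweep(X, 2, ss, "/")

  Vt_raw <- t(W) %*% R
  rn <- sqrt(rowSums(Vt_raw^2))
  Vt <- sweep(Vt_raw, 1, rn, "/")
  sigma1 <- cc * rn
  sigma2 <- ss * rn
  ratios <- sigma1 / sigma2

  # order by decreasing ratio; ties by decreasing sigma1, then index
  ord <- order(-ratios, -sigma1, seq_len(L), method = "radix")
  P1 <- P1[, ord, drop = FALSE]
  U2 <- U2[, ord, drop = FALSE]
  Vt <- Vt[ord, , drop = FALSE]
  sigma1 <- sigma1[ord]; sigma2 <- sigma2[ord]; ratios <- ratios[ord]

  # sign convention: largest-magnitude entry of each row of Vt positive
  for (a in seq_len(L)) {
    j <- which.max(abs(Vt[a, ]))
    if (Vt[a, j] < 0) {
      Vt[a, ] <- -Vt[a, ]
      P1[, a] <- -P1[, a]
      U2[, a] <- -U2[, a]
    }
  }

  theta <- atan(ratios) - pi / 4

  fit <- structure(
    list(
      U1 = P1, U2 = U2, Vt = Vt,
      sigma1 = sigma1, sigma2 = sigma2,
      ratios = ratios, theta = theta,
      significance1 = sigma1^2 / sum(sigma1^2),
      significance2 = sigma2^2 / sum(sigma2^2),
      degenerate_groups = degenerate_groups(ratios),
      patients = pair$tumor$patients,
      tumor_bins = pair$tumor$bins,
      normal_bins = pair$normal$bins
    ),
    class = "gsvd_fit"
  )
  fit
}

# index groups with |ratio_a - ratio_b| < tol * max(ratio): there the
# decomposition is unique only up to rotation within the group
degenerate_groups <- function(ratios, tol = 1e-8) {
  if (!length(ratios)) return(list())
  thr <- tol * max(ratios)
  grp <- cumsum(c(1, diff(ratios) < -thr))  # ratios are nonincreasing
  gl <- split(seq_along(ratios), grp)
  unname(gl[lengths(gl) > 1])
}

#' GSVD angular distance
#'
#' `atan(sigma1 / sigma2) - pi/4`, the exclusivity of a component to the
#' first dataset, strictly inside `(-pi/4, pi/4)`. Antisymmetric under
#' swapping the two generalized singular values.
#'
#' @param sigma1,sigma2 Strictly positive generalized singular values
#'   (vectorized).
#' @return Angular distance(s) in radians.
#' @export
angular_distance <- function(sigma1, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) {
    stop("generalized singular values must be strictly positive")
  }
  atan(sigma1 / sigma2) - pi / 4
}

#' Reconstruct a dataset from GSVD components
#'
#' Sums the rank-1 terms `sigma_{i,a} * u_{i,a} %o% v_a` over the chosen
#' components. The full component set reproduces the input dataset to
#' machine precision; a singleton gives one rank-1 pattern; the empty
#' set gives the zero matrix of the dataset's shape (documented
#' behavior, not an error).
#'
#' @param fit A `gsvd_fit`.
#' @param dataset Which dataset to reconstruct: 1 (tumor) or 2 (normal).
#' @param components Integer subset of `1:L`; default all.
#' @return A numeric matrix.
#' @export
reconstruct <- function(fit, dataset = 1, components = NULL) {
  stopifnot(inherits(fit, "gsvd_fit"), dataset %in% c(1, 2))
  L <- length(fit$sigma1)
  if (is.null(components)) components <- seq_len(L)
  if (length(components) && (any(components < 1) || any(components > L))) {
    stop("components must lie in 1..", L)
  }
  U <- if (dataset == 1) fit$U1 else fit$U2
  s <- if (dataset == 1) fit$sigma1 else fit$sigma2
  if (!length(components)) {
    return(matrix(0, nrow(U), ncol(fit$Vt)))
  }
  cs <- as.integer(components)
  U[, cs, drop = FALSE] %*% (s[cs] * fit$Vt[cs, , drop = FALSE])
}

#' @export
print.gsvd_fit <- function(x, ...) {
  L <- length(x$sigma1)
  cat("<gsvd_fit> ", L, " components over ", length(x$patients),
      " patients\n", sep = "")
  cat("  theta range: [", format(min(x$theta), digits = 4), ", ",
      format(max(x$theta), digits = 4), "] rad\n", sep = "")
  if (length(x$degenerate_groups)) {
    cat("  degenerate ratio groups: ", length(x$degenerate_groups), "\n", sep = "")
  }
  invisible(x)
}

#' Per-component summary of a GSVD fit
#'
#' @param x A `gsvd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `sigma1`,
#'   `sigma2`, `ratio`, `theta`, `significance1`, `significance2`,
#'   `degenerate`.
#' @method tidy gsvd_fit
#' @export
tidy.gsvd_fit <- function(x, ...) {
  L <- length(x$sigma1)
  degen <- rep(FALSE, L)
  for (g in x$degenerate_groups) degen[g] <- TRUE
  tibble::tibble(
    component = seq_len(L),
    sigma1 = x$sigma1, sigma2 = x$sigma2,
    ratio = x$ratios, theta = x$theta,
    significance1 = x$significance1, significance2 = x$significance2,
    degenerate = degen
  )
}

#' One-row summary of a GSVD fit
#'
#' @param x A `gsvd_fit`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of components and patients, the
#'   extreme angular distances, and the count of degenerate groups.
#' @method glance gsvd_fit
#' @export
glance.gsvd_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$sigma1),
    n_patients = length(x$patients),
    max_theta = max(x$theta),
    min_theta = min(x$theta),
    n_degenerate_groups = length(x$degenerate_groups)
  )
}

#' Bar chart of GSVD angular distances
#'
#' @param object A `gsvd_fit`.
#' @param ... Unused.
#' @return A ggplot: per-component angular distance, colored by tumor
#'   significance, with the `+/- pi/4` exclusivity limits.
#' @method autoplot gsvd_fit
#' @export
autoplot.gsvd_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$theta,
                                   fill = .data$significance1)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-pi / 4, 0, pi / 4), linetype = "dashed") +
    ggplot2::labs(x = "component", y = "angular distance (rad)",
                  fill = "tumor\nsignificance") +
    ggplot2::theme_minimal()
}
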