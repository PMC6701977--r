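#' Unfold a third-order tensor along one mode
#'
#' For a `K x L x M` array with axes (bins `k`, patients `l` = x axis,
#' platforms `m` = y axis) the three unfoldings are:
#' \describe{
#'   \item{`row`}{`K x LM`, column index `(m-1)*L + l` (x varies fastest,
#'     matching the Kronecker-product convention used for the core tensor).}
#'   \item{`x`}{the `MK x L` matrix whose transpose is `L x MK` with
#'     column index `(m-1)*K + k`.}
#'   \item{`y`}{the `KL x M` matrix whose transpose is `M x KL` with
#'     column index `(l-1)*K + k`.}
#' }
#'
#' @param tensor A 3-dimensional numeric array.
#' @param mode One of `"row"`, `"x"`, `"y"`.
#' @return The unfolded matrix.
#' @export
unfold <- function(tensor, mode = c("row", "x", "y")) {
  stopifnot(length(dim(tensor)) == 3)
  mode <- match.arg(mode)
  d <- dim(tensor)
  K <- d[1]; L <- d[2]; M <- d[3]
  switch(mode,
    row = { dim(tensor) <- c(K, L * M); tensor },
    x = {
      B <- aperm(tensor, c(2, 1, 3))  # L x K x M
      dim(B) <- c(L, K * M)
      t(B)
    },
    y = {
      B <- aperm(tensor, c(3, 1, 2))  # M x K x L
      dim(B) <- c(M, K * L)
      t(B)
    }
  )
}

#' Refold a row-mode unfolding back into a tensor
#'
#' Inverse of `unfold(tensor, "row")`.
#'
#' @param mat A `K x LM` matrix.
#' @param L,M Target patient and platform dimensions.
#' @return A `K x L x M` array.
#' @export
refold_row <- function(mat, L, M) {
  stopifnot(ncol(mat) == L * M)
  array(mat, dim = c(nrow(mat), L, M))
}

#' Tensor GSVD of a matched tensor pair
#'
#' Extends [compute_gsvd()] to two third-order tensors `D_i` (`K_i x L x M`)
#' sharing the patient (x) and platform (y) axes. Each dataset is
#' factorized as `D_i = R_i x_a U_i x_b V_x x_c V_y` with column-wise
#' orthonormal row-mode factors `U_i` (`K_i x LM`), shared invertible
#' row-normalized `V_x` (`L x L`) and `V_y` (`M x M`), and core tensors
#' `R_i` (`LM x L x M`) of superposition coefficients `r_{i,abc}` (the
#' tensor generalized singular values).
#'
#' The factors come from the GSVDs of the three pairs of mode
#' unfoldings: the row unfoldings give `U_i` and the row-mode values
#' `sigma_{i,a}`; the x and y unfoldings give `V_x` and `V_y` (their
#' dataset-specific factors are intermediate and returned only for
#' inspection). The cores are computed as
#' `R_i = Sigma_i Vt (Vy^-T kron Vx^-T)` and reshaped; consequently the
#' ratio `|r1_abc / r2_abc|` equals `sigma1_a / sigma2_a` wherever the
#' denominator is nonzero, and the tensor angular distance
#' `Theta_abc = atan(|r1/r2|) - pi/4` equals the row-mode `theta_a`.
#'
#' @param tpair A `matched_tensor_pair`.
#' @param rank_tol Relative rank tolerance for every unfolded pair.
#' @return A `tensor_gsvd_fit` with fields `U1`, `U2`, `Vx_t`, `Vy_t`
#'   (row-normalized transposes of the shared factors), `R1`, `R2`
#'   (`LM x L x M` core tensors), `Theta` (tensor angular distances,
#'   `NA` where `r2` is numerically zero), `row_mode` (the embedded
#'   `gsvd_fit` of the row unfoldings) and `x_mode`, `y_mode`
#'   (intermediate `gsvd_fit`s of the x/y unfoldings).
#' @export
compute_tensor_gsvd <- function(tpair, rank_tol = 1e-10) {
  stopifnot(inherits(tpair, "matched_tensor_pair"))
  D1 <- tpair$tumor; D2 <- tpair$normal
  L <- dim(D1)[2]; M <- dim(D1)[3]

  gsvd_of <- function(A1, A2, mode) {
    pair <- matched_pair_from_matrices(A1, A2)
    tryCatch(
      compute_gsvd(pair, rank_tol = rank_tol),
      error = function(e) {
        stop("rank-deficient ", mode, "-mode unfolding: ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }

  row_mode <- gsvd_of(unfold(D1, "row"), unfold(D2, "row"), "row")
  x_mode <- gsvd_of(unfold(D1, "x"), unfold(D2, "x"), "x")
  y_mode <- if (M == 1) NULL else gsvd_of(unfold(D1, "y"), unfold(D2, "y"), "y")

  Vx_t <- x_mode$Vt                       # L x L, rows normalized
  Vy_t <- if (M == 1) matrix(1, 1, 1) else y_mode$Vt

  # cores: R_i = Sigma_i V^T (Vy^-T kron Vx^-T), unfolded LM x LM.
  # Vx^-T etc. obtained by solving; condition warnings for near-dependence.
  inv_t <- function(Vt, label) {
    kap <- kappa(Vt, exact = TRUE)
    if (kap > 1e8) {
      warning("shared ", label, " factor nearly dependent (condition number ",
              format(kap, digits = 3), ")")
    }
    # V^-T is the inverse of the stored row-normalized transpose V^T
    solve(Vt)
  }
  Vx_inv_t <- inv_t(Vx_t, "x")
  Vy_inv_t <- if (M == 1) matrix(1, 1, 1) else inv_t(Vy_t, "y")

  core_mat <- function(sigma, Vt) {
    (sigma * Vt) %*% (Vy_inv_t %x% Vx_inv_t)
  }
  R1m <- core_mat(row_mode$sigma1, row_mode$Vt)
  R2m <- core_mat(row_mode$sigma2, row_mode$Vt)

  Theta <- atan(abs(R1m / R2m)) - pi / 4
  zero2 <- abs(R2m) < 1e-12 * max(abs(R2m))
  Theta[zero2] <- NA_real_

  structure(
    list(
      U1 = row_mode$U1, U2 = row_mode$U2,
      Vx_t = Vx_t, Vy_t = Vy_t,
      R1 = refold_row(R1m, L, M), R2 = refold_row(R2m, L, M),
      Theta = refold_row(Theta, L, M),
      row_mode = row_mode, x_mode = x_mode, y_mode = y_mode,
      patients = tpair$patients, platforms = tpair$platforms
    ),
    class = "tensor_gsvd_fit"
  )
}

#' Tensor GSVD angular distance
#'
#' `atan(|r1 / r2|) - pi/4` for a pair of tensor generalized singular
#' values. Undefined (returns `NA`) where `r2` is zero, rather than
#' snapping to `pi/4`.
#'
#' @param r1,r2 Tensor generalized singular values (vectorized).
#' @return Angular distance(s) in radians, `NA` where `r2 == 0`.
#' @export
tensor_angular_distance <- function(r1, r2) {
  out <- atan(abs(r1 / r2)) - pi / 4
  out[r2 == 0] <- NA_real_
  out
}

#' Reconstruct a dataset from its tensor GSVD
#'
#' Applies the three mode products `R_i x_a U_i x_b V_x x_c V_y`.
#'
#' @param fit A `tensor_gsvd_fit`.
#' @param dataset 1 (tumor) or 2 (normal).
#' @return A `K_i x L x M` array.
#' @export
reconstruct_tensor <- function(fit, dataset = 1) {
  stopifnot(inherits(fit, "tensor_gsvd_fit"), dataset %in% c(1, 2))
  U <- if (dataset == 1) fit$U1 else fit$U2
  Rm <- unfold(if (dataset == 1) fit$R1 else fit$R2, "row")
  L <- ncol(fit$Vx_t); M <- ncol(fit$Vy_t)
  # row unfolding of the reconstruction: U %*% Rm %*% (Vy kron Vx)^T
  mat <- U %*% Rm %*% t(t(fit$Vy_t) %x% t(fit$Vx_t))
  refold_row(mat, L, M)
}

#' @export
print.tensor_gsvd_fit <- function(x, ...) {
  cat("<tensor_gsvd_fit> ", nrow(x$U1), "x", ncol(x$Vx_t), "x", ncol(x$Vy_t),
      " tumor vs ", nrow(x$U2), "-bin normal; ", length(x$row_mode$sigma1),
      " row-mode components\n", sep = "")
  invisible(x)
}

#' Long table of tensor generalized singular values
#'
#' @param x A `tensor_gsvd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per `(a, b, c)` triplet: `r1`, `r2`,
#'   `Theta` (`NA` where undefined) and the row-mode `theta_a`.
#' @method tidy tensor_gsvd_fit
#' @export
tidy.tensor_gsvd_fit <- function(x, ...) {
  d <- dim(x$R1)
  idx <- expand.grid(a = seq_len(d[1]), b = seq_len(d[2]), c = seq_len(d[3]))
  tibble::tibble(
    a = idx$a, b = idx$b, c = idx$c,
    r1 = as.vector(x$R1), r2 = as.vector(x$R2),
    Theta = as.vector(x$Theta),
    theta_a = x$row_mode$theta[idx$a]
  )
}

#' @method glance tensor_gsvd_fit
#' @export
glance.tensor_gsvd_fit <- function(x, ...) {
  tibble::tibble(
    n_row_components = length(x$row_mode$sigma1),
    n_patients = length(x$patients),
    n_platforms = length(x$platforms),
    max_theta = max(x$row_mode$theta),
    min_theta = min(x$row_mode$theta)
  )
}
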