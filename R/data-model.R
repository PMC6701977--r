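#' Construct a copy-number profile matrix
#'
#' A profile matrix holds relative copy numbers for `K` genomic bins
#' (rows) by `L` patients (columns). Bins follow the BED convention:
#' 0-based, half-open `[start, end)` coordinates. Bins are sorted by
#' `(chrom, start)` on construction; values must be finite and the
#' patient identifiers unique.
#'
#' @param bins A data frame with columns `chrom`, `start`, `end` and
#'   optionally `n_probes` (positive integer, default 1) and `gc`
#'   (fraction in \[0, 1\]).
#' @param values Numeric matrix, `nrow(bins)` by `length(patients)`.
#' @param patients Character vector of unique patient identifiers.
#' @return An object of class `profile_matrix` with fields `bins`
#'   (tibble), `patients` and `values`.
#' @export
profile_matrix <- function(bins, values, patients) {
  bins <- tibble::as_tibble(bins)
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  if (!("n_probes" %in% names(bins))) bins$n_probes <- 1L
  if (!("gc" %in% names(bins))) bins$gc <- NA_real_
  values <- as.matrix(values)
  patients <- as.character(patients)

  if (nrow(bins) != nrow(values)) {
    stop("`bins` has ", nrow(bins), " rows but `values` has ", nrow(values))
  }
  if (length(patients) != ncol(values)) {
    stop("`patients` has length ", length(patients),
         " but `values` has ", ncol(values), " columns")
  }
  if (anyDuplicated(patients)) {
    stop("duplicate patient identifiers: ",
         paste(unique(patients[duplicated(patients)]), collapse = ", "))
  }
  bad <- which(!(bins$start < bins$end))
  if (length(bad)) {
    stop("bin rows with start >= end: ", paste(bad, collapse = ", "))
  }
  gc_bad <- which(!is.na(bins$gc) & (bins$gc < 0 | bins$gc > 1))
  if (length(gc_bad)) {
    stop("gc fraction outside [0, 1] at bin rows: ",
         paste(gc_bad, collapse = ", "))
  }
  if (!all(is.finite(values))) {
    stop("profile values must all be finite (no NA/NaN/Inf); ",
         sum(!is.finite(values)), " offending entries")
  }

  ord <- order(bins$chrom, bins$start, method = "radix")
  bins <- bins[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]
  dimnames(values) <- list(NULL, patients)

  structure(
    list(bins = bins, patients = patients, values = values),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix> ", nrow(x$values), " bins x ",
      length(x$patients), " patients\n", sep = "")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' Long-format view of a profile matrix
#'
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (bin, patient) pair: the bin
#'   coordinates, `patient` and `value`.
#' @method as_tibble profile_matrix
#' @export
as_tibble.profile_matrix <- function(x, ...) {
  dplyr::bind_cols(
    x$bins[rep(seq_len(nrow(x$bins)), times = length(x$patients)), ],
    tibble::tibble(
      patient = rep(x$patients, each = nrow(x$bins)),
      value = as.vector(x$values)
    )
  )
}

#' Pair tumor and normal profiles over their shared patients
#'
#' Restricts both matrices to the intersection of their patient
#' identifiers and puts the columns in the same (lexicographic) order,
#' producing the column-matched, row-independent pair of datasets that
#' the GSVD factorizes. The bin axes stay independent: the tumor and
#' normal matrices may cover different bins and even different numbers
#' of bins.
#'
#' @param tumor,normal `profile_matrix` objects.
#' @return A `matched_pair` with fields `tumor` and `normal` whose
#'   patient axes are identical.
#' @export
match_patients <- function(tumor, normal) {
  stopifnot(inherits(tumor, "profile_matrix"), inherits(normal, "profile_matrix"))
  shared <- sort(intersect(tumor$patients, normal$patients))
  if (length(shared) < 2) {
    stop("need at least 2 shared patients; found ", length(shared))
  }
  take <- function(pm, ids) {
    idx <- match(ids, pm$patients)
    profile_matrix(pm$bins, pm$values[, idx, drop = FALSE], ids)
  }
  structure(
    list(tumor = take(tumor, shared), normal = take(normal, shared)),
    class = "matched_pair"
  )
}

#' @export
print.matched_pair <- function(x, ...) {
  cat("<matched_pair> tumor ", nrow(x$tumor$values), " bins, normal ",
      nrow(x$normal$values), " bins, ", length(x$tumor$patients),
      " shared patients\n", sep = "")
  invisible(x)
}

#' Construct a matched pair directly from two matrices
#'
#' Convenience constructor for decomposition-oriented work where bins
#' carry no genomic coordinates (e.g. simulations): bins are synthesized
#' as unit intervals on a single pseudo-chromosome.
#'
#' @param tumor,normal Numeric matrices with the same number of columns.
#' @param patients Optional patient identifiers (defaults to `P001`...).
#' @return A `matched_pair`.
#' @export
matched_pair_from_matrices <- function(tumor, normal, patients = NULL) {
  tumor <- as.matrix(tumor)
  normal <- as.matrix(normal)
  if (ncol(tumor) != ncol(normal)) {
    stop("tumor and normal must share the patient (column) axis: ",
         ncol(tumor), " vs ", ncol(normal), " columns")
  }
  if (is.null(patients)) {
    patients <- sprintf("P%03d", seq_len(ncol(tumor)))
  }
  mk_bins <- function(k) {
    tibble::tibble(chrom = "bin", start = seq_len(k) - 1L, end = seq_len(k))
  }
  structure(
    list(
      tumor = profile_matrix(mk_bins(nrow(tumor)), tumor, patients),
      normal = profile_matrix(mk_bins(nrow(normal)), normal, patients)
    ),
    class = "matched_pair"
  )
}

#' Construct a matched tensor pair
#'
#' Third-order extension of [match_patients()]: each dataset is a
#' `K_i x L x M` array over bins, patients (shared x axis) and profiling
#' platforms (shared y axis). Requires `L * M <= K_i` for both datasets
#' so the row unfoldings can have full column rank.
#'
#' @param tumor,normal Numeric arrays of dimension `K_i x L x M`.
#' @param patients Length-`L` patient identifiers.
#' @param platforms Length-`M` platform identifiers.
#' @return A `matched_tensor_pair`.
#' @export
matched_tensor_pair <- function(tumor, normal, patients = NULL, platforms = NULL) {
  stopifnot(length(dim(tumor)) == 3, length(dim(normal)) == 3)
  dt <- dim(tumor); dn <- dim(normal)
  if (dt[2] != dn[2] || dt[3] != dn[3]) {
    stop("tumor and normal tensors must share the patient and platform axes")
  }
  L <- dt[2]; M <- dt[3]
  if (L * M > dt[1] || L * M > dn[1]) {
    stop("need L*M <= K_i for both datasets (row unfoldings of full column rank); ",
         "got L*M = ", L * M, ", K = ", dt[1], " and ", dn[1])
  }
  if (is.null(patients)) patients <- sprintf("P%03d", seq_len(L))
  if (is.null(platforms)) platforms <- sprintf("platform%d", seq_len(M))
  stopifnot(length(patients) == L, length(platforms) == M)
  structure(
    list(tumor = tumor, normal = normal,
         patients = as.character(patients), platforms = as.character(platforms)),
    class = "matched_tensor_pair"
  )
}

#' @export
print.matched_tensor_pair <- function(x, ...) {
  cat("<matched_tensor_pair> tumor ", paste(dim(x$tumor), collapse = "x"),
      ", normal ", paste(dim(x$normal), collapse = "x"), "\n", sep = "")
  invisible(x)
}

validate_clinical <- function(df) {
  req <- c("patient_id", "os_months", "os_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  if (!("pfs_months" %in% names(df))) df$pfs_months <- NA_real_
  if (!("stage" %in% names(df))) df$stage <- NA_integer_
  if (!("platinum" %in% names(df))) df$platinum <- NA

  parse_flag <- function(x, col) {
    if (is.logical(x)) return(x)
    x_chr <- tolower(trimws(as.character(x)))
    out <- rep(NA, length(x_chr))
    out[x_chr %in% c("1", "true", "t")] <- TRUE
    out[x_chr %in% c("0", "false", "f")] <- FALSE
    bad <- which(!is.na(x_chr) & x_chr != "na" & x_chr != "" & is.na(out))
    if (length(bad)) {
      stop("column `", col, "` has values outside {0,1,true,false} at row(s): ",
           paste(bad, collapse = ", "))
    }
    out
  }
  df$os_event <- parse_flag(df$os_event, "os_event")
  if (anyNA(df$os_event)) {
    stop("`os_event` is required for every record; missing at row(s): ",
         paste(which(is.na(df$os_event)), collapse = ", "))
  }
  df$platinum <- parse_flag(df$platinum, "platinum")
  df$os_months <- as.numeric(df$os_months)
  df$pfs_months <- as.numeric(df$pfs_months)
  df$stage <- parse_stage(df$stage)

  if (any(df$os_months < 0, na.rm = TRUE)) {
    stop("os_months must be nonnegative; offending row(s): ",
         paste(which(df$os_months < 0), collapse = ", "))
  }
  flagged <- !is.na(df$pfs_months) & df$pfs_months > df$os_months
  if (any(flagged)) {
    warning("pfs_months exceeds os_months for row(s): ",
            paste(which(flagged), collapse = ", "), "; records flagged")
  }
  df$pfs_exceeds_os <- flagged
  df[c("patient_id", "os_months", "os_event", "pfs_months", "stage",
       "platinum", "pfs_exceeds_os")]
}

# Stage as ordinal 1..4; accepts integers or roman numerals (I-IV, case
# insensitive, substage suffixes like "IIIa" tolerated).
parse_stage <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x_chr <- toupper(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x_chr))
  roman <- c(IV = 4L, III = 3L, II = 2L, I = 1L)
  for (nm in names(roman)) {
    hit <- is.na(out) & startsWith(x_chr, nm)
    out[hit] <- roman[[nm]]
  }
  num <- suppressWarnings(as.integer(x_chr))
  out[is.na(out) & !is.na(num)] <- num[is.na(out) & !is.na(num)]
  out
}
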