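#' Read a copy-number profile matrix from TSV
#'
#' Expected header: `chrom start end [n_probes] [gc] <patient ids...>`,
#' tab separated; coordinates 0-based half-open. Every non-coordinate,
#' non-annotation column is treated as one patient's relative
#' copy-number profile.
#'
#' @param path Path to a TSV file.
#' @return A [profile_matrix()].
#' @export
read_profile_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta_cols <- intersect(c("chrom", "start", "end", "n_probes", "gc"), names(df))
  if (!all(c("chrom", "start", "end") %in% meta_cols)) {
    stop("profile TSV must start with columns chrom, start, end: ", path)
  }
  patient_cols <- setdiff(names(df), meta_cols)
  if (length(patient_cols) < 1) stop("no patient columns found in ", path)
  vals <- as.matrix(df[patient_cols])
  if (!is.numeric(vals)) {
    bad <- patient_cols[!vapply(df[patient_cols], is.numeric, logical(1))]
    for (col in bad) {
      row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) & !is.na(df[[col]]))[1]
      stop("non-numeric value in column `", col, "`, row ", row, " of ", path)
    }
  }
  bins <- df[meta_cols]
  names(bins)[names(bins) == "gc"] <- "gc"
  profile_matrix(bins, vals, patient_cols)
}

#' Write a profile matrix to TSV
#'
#' Inverse of [read_profile_matrix()]; full double precision is kept so
#' a write/read round trip reproduces the matrix.
#'
#' @param pm A `profile_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  keep <- c("chrom", "start", "end", "n_probes",
            if (!all(is.na(pm$bins$gc))) "gc")
  df <- dplyr::bind_cols(pm$bins[keep], tibble::as_tibble(pm$values))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical outcome table from TSV
#'
#' Requires columns `patient_id`, `os_months` (overall survival, months)
#' and `os_event` (1/0 or true/false, death observed); optional
#' `pfs_months` (progression-free survival), `stage` (I-IV or 1-4) and
#' `platinum` (platinum-treated flag). Records where `pfs_months`
#' exceeds `os_months` raise a warning and are flagged in the
#' `pfs_exceeds_os` column.
#'
#' @param path Path to a TSV file.
#' @return A tibble of survival records, one row per patient.
#' @export
read_clinical <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_clinical(df)
}

#' Write survival records to TSV
#'
#' @param records A tibble of survival records (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(records, path) {
  out <- records[intersect(
    c("patient_id", "os_months", "os_event", "pfs_months", "stage", "platinum"),
    names(records))]
  out$os_event <- as.integer(out$os_event)
  if ("platinum" %in% names(out)) out$platinum <- as.integer(out$platinum)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read segment definitions (BED) with a chromosome-arm table
#'
#' Segments come from a BED file (`chrom start end name`, 0-based
#' half-open); the arm table is a 2-column TSV (`name`, `arm`) assigning
#' every segment to exactly one chromosome arm. Arm assignment is an
#' input, not derived from any genome build.
#'
#' @param bed_path Path to the 4-column BED file.
#' @param arm_path Path to the 2-column TSV (`name`, `arm`). May be
#'   `NULL` if the BED names already encode arms (then `arm = name`).
#' @return A tibble with columns `chrom`, `start`, `end`, `label`, `arm`.
#' @export
read_segments <- function(bed_path, arm_path = NULL) {
  seg <- readr::read_tsv(
    bed_path, col_names = c("chrom", "start", "end", "label"),
    show_col_types = FALSE, progress = FALSE, comment = "#"
  )
  if (anyDuplicated(seg$label)) {
    stop("duplicate segment labels in ", bed_path)
  }
  if (is.null(arm_path)) {
    seg$arm <- seg$label
  } else {
    arms <- readr::read_tsv(arm_path, show_col_types = FALSE, progress = FALSE)
    names(arms)[1:2] <- c("name", "arm")
    idx <- match(seg$label, arms$name)
    if (anyNA(idx)) {
      stop("segments without an arm assignment: ",
           paste(seg$label[is.na(idx)], collapse = ", "))
    }
    seg$arm <- arms$arm[idx]
  }
  check_segment_overlap(seg)
  seg
}

check_segment_overlap <- function(seg) {
  by_arm <- split(seg, seg$arm)
  for (arm in names(by_arm)) {
    s <- by_arm[[arm]]
    s <- s[order(s$chrom, s$start), ]
    same_chrom <- s$chrom[-1] == s$chrom[-nrow(s)]
    if (nrow(s) > 1 && any(same_chrom & s$start[-1] < s$end[-nrow(s)])) {
      stop("overlapping segments within arm ", arm)
    }
  }
  invisible(seg)
}

#' Save decomposition factors as an archive plus TSV exports
#'
#' Writes a single RDS archive keyed by factor name and, alongside it,
#' one TSV per factor and a per-component summary table.
#'
#' @param fit A `gsvd_fit` (see [compute_gsvd()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
export_gsvd <- function(fit, dir) {
  stopifnot(inherits(fit, "gsvd_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(unclass(fit), file.path(dir, "decomposition.rds"))
  wm <- function(m, name) {
    readr::write_tsv(tibble::as_tibble(m, .name_repair = "unique_quiet"),
                     file.path(dir, paste0(name, ".tsv")), progress = FALSE,
                     col_names = FALSE)
  }
  wm(fit$U1, "U1"); wm(fit$U2, "U2"); wm(fit$Vt, "Vt")
  readr::write_tsv(tidy(fit), file.path(dir, "components.tsv"), progress = FALSE)
  invisible(dir)
}
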