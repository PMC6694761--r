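#' Per-target mismatch table
#'
#' Compares target sequences to a guide's spacer and returns one row per
#' mismatched base. Positions are numbered PAM-proximally: position 1 is the
#' base adjacent to the PAM (the 3' end of the spacer string), position `L`
#' the PAM-distal end.
#'
#' @param targets character vector of target sequences (same length as the
#'   spacer, A/C/G/T only).
#' @param guide a [guide_spec()] object (or a plain spacer string).
#' @return a `data.table` with columns `idx` (index into `targets`),
#'   `pos` (PAM-proximal position), `wt` (spacer base), `obs` (target base).
#' @export
mismatch_table <- function(targets, guide) {
  spacer <- if (inherits(guide, "blt_guide")) guide$spacer else guide
  L <- nchar(spacer)
  if (any(nchar(targets) != L))
    stop("targets must have the spacer length (", L, ")", call. = FALSE)
  bad <- grepl("[^ACGT]", targets)
  if (any(bad))
    stop("targets contain ambiguous (non-ACGT) bases", call. = FALSE)
  tm <- .char_matrix(targets, L)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  mm <- tm != matrix(sp, nrow = length(targets), ncol = L, byrow = TRUE)
  w <- which(mm, arr.ind = TRUE)
  strpos <- w[, 2L]
  data.table(idx = w[, 1L],
             pos = L - strpos + 1L,          # PAM-proximal numbering
             wt = sp[strpos],
             obs = tm[w])[order(idx, pos)]
}

#' Annotate targets with mismatch summaries
#'
#' Adds, for each target, the mismatch count, a compact annotation string
#' (`pos:WT>obs`, PAM-proximal positions, comma-separated) and the mean
#' mismatch distance from the PAM.
#'
#' @inheritParams mismatch_table
#' @return a `data.table` with one row per target: `target`, `n_mm`, `mm`,
#'   `mean_mm_dist_pam` (NA for perfect matches).
#' @export
annotate_mismatches <- function(targets, guide) {
  mm <- mismatch_table(targets, guide)
  out <- data.table(target = targets, n_mm = 0L, mm = "",
                    mean_mm_dist_pam = NA_real_)
  if (nrow(mm)) {
    ann <- mm[, .(n_mm = .N,
                  mm = paste0(pos, ":", wt, ">", obs, collapse = ","),
                  mean_mm_dist_pam = mean(pos)), by = idx]
    out[ann$idx, `:=`(n_mm = ann$n_mm, mm = ann$mm,
                      mean_mm_dist_pam = ann$mean_mm_dist_pam)]
  }
  out[]
}
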