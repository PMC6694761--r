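#' Cleavage-given-binding from printed observation counts
#'
#' Computes the uncleaved fraction and the probability of cleavage given
#' Cas9 binding from a pair of (uncleaved, total) observation counts, as
#' reported for a pulled-down, Cas9-bound population:
#' `p_cut = 1 - uncleaved / total`.
#'
#' Published count pairs are occasionally transposed (uncleaved printed
#' larger than total); when the ratio exceeds 1 the two counts are swapped
#' with a loud warning rather than producing an impossible fraction.
#'
#' @param uncleaved uncleaved observation count.
#' @param total total observation count.
#' @return list with `p_cut`, `uncleaved_fraction`, `uncleaved`, `total`.
#' @examples
#' pcut_from_counts(62587, 353065)$p_cut   # 0.823
#' @export
pcut_from_counts <- function(uncleaved, total) {
  stopifnot(uncleaved >= 0, total >= 0)
  if (total > 0 && uncleaved > total) {
    warning("uncleaved count exceeds total (", uncleaved, "/", total,
            "); counts look transposed - swapping", call. = FALSE)
    tmp <- uncleaved; uncleaved <- total; total <- tmp
  }
  if (total == 0)
    return(list(p_cut = NA_real_, uncleaved_fraction = NA_real_,
                uncleaved = uncleaved, total = total))
  uf <- uncleaved / total
  list(p_cut = 1 - uf, uncleaved_fraction = uf,
       uncleaved = uncleaved, total = total)
}

#' Estimate P_cut from paired bound / whole-reaction records
#'
#' Joins the target records of a Cas9-bound (bead pull-down) library and a
#' whole-reaction control and estimates, per target or per mismatch-count
#' class, the probability of cleavage given binding
#' (`p_cut = bound_cut / bound_total`) alongside the whole-reaction cut
#' fraction. An `"on_target"` row pooling all perfect-match UMI_Ts is
#' always included (the same pooling convention as the eta normalization).
#'
#' @param bound_records target records of the bound fraction.
#' @param whole_records target records of the whole reaction.
#' @param guide a [guide_spec()] (used for mismatch annotation).
#' @param by `"target"` (per UMI_T) or `"mismatch_count"` (pool by number
#'   of mismatches).
#' @param min_obs classes/targets with fewer bound observations are flagged
#'   `low_support`.
#' @return a `data.table` of P_cut records: key columns, `bound_cut`,
#'   `bound_total`, `whole_cut`, `whole_total`, `p_cut` (NA where
#'   `bound_total` is 0), `whole_fraction`, `mean_mm_dist_pam`,
#'   `low_support`.
#' @export
compute_pcut <- function(bound_records, whole_records, guide,
                         by = c("target", "mismatch_count"),
                         min_obs = 20L) {
  by <- match.arg(by)
  prep <- function(rec) {
    x <- as.data.table(rec)
    if ("validated" %in% names(x)) x <- x[validated == TRUE]
    if (!"n_mm" %in% names(x)) {
      ann <- annotate_mismatches(x$target, guide)
      x[, `:=`(n_mm = ann$n_mm, mean_mm_dist_pam = ann$mean_mm_dist_pam)]
    }
    x
  }
  b <- prep(bound_records)
  w <- prep(whole_records)
  if (by == "target") {
    bs <- b[, .(bound_cut = sum(n_cut), bound_total = sum(n_obs),
                mean_mm_dist_pam = mean(mean_mm_dist_pam, na.rm = TRUE),
                n_mm = n_mm[1L]), by = .(umi_t)]
    ws <- w[, .(whole_cut = sum(n_cut), whole_total = sum(n_obs)),
            by = .(umi_t)]
    key <- "umi_t"
  } else {
    bs <- b[, .(bound_cut = sum(n_cut), bound_total = sum(n_obs),
                mean_mm_dist_pam = mean(mean_mm_dist_pam, na.rm = TRUE)),
            by = .(n_mm)]
    ws <- w[, .(whole_cut = sum(n_cut), whole_total = sum(n_obs)),
            by = .(n_mm)]
    key <- "n_mm"
  }
  out <- merge(bs, ws, by = key, all = TRUE)
  for (col in c("bound_cut", "bound_total", "whole_cut", "whole_total"))
    out[is.na(get(col)), (col) := 0L]
  if (by == "mismatch_count") out[, class := as.character(n_mm)]
  ## pooled on-target class (the eta-normalization convention)
  on <- data.table(
    bound_cut = b[n_mm == 0L, sum(n_cut)],
    bound_total = b[n_mm == 0L, sum(n_obs)],
    whole_cut = w[n_mm == 0L, sum(n_cut)],
    whole_total = w[n_mm == 0L, sum(n_obs)],
    mean_mm_dist_pam = NA_real_, n_mm = 0L)
  if (by == "target") on[, umi_t := "on_target"] else
    on[, class := "on_target"]
  out <- rbind(out, on, fill = TRUE)
  out[, p_cut := fifelse(bound_total > 0, bound_cut / bound_total, NA_real_)]
  out[, whole_fraction := fifelse(whole_total > 0,
                                  whole_cut / whole_total, NA_real_)]
  out[, low_support := bound_total < min_obs]
  out[]
}

#' Whole-reaction versus Cas9-bound efficiency pairs
#'
#' Pairs each target's normalized efficiency in the whole reaction with its
#' efficiency in the Cas9-bound fraction, annotated with the mean mismatch
#' distance from the PAM. The identity-line residual (`whole - bound`) is
#' the occlusion-risk indicator: targets whose bound-fraction efficiency
#' matches the whole reaction (near y = x, typically PAM-distal mismatch
#' combinations) derive their overall efficiency from cleavage-given-
#' binding rather than binding, and are flagged as occlusion-prone.
#'
#' @param eta_whole,eta_bound efficiency tables ([compute_eta()]) of the
#'   whole reaction and the bound fraction, sharing UMI_Ts.
#' @param identity_tol absolute residual below which a target is flagged
#'   `occlusion_risk`.
#' @return `data.table`: `umi_t`, `n_mm`, `mean_mm_dist_pam`, `eta_whole`,
#'   `eta_bound`, `residual`, `occlusion_risk`.
#' @export
pcut_vs_whole <- function(eta_whole, eta_bound, identity_tol = 0.1) {
  w <- as.data.table(eta_whole)
  b <- as.data.table(eta_bound)
  p <- merge(w[, .(umi_t, n_mm, mean_mm_dist_pam, eta_whole = eta)],
             b[, .(umi_t, eta_bound = eta)], by = "umi_t")
  p[, residual := eta_whole - eta_bound]
  p[, occlusion_risk := abs(residual) <= identity_tol]
  p[]
}
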