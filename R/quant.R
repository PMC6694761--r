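#' Normalized cleavage efficiency
#'
#' Computes, per target, the on-target-normalized cleavage efficiency
#'
#' `eta_i = (cut_i / obs_i) * (obs_on / cut_on)`
#'
#' where the on-target sums pool every validated perfect-match UMI_T within
#' the same (replicate) group. The on-target class therefore has eta = 1 by
#' construction; mismatched targets can exceed 1 and are deliberately not
#' clipped. When the input carries a `replicate` column, normalization is
#' performed within each replicate.
#'
#' @param records validated target records (from [validate_targets()],
#'   [group_by_guide_pam()] or [tabulate_records()]); rows with
#'   `validated == FALSE` are dropped. Mismatch annotation (`n_mm`) is
#'   computed from `guide` if absent.
#' @param guide a [guide_spec()]; used to annotate mismatches when needed
#'   and to identify perfect-match targets.
#' @param min_obs drop targets with fewer total observations.
#' @return an efficiency `data.table`: (`replicate`,) `umi_t`, `target`,
#'   `n_mm`, `mean_mm_dist_pam`, `n_obs`, `n_reads`, `raw_cut_fraction`,
#'   `eta`.
#' @export
compute_eta <- function(records, guide, min_obs = 1L) {
  rec <- as.data.table(records)
  if ("validated" %in% names(rec)) rec <- rec[validated == TRUE]
  if (!"n_mm" %in% names(rec)) {
    ann <- annotate_mismatches(rec$target, guide)
    rec[, `:=`(n_mm = ann$n_mm, mean_mm_dist_pam = ann$mean_mm_dist_pam)]
  }
  if (!"mean_mm_dist_pam" %in% names(rec))
    rec[, mean_mm_dist_pam := annotate_mismatches(target, guide)$mean_mm_dist_pam]
  if (!"n_reads" %in% names(rec)) rec[, n_reads := n_obs]
  rec <- rec[n_obs >= min_obs]
  byrep <- "replicate" %in% names(rec)
  grp <- if (byrep) "replicate" else character(0)
  norm <- rec[n_mm == 0L,
              .(on_obs = sum(n_obs), on_cut = sum(n_cut)),
              by = grp]
  if (nrow(norm) == 0L || any(norm$on_obs == 0L))
    stop("no perfect-match (on-target) observations; eta undefined",
         call. = FALSE)
  if (any(norm$on_cut == 0L))
    stop("on-target efficiency undefined: zero cleaved on-target observations",
         call. = FALSE)
  out <- if (byrep) merge(rec, norm, by = "replicate") else
    rec[, `:=`(on_obs = norm$on_obs, on_cut = norm$on_cut)]
  out[, raw_cut_fraction := n_cut / n_obs]
  out[, eta := raw_cut_fraction * (on_obs / on_cut)]
  keep <- intersect(c("replicate", "sample", "guide", "pam", "umi_t",
                      "target", "n_mm", "mean_mm_dist_pam", "n_obs",
                      "n_reads", "raw_cut_fraction", "eta", "p_true"),
                    names(out))
  out[, ..keep][]
}

#' Average efficiencies across replicates
#'
#' Unweighted mean of per-replicate eta per target; targets missing from
#' some replicates are averaged over the replicates where they appear, with
#' the replicate count reported.
#'
#' @param eta_table output of [compute_eta()] with a `replicate` column.
#' @return `data.table` with `umi_t`, `target`, `n_mm`,
#'   `mean_mm_dist_pam`, `eta` (mean), `n_replicates`, `n_obs`, `n_reads`
#'   (summed).
#' @export
replicate_average <- function(eta_table) {
  x <- as.data.table(eta_table)
  if (!"replicate" %in% names(x)) x[, replicate := "rep1"]
  x[, .(eta = mean(eta), n_replicates = uniqueN(replicate),
        n_obs = sum(n_obs), n_reads = sum(n_reads),
        n_mm = n_mm[1L], mean_mm_dist_pam = mean_mm_dist_pam[1L]),
    by = .(umi_t, target)][]
}

#' Reproducibility between two experiments
#'
#' Coefficient of determination (squared Pearson correlation) of eta
#' between two experiments across shared targets, optionally filtered on
#' per-target read support. On sampling-noise-limited data, R^2 rises
#' monotonically with the read filter.
#'
#' @param table_a,table_b efficiency tables sharing `umi_t` keys.
#' @param min_reads keep targets with at least this read support in both
#'   tables (uses `n_reads`, falling back to `n_obs`).
#' @return list with `r_squared`, `n_targets`, and the paired table.
#' @export
reproducibility <- function(table_a, table_b, min_reads = 0L) {
  a <- as.data.table(table_a); b <- as.data.table(table_b)
  if (!"n_reads" %in% names(a)) a[, n_reads := n_obs]
  if (!"n_reads" %in% names(b)) b[, n_reads := n_obs]
  p <- merge(a[, .(umi_t, eta_a = eta, n_reads_a = n_reads)],
             b[, .(umi_t, eta_b = eta, n_reads_b = n_reads)],
             by = "umi_t")
  p <- p[n_reads_a >= min_reads & n_reads_b >= min_reads]
  if (nrow(p) < 2L)
    stop("fewer than 2 shared targets after filtering", call. = FALSE)
  list(r_squared = cor(p$eta_a, p$eta_b)^2, n_targets = nrow(p),
       pairs = p[])
}

#' Aggregate efficiencies by mismatch structure
#'
#' Summaries over the mismatch annotation of an efficiency table:
#' mean eta by mismatch count; the position-by-base single-mismatch matrix
#' (4 x L, wild-type cells NA); the position-pair double-mismatch matrix;
#' and a pairwise epistasis summary comparing each observed double to the
#' product of its constituent single-mismatch means (exact for a
#' multiplicative truth, so planted multiplicative models give epistasis
#' near 0).
#'
#' @param eta_table efficiency table (averaged or per replicate).
#' @param guide a [guide_spec()].
#' @return list with elements `by_count` (`n_mm`, `mean_eta`, `n_targets`),
#'   `single_mm` (4 x L matrix), `single_mm_table`, `double_mm` (L x L
#'   matrix, upper triangle), `epistasis` (`pos1`, `pos2`, `eta_obs`,
#'   `eta_exp`, `epistasis`).
#' @export
aggregate_by_mismatch <- function(eta_table, guide) {
  x <- as.data.table(eta_table)
  L <- guide$length
  by_count <- x[, .(mean_eta = mean(eta), n_targets = .N), by = n_mm][order(n_mm)]

  mm1 <- x[n_mm == 1L]
  single_tab <- data.table(pos = integer(0), base = character(0),
                           mean_eta = numeric(0), n_targets = integer(0))
  single_mat <- matrix(NA_real_, 4L, L,
                       dimnames = list(DNA_BASES, as.character(seq_len(L))))
  if (nrow(mm1)) {
    d <- mismatch_table(mm1$target, guide)
    d[, eta := mm1$eta[idx]]
    single_tab <- d[, .(mean_eta = mean(eta), n_targets = .N),
                    by = .(pos, base = obs)][order(pos, base)]
    single_mat[cbind(match(single_tab$base, DNA_BASES), single_tab$pos)] <-
      single_tab$mean_eta
  }

  mm2 <- x[n_mm == 2L]
  double_mat <- matrix(NA_real_, L, L,
                       dimnames = list(as.character(seq_len(L)),
                                       as.character(seq_len(L))))
  epi <- data.table(pos1 = integer(0), pos2 = integer(0),
                    eta_obs = numeric(0), eta_exp = numeric(0),
                    epistasis = numeric(0), n_targets = integer(0))
  if (nrow(mm2)) {
    d <- mismatch_table(mm2$target, guide)
    pairs <- d[, .(pos1 = min(pos), pos2 = max(pos)), by = idx]
    pairs[, eta := mm2$eta[idx]]
    dtab <- pairs[, .(eta_obs = mean(eta), n_targets = .N),
                  by = .(pos1, pos2)][order(pos1, pos2)]
    double_mat[cbind(dtab$pos1, dtab$pos2)] <- dtab$eta_obs
    ## expected double = product of position-level single-mismatch means
    pos_mean <- if (nrow(mm1)) {
      d1 <- mismatch_table(mm1$target, guide)
      d1[, eta := mm1$eta[idx]]
      d1[, .(m = mean(eta)), by = pos]
    } else data.table(pos = integer(0), m = numeric(0))
    pm <- setNames(rep(NA_real_, L), seq_len(L))
    pm[as.character(pos_mean$pos)] <- pos_mean$m
    epi <- dtab[, .(pos1, pos2, eta_obs,
                    eta_exp = pm[as.character(pos1)] * pm[as.character(pos2)],
                    n_targets)]
    epi[, epistasis := eta_obs - eta_exp]
  }
  list(by_count = by_count, single_mm = single_mat,
       single_mm_table = single_tab, double_mm = double_mat,
       epistasis = epi)
}

#' Guide-intrinsic mismatch permissiveness (GIMP) score
#'
#' Integrates the mean normalized efficiency over mismatch counts:
#' `GIMP = sum_{N=j..k} eta_bar(N) / (k - j)` with the inclusive sum and
#' the `k - j` denominator taken literally from the defining formula
#' (`mode = "literal"`, default; a constant eta_bar = c thus gives
#' `c * (k - j + 1) / (k - j)`). `mode = "mean"` instead averages over the
#' `k - j + 1` classes. High scores indicate promiscuous guides. Because
#' eta is normalized to the on-target efficiency, GIMP is invariant to
#' uniform scaling of absolute cleavage probabilities (e.g. nuclease dose).
#'
#' @param eta_table efficiency table with `n_mm` and `eta` columns.
#' @param j,k mismatch-count bounds (defaults 1 and 4).
#' @param mode `"literal"` or `"mean"` (see above).
#' @param min_targets minimum targets required in every class of `[j, k]`.
#' @return an object of class `blt_gimp`: list with `gimp`, `j`, `k`,
#'   `mode`, and `by_count` (per-N mean eta and target counts).
#' @export
gimp_score <- function(eta_table, j = 1L, k = 4L,
                       mode = c("literal", "mean"), min_targets = 1L) {
  mode <- match.arg(mode)
  stopifnot(k > j)
  x <- as.data.table(eta_table)
  bc <- x[, .(mean_eta = mean(eta), n_targets = .N), by = n_mm][order(n_mm)]
  need <- seq.int(j, k)
  have <- bc[n_mm %in% need & n_targets >= min_targets, n_mm]
  missing <- setdiff(need, have)
  if (length(missing))
    stop("no (or too few) targets in mismatch class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  s <- sum(bc[n_mm %in% need, mean_eta])
  gimp <- if (mode == "literal") s / (k - j) else s / (k - j + 1L)
  structure(list(gimp = gimp, j = j, k = k, mode = mode,
                 by_count = bc[n_mm %in% need]),
            class = "blt_gimp")
}

#' @export
print.blt_gimp <- function(x, ...) {
  cat(sprintf("GIMP = %.4f (N = %d..%d, mode = %s)\n",
              x$gimp, x$j, x$k, x$mode))
  print(x$by_count)
  invisible(x)
}
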