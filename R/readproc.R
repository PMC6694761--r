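#' Parse and demultiplex BLT reads
#'
#' Locates the pair of barcode-flanking probe anchors to infer the stagger
#' length, extracts barcode,
#' UMI_P, junction, target (uncut reads only), PAM and UMI_T, classifies
#' each read as cut- or uncut-derived from the junction sequence context
#' (EcoRV-site remnant versus Cas9 cut-site remnant — robust to the 1-8 bp
#' stagger, unlike a read-length rule), and computes the mean Phred quality
#' over the extracted constant regions (UMI_P, PAM, UMI_T) only.
#'
#' Unassignable reads are dropped with a reason code, never an error; the
#' per-reason tally is attached as the `"drop_report"` attribute (see
#' [drop_report()]) and reads in = reads parsed + reads dropped always
#' holds.
#'
#' @param reads a FASTQ path (or vector of paths), or a table from
#'   [read_fastq()].
#' @param guide a [guide_spec()].
#' @param layout a [construct_layout()].
#' @param seqp a [sequencing_params()] describing the probe architecture.
#' @param barcode_set barcodes to demultiplex against (defaults to
#'   `seqp$barcode_set`).
#' @return a `data.table` of parsed reads: `barcode`, `umi_p`, `stagger`,
#'   `cut_status`, `target` (NA for cut reads), `pam_seq`, `umi_t`,
#'   `mean_quality`; attribute `drop_report` holds the drop tally.
#' @export
parse_and_demultiplex <- function(reads, guide, layout, seqp,
                                  barcode_set = seqp$barcode_set) {
  stopifnot(inherits(guide, "blt_guide"), inherits(layout, "blt_layout"),
            inherits(seqp, "blt_seqparams"))
  .check_read_span(guide, layout, seqp)
  if (is.character(reads))
    reads <- rbindlist(lapply(reads, read_fastq))
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  n <- nrow(reads)
  sq <- reads$seq
  ql <- reads$qual

  a1 <- seqp$anchor1; a2 <- seqp$anchor2; a3 <- seqp$anchor3
  w1 <- nchar(a1); w2 <- nchar(a2); w3 <- nchar(a3)
  bw <- seqp$barcode_width
  up <- seqp$umi_p_length
  L <- guide$length
  pamlen <- nchar(layout$pam)
  utl <- layout$umi_t_length
  jl <- nchar(layout$uncut_junction)
  co <- guide$cut_offset

  ## stagger = first offset at which BOTH barcode-flanking anchors match;
  ## requiring the pair makes a chance match in the random stagger bases
  ## (~4^-12) negligible
  stagger <- rep(NA_integer_, n)
  for (s in seq.int(seqp$stagger_range[1], seqp$stagger_range[2])) {
    hit <- is.na(stagger) &
      substr(sq, s + 1L, s + w1) == a1 &
      substr(sq, s + w1 + bw + 1L, s + w1 + bw + w2) == a2
    stagger[hit] <- s
  }
  reason <- rep(NA_character_, n)
  reason[is.na(stagger)] <- "anchor"

  st <- fifelse(is.na(stagger), 0L, stagger)
  b0 <- st + w1 + 1L
  barcode <- substr(sq, b0, b0 + bw - 1L)
  u0 <- b0 + bw + w2
  umi_p <- substr(sq, u0, u0 + up - 1L)
  anchor3_ok <- substr(sq, u0 + up, u0 + up + w3 - 1L) == a3
  reason[is.na(reason) & !anchor3_ok] <- "anchor"
  reason[is.na(reason) & !(barcode %in% barcode_set)] <- "barcode"

  ## junction classification
  j0 <- u0 + up + w3
  is_uncut <- substr(sq, j0, j0 + jl - 1L) == layout$uncut_junction
  is_cut <- !is_uncut & substr(sq, j0 + co, j0 + co + pamlen - 1L) == layout$pam
  reason[is.na(reason) & !(is_uncut | is_cut)] <- "junction"

  ## field coordinates per class
  pam0 <- fifelse(is_uncut, j0 + jl + L, j0 + co)
  ut0 <- pam0 + pamlen
  too_short <- nchar(sq) < ut0 + utl - 1L
  reason[is.na(reason) & too_short] <- "truncated"

  keep <- is.na(reason)
  out <- data.table(
    barcode = barcode[keep],
    umi_p = umi_p[keep],
    stagger = stagger[keep],
    cut_status = fifelse(is_uncut[keep], "uncut", "cut"),
    target = fifelse(is_uncut[keep],
                     substr(sq[keep], j0[keep] + jl, j0[keep] + jl + L - 1L),
                     NA_character_),
    pam_seq = substr(sq[keep], pam0[keep], pam0[keep] + pamlen - 1L),
    umi_t = substr(sq[keep], ut0[keep], ut0[keep] + utl - 1L))
  qconst <- paste0(substr(ql[keep], u0[keep], u0[keep] + up - 1L),
                   substr(ql[keep], pam0[keep], pam0[keep] + pamlen - 1L),
                   substr(ql[keep], ut0[keep], ut0[keep] + utl - 1L))
  out[, mean_quality := .mean_phred(qconst)]

  rep_tab <- c(list(input = n, parsed = sum(keep)),
               as.list(table(reason[!keep])))
  setattr(out, "drop_report", rep_tab)
  out[]
}

#' Drop-report of a parsing step
#'
#' @param x result of [parse_and_demultiplex()].
#' @return named list: reads in, reads parsed, and per-reason drop counts.
#' @export
drop_report <- function(x) attr(x, "drop_report")

#' Mean-quality read filter
#'
#' Discards reads whose mean Phred quality over the extracted constant
#' regions (UMI_P, PAM, UMI_T — not the entire read) is below the
#' threshold; a read at exactly the threshold is retained.
#'
#' @param reads parsed reads from [parse_and_demultiplex()].
#' @param q_threshold minimum mean constant-region quality (default Q20).
#' @return the retained rows; attribute `quality_report` holds pass/fail
#'   counts.
#' @export
quality_filter <- function(reads, q_threshold = 20) {
  keep <- reads$mean_quality >= q_threshold
  out <- reads[keep]
  setattr(out, "quality_report",
          list(input = length(keep), passed = sum(keep),
               failed = sum(!keep), q_threshold = q_threshold))
  out[]
}

#' Collapse reads into observations
#'
#' Deduplicates PCR copies: one observation per unique
#' (barcode, UMI_T, UMI_P, cut status, stagger length) tuple. The target
#' sequence of an uncut observation is the modal target among its
#' supporting reads; `n_reads` counts the reads collapsed into the tuple.
#' Collapsing is idempotent.
#'
#' @param reads parsed (and normally quality-filtered) reads.
#' @return an observation `data.table`: `barcode`, `umi_t`, `umi_p`,
#'   `cut_status`, `stagger`, `target`, `n_reads`.
#' @export
collapse_observations <- function(reads) {
  nr <- if ("n_reads" %in% names(reads)) reads$n_reads else rep(1L, nrow(reads))
  x <- copy(reads)[, .n_reads_in := nr]
  obs <- x[, .(
    target = if (cut_status[1L] == "uncut") {
      tt <- table(target)
      names(tt)[which.max(tt)]
    } else NA_character_,
    n_reads = sum(.n_reads_in)),
    by = .(barcode, umi_t, umi_p, cut_status, stagger)]
  setcolorder(obs, c("barcode", "umi_t", "umi_p", "cut_status", "stagger",
                     "target", "n_reads"))
  obs[]
}

#' Validate targets and build per-UMI_T records
#'
#' A UMI_T is validated when at least `min_uncut` unique uncut observations
#' support a consensus target sequence. Spike-in observations (an
#' undigested naive library sequenced alongside) count toward validation
#' and consensus but — unless `include_spikein_counts` — not toward the
#' cut-fraction counts, since their molecules never saw Cas9. Cut
#' observations are assigned the consensus sequence via UMI_T lookup.
#' UMI_Ts whose uncut observations disagree without a strict majority
#' (UMI collisions) are discarded and counted.
#'
#' @param observations observation table from [collapse_observations()]
#'   (one sample or several; the validation key is UMI_T).
#' @param min_uncut minimum unique uncut observations (default 3).
#' @param spikein optional observation table from a naive spike-in library.
#' @param guide optional [guide_spec()] for mismatch annotation.
#' @param include_spikein_counts if TRUE, spike-in uncut observations also
#'   enter `n_uncut` (and hence the cut-fraction denominator).
#' @return a target-record `data.table`: `umi_t`, `target`, `n_cut`,
#'   `n_uncut`, `n_obs`, `n_spikein`, `n_reads`, `validated` (+ mismatch
#'   columns when `guide` is given). Attribute `validation_report` counts
#'   validated / unsupported / collision UMI_Ts.
#' @export
validate_targets <- function(observations, min_uncut = 3L, spikein = NULL,
                             guide = NULL, include_spikein_counts = FALSE) {
  obs <- copy(observations)[, .src := "sample"]
  if (!is.null(spikein) && nrow(spikein))
    obs <- rbind(obs, copy(spikein)[, .src := "spikein"])

  uncut <- obs[cut_status == "uncut"]
  ## consensus = strict majority of uncut observation sequences; tie -> drop
  cons <- uncut[, {
    tt <- sort(table(target), decreasing = TRUE)
    list(target = names(tt)[1L],
         collision = length(tt) > 1L && tt[1L] == tt[2L],
         n_support = .N)
  }, by = umi_t]
  collided <- cons[collision == TRUE, umi_t]
  cons <- cons[collision == FALSE]

  cnt <- obs[!umi_t %in% collided, .(
    n_cut = sum(cut_status == "cut" & .src == "sample"),
    n_uncut = if (include_spikein_counts) sum(cut_status == "uncut")
              else sum(cut_status == "uncut" & .src == "sample"),
    n_spikein = sum(.src == "spikein"),
    n_support = sum(cut_status == "uncut"),
    n_reads = sum(n_reads)), by = umi_t]
  rec <- merge(cnt, cons[, .(umi_t, target)], by = "umi_t", all.x = TRUE)
  rec[, n_obs := n_cut + n_uncut]
  rec[, validated := !is.na(target) & n_support >= min_uncut]
  rec[, n_support := NULL]
  if (!is.null(guide)) {
    ok <- !is.na(rec$target)
    rec[, `:=`(n_mm = NA_integer_, mm = NA_character_,
               mean_mm_dist_pam = NA_real_)]
    if (any(ok)) {
      ann <- annotate_mismatches(rec$target[ok], guide)
      rec[ok, `:=`(n_mm = ann$n_mm, mm = ann$mm,
                   mean_mm_dist_pam = ann$mean_mm_dist_pam)]
    }
  }
  setcolorder(rec, c("umi_t", "target", "n_cut", "n_uncut", "n_obs",
                     "n_spikein", "n_reads", "validated"))
  setattr(rec, "validation_report",
          list(umi_t_total = uniqueN(obs$umi_t),
               validated = sum(rec$validated),
               unsupported = sum(!rec$validated),
               collisions = length(collided)))
  rec[]
}

#' Group target records across samples by guide and PAM
#'
#' Merges per-sample record tables of replicate reactions into one long
#' table keyed by (guide, pam, umi_t), preserving per-sample counts for
#' replicate-level statistics. Grouping is invariant to sample order.
#'
#' @param records named list of target-record tables (names = sample ids),
#'   or a single table with a `sample` column.
#' @param sample_info `data.frame` with columns `sample`, `guide`, `pam`
#'   and optionally `replicate` (defaults to the sample id).
#' @return long `data.table` with columns `guide`, `pam`, `replicate`,
#'   `sample` and the record columns, keyed by (guide, pam, umi_t).
#' @export
group_by_guide_pam <- function(records, sample_info) {
  si <- as.data.table(sample_info)
  stopifnot(all(c("sample", "guide", "pam") %in% names(si)))
  if (!"replicate" %in% names(si)) si[, replicate := sample]
  if (is.data.frame(records)) {
    stopifnot("sample" %in% names(records))
    long <- as.data.table(records)
  } else {
    stopifnot(is.list(records), !is.null(names(records)))
    long <- rbindlist(records, idcol = "sample", fill = TRUE)
  }
  missing <- setdiff(unique(long$sample), si$sample)
  if (length(missing))
    stop("samples without sample_info entry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- merge(long, si, by = "sample")
  setorder(out, guide, pam, umi_t, replicate, sample)
  setcolorder(out, c("guide", "pam", "replicate", "sample", "umi_t"))
  out[]
}
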