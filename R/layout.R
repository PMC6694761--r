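#' Define a guide RNA / protospacer
#'
#' A guide is described by its spacer sequence (written 5'->3' so that the
#' 3' end of the protospacer abuts the PAM), the constant PAM instance used
#' in the library construct, and the blunt-cut offset of Cas9 relative to
#' the PAM.
#'
#' Throughout the package, target positions are numbered with **position 1
#' PAM-proximal**: position 1 is the last base of the spacer string and
#' position `L` the first. Mismatch annotations, truth-model position
#' weights and encoding columns all share this convention.
#'
#' @param name identifier for the guide.
#' @param spacer protospacer-matching sequence, 19-21 nt, A/C/G/T only.
#' @param pam constant PAM sequence of the library construct (an instance of
#'   the nuclease's PAM pattern; `"TTGAAT"` fits the S. aureus NNGRRT).
#' @param cut_offset blunt-cut position, in bp 5' of the PAM. The default of
#'   3 bp is the accepted Cas9 blunt-cut geometry and fixes the length of
#'   target sequence retained on cut-derived reads.
#' @return an object of class `blt_guide`.
#' @examples
#' g <- guide_spec("demo", "GGTGAGTGAGTGTGTGCGTGT")
#' g$length
#' @export
guide_spec <- function(name, spacer, pam = "TTGAAT", cut_offset = 3L) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .check_dna(spacer, "spacer")
  .check_dna(pam, "pam")
  L <- nchar(spacer)
  if (L < 19L || L > 21L)
    stop("spacer must be 19-21 nt (got ", L, ")", call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 1L || cut_offset >= L)
    stop("cut_offset must be >= 1 and < spacer length", call. = FALSE)
  structure(
    list(name = name, spacer = spacer, pam = pam,
         cut_offset = cut_offset, length = L),
    class = "blt_guide")
}

#' @export
print.blt_guide <- function(x, ...) {
  cat(sprintf("<blt_guide> %s: %s-%s (L=%d, cut %d bp 5' of PAM)\n",
              x$name, x$spacer, x$pam, x$length, x$cut_offset))
  invisible(x)
}

#' Amplicon construct layout
#'
#' Describes the fixed architecture of a library molecule:
#' `upstream_const | target | pam | UMI_T | downstream_const`.
#' The upstream constant region must contain exactly one EcoRV site
#' (`GATATC`); EcoRV digestion of Cas9-uncut molecules exposes a blunt end
#' in the middle of that site (`GAT|ATC`), so uncut-derived reads carry a
#' fixed junction sequence (the upstream remnant 3' of the cut) followed by
#' the full target. Cas9-cut molecules instead retain only `cut_offset`
#' PAM-proximal target bases at the ligation junction.
#'
#' With the defaults (7 bp EcoRV remnant, 21 nt target, 3 bp Cas9 remnant)
#' uncut- and cut-derived inserts differ by a fixed 25 bp, matching the
#' long/short amplicon split observed on a sequencer.
#'
#' @param pam constant PAM sequence (normally taken from the guide).
#' @param upstream_const constant sequence 5' of the target; must contain
#'   exactly one EcoRV recognition site `GATATC`.
#' @param umi_t_length length of the randomized template UMI (nt). 12 nt
#'   keeps collisions rare at 5e5 templates.
#' @param downstream_const constant sequence 3' of the UMI (P7 priming side).
#' @return an object of class `blt_layout` with derived fields
#'   `uncut_junction` (upstream remnant after EcoRV digestion) and
#'   `ecorv_pos`.
#' @export
construct_layout <- function(pam,
                             upstream_const = "ACGACGCTCTTCCGATATCCAGT",
                             umi_t_length = 12L,
                             downstream_const = "AGATCGGAAGAGCACACGTC") {
  .check_dna(pam, "pam")
  .check_dna(upstream_const, "upstream_const")
  .check_dna(downstream_const, "downstream_const")
  umi_t_length <- as.integer(umi_t_length)
  stopifnot(umi_t_length >= 4L)
  hits <- gregexpr("GATATC", upstream_const, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] == -1L)
    stop("upstream_const must contain exactly one EcoRV site (GATATC)",
         call. = FALSE)
  ## EcoRV cuts blunt between GAT|ATC
  cutpos <- hits[1] + 2L
  uncut_junction <- substr(upstream_const, cutpos + 1L, nchar(upstream_const))
  structure(
    list(upstream_const = upstream_const, pam = pam,
         umi_t_length = umi_t_length, downstream_const = downstream_const,
         ecorv_pos = hits[1], uncut_junction = uncut_junction),
    class = "blt_layout")
}

#' Sequencing and probe-ligation parameters
#'
#' Parameters of the probe side of the construct and of read generation.
#' Reads are laid out, 5' to 3', as
#' `stagger | anchor1 | barcode | anchor2 | UMI_P | anchor3 | insert`,
#' where the insert is the ligated template (junction-dependent, see
#' [construct_layout()]) and the read is truncated to `read_length`.
#'
#' Base qualities are drawn from two regimes so that the mean-Q20 filter is
#' exercised: most reads draw per-base Phred scores around `q_good_mean`,
#' a `bad_read_rate` fraction around `q_bad_mean`, and bases hit by a
#' substitution error around `q_err_mean`.
#'
#' @param read_length single-end read length in bp (150 default).
#' @param mean_pcr_duplicates mean reads per ligation event (>= 1); the
#'   per-event count is 1 + Poisson(mean - 1).
#' @param error_rate per-base substitution probability.
#' @param stagger_range integer range (inclusive) of the probe stagger.
#' @param barcode_set sample barcodes (mutually distinct, equal width).
#' @param umi_p_length probe UMI length (nt).
#' @param anchor1,anchor2,anchor3 constant probe anchor sequences.
#' @param bad_read_rate fraction of reads drawn from the low-quality regime.
#' @param q_good_mean,q_good_sd,q_bad_mean,q_bad_sd,q_err_mean,q_err_sd
#'   Phred-score normal regimes (rounded, clamped to 2..40).
#' @return an object of class `blt_seqparams`.
#' @export
sequencing_params <- function(read_length = 150L,
                              mean_pcr_duplicates = 3,
                              error_rate = 0.002,
                              stagger_range = c(1L, 8L),
                              barcode_set = c("ACTGAC", "TGCAGT", "GATCCA",
                                              "CTAGTG", "AGGTCA", "TCCAGT"),
                              umi_p_length = 8L,
                              anchor1 = "TCAGCG",
                              anchor2 = "GTGACT",
                              anchor3 = "CTGAGC",
                              bad_read_rate = 0.01,
                              q_good_mean = 36, q_good_sd = 2,
                              q_bad_mean = 12, q_bad_sd = 4,
                              q_err_mean = 15, q_err_sd = 5) {
  stagger_range <- as.integer(stagger_range)
  stopifnot(length(stagger_range) == 2L,
            stagger_range[1] >= 1L, stagger_range[2] >= stagger_range[1],
            mean_pcr_duplicates >= 1, error_rate >= 0, error_rate < 1,
            bad_read_rate >= 0, bad_read_rate <= 1)
  for (b in barcode_set) .check_dna(b, "barcode")
  if (anyDuplicated(barcode_set))
    stop("barcodes must be mutually distinct", call. = FALSE)
  if (length(unique(nchar(barcode_set))) != 1L)
    stop("barcodes must have equal width", call. = FALSE)
  .check_dna(anchor1, "anchor1"); .check_dna(anchor2, "anchor2")
  .check_dna(anchor3, "anchor3")
  structure(
    list(read_length = as.integer(read_length),
         mean_pcr_duplicates = mean_pcr_duplicates,
         error_rate = error_rate,
         stagger_range = stagger_range,
         barcode_set = barcode_set,
         barcode_width = nchar(barcode_set[1]),
         umi_p_length = as.integer(umi_p_length),
         anchor1 = anchor1, anchor2 = anchor2, anchor3 = anchor3,
         bad_read_rate = bad_read_rate,
         q_good_mean = q_good_mean, q_good_sd = q_good_sd,
         q_bad_mean = q_bad_mean, q_bad_sd = q_bad_sd,
         q_err_mean = q_err_mean, q_err_sd = q_err_sd),
    class = "blt_seqparams")
}

#' Template library parameters
#'
#' @param per_base_mismatch_rate probability that a given target base is
#'   replaced by a uniformly chosen non-wild-type base (10% programmed
#'   degeneracy by default).
#' @param n_templates number of unique bottlenecked template molecules
#'   (default 500,000; scale down for quick runs).
#' @param umi_t_length template UMI length (nt).
#' @return an object of class `blt_libparams`.
#' @export
library_params <- function(per_base_mismatch_rate = 0.10,
                           n_templates = 500000L,
                           umi_t_length = 12L) {
  stopifnot(per_base_mismatch_rate >= 0, per_base_mismatch_rate < 1,
            n_templates >= 1)
  structure(
    list(per_base_mismatch_rate = per_base_mismatch_rate,
         n_templates = as.integer(n_templates),
         umi_t_length = as.integer(umi_t_length)),
    class = "blt_libparams")
}

## length of probe prefix for a given stagger
.probe_prefix_len <- function(seqp, stagger) {
  stagger + nchar(seqp$anchor1) + seqp$barcode_width +
    nchar(seqp$anchor2) + seqp$umi_p_length + nchar(seqp$anchor3)
}

## check that every field through UMI_T fits in the read for the worst-case
## (longest) stagger and the uncut junction
.check_read_span <- function(guide, layout, seqp) {
  need <- .probe_prefix_len(seqp, seqp$stagger_range[2]) +
    nchar(layout$uncut_junction) + guide$length + nchar(layout$pam) +
    layout$umi_t_length
  if (need > seqp$read_length)
    stop("read_length too short to reach UMI_T (need ", need, " bp, have ",
         seqp$read_length, ")", call. = FALSE)
  invisible(need)
}
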