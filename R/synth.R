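#' Generate a degenerate template library
#'
#' Draws `n_templates` unique library members for a guide. Independently at
#' each target position, the wild-type base is replaced with probability
#' `per_base_mismatch_rate` by a uniformly chosen non-wild-type base; each
#' template carries a random UMI_T (collisions possible and handled
#' downstream).
#'
#' @param guide a [guide_spec()].
#' @param params a [library_params()].
#' @param seed optional integer seed for reproducibility.
#' @return a `data.table` with one row per template: `umi_t`, `target`,
#'   `n_mm`, `mm`, `mean_mm_dist_pam`.
#' @export
generate_template_library <- function(guide, params = library_params(),
                                      seed = NULL) {
  stopifnot(inherits(guide, "blt_guide"), inherits(params, "blt_libparams"))
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_templates
  L <- guide$length
  sp <- strsplit(guide$spacer, "", fixed = TRUE)[[1]]
  tm <- matrix(sp, nrow = n, ncol = L, byrow = TRUE)
  mask <- matrix(runif(n * L) < params$per_base_mismatch_rate, n, L)
  k <- sum(mask)
  if (k > 0) {
    ## uniformly one of the three non-WT bases: offset 1..3 in base order
    wt_idx <- match(tm[mask], DNA_BASES)
    alt <- (wt_idx - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L
    tm[mask] <- DNA_BASES[alt]
  }
  targets <- do.call(paste0, as.data.frame(tm, stringsAsFactors = FALSE))
  out <- annotate_mismatches(targets, guide)
  out[, umi_t := .random_dna(n, params$umi_t_length)]
  setcolorder(out, c("umi_t", "target", "n_mm", "mm", "mean_mm_dist_pam"))
  out[]
}

#' Simulate the Cas9 cutting reaction
#'
#' Expands each template into physical molecule copies and marks each
#' molecule as Cas9-cleaved by an independent Bernoulli draw with the
#' truth-model probability of its target sequence. The cut is blunt,
#' `cut_offset` bp 5' of the PAM.
#'
#' The bottlenecked library exists as many amplified copies of each unique
#' template; `copies` controls that multiplicity (`copies = 1` with
#' `copies_dist = "fixed"` gives one molecule per template, the convention
#' used by the simple worked examples).
#'
#' @param templates template table from [generate_template_library()].
#' @param truth a [cleavage_truth()] model for the same guide.
#' @param copies mean number of molecule copies per template.
#' @param copies_dist `"fixed"` (exactly `round(copies)` each) or
#'   `"poisson"` (Poisson-distributed; zero-copy templates drop out).
#' @param seed optional integer seed.
#' @return a molecule-level `data.table`: `umi_t`, `target`, `cut`
#'   (logical), `p_true` (planted cleavage probability).
#' @export
simulate_cut_reaction <- function(templates, truth, copies = 1,
                                  copies_dist = c("fixed", "poisson"),
                                  seed = NULL) {
  stopifnot(inherits(truth, "blt_truth"))
  copies_dist <- match.arg(copies_dist)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(templates)
  nc <- if (copies_dist == "fixed") rep(as.integer(round(copies)), n)
        else rpois(n, copies)
  p <- truth_cut_prob(truth, templates$target)
  mol <- data.table(umi_t = rep(templates$umi_t, nc),
                    target = rep(templates$target, nc),
                    p_true = rep(p, nc))
  mol[, cut := runif(.N) < p_true]
  mol[]
}

#' Simulate a Cas9 pull-down experiment
#'
#' Models the bead pull-down used to estimate cleavage-given-binding: each
#' molecule is Cas9-bound with its planted binding probability and, if
#' bound, cleaved with its planted cleavage-given-binding probability
#' (single-encounter model: unbound molecules are never cleaved, so the
#' whole-reaction cut probability is `binding * pcut`).
#'
#' @param templates template table from [generate_template_library()].
#' @param truth a [cleavage_truth()] model with `binding` and `pcut`
#'   channels.
#' @inheritParams simulate_cut_reaction
#' @return `list(whole = <all molecules>, bound = <Cas9-bound subset>)`;
#'   molecule tables carry `umi_t`, `target`, `bound`, `cut`, and the
#'   planted `p_bind`/`p_cut_true` probabilities.
#' @export
simulate_pulldown <- function(templates, truth, copies = 1,
                              copies_dist = c("fixed", "poisson"),
                              seed = NULL) {
  stopifnot(inherits(truth, "blt_truth"))
  if (is.null(truth$binding) || is.null(truth$pcut))
    stop("truth model must define binding and pcut channels", call. = FALSE)
  copies_dist <- match.arg(copies_dist)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(templates)
  nc <- if (copies_dist == "fixed") rep(as.integer(round(copies)), n)
        else rpois(n, copies)
  pb <- truth_binding_prob(truth, templates$target)
  pc <- truth_pcut_prob(truth, templates$target)
  mol <- data.table(umi_t = rep(templates$umi_t, nc),
                    target = rep(templates$target, nc),
                    p_bind = rep(pb, nc), p_cut_true = rep(pc, nc))
  mol[, bound := runif(.N) < p_bind]
  mol[, cut := bound & (runif(.N) < p_cut_true)]
  list(whole = mol[], bound = mol[bound == TRUE][])
}

#' Tabulate molecules into per-template target records
#'
#' Exact ground-truth tabulation of a molecule table into the same shape
#' that the read-processing pipeline produces: per UMI_T cut/uncut counts
#' with the standard uncut-support validation rule. Used as the oracle for
#' pipeline-equivalence tests and as a fast path for statistical
#' experiments that do not need FASTQ round-tripping.
#'
#' @param molecules molecule table from [simulate_cut_reaction()] (or one
#'   element of [simulate_pulldown()]).
#' @param guide optional [guide_spec()]; if given, mismatch annotations are
#'   added.
#' @param min_uncut validation threshold on uncut molecule support.
#' @return a target-record `data.table`: `umi_t`, `target`, `n_cut`,
#'   `n_uncut`, `n_obs`, `validated` (+ mismatch columns when `guide` is
#'   given).
#' @export
tabulate_records <- function(molecules, guide = NULL, min_uncut = 3L) {
  rec <- molecules[, .(target = target[1L],
                       n_cut = sum(cut), n_uncut = sum(!cut)),
                   by = umi_t]
  rec[, n_obs := n_cut + n_uncut]
  rec[, validated := n_uncut >= min_uncut]
  if (!is.null(guide)) {
    ann <- annotate_mismatches(rec$target, guide)
    rec[, `:=`(n_mm = ann$n_mm, mm = ann$mm,
               mean_mm_dist_pam = ann$mean_mm_dist_pam)]
  }
  rec[]
}

#' One-call simulation of target records
#'
#' Convenience wrapper: generate a template library, run the cutting
#' reaction and tabulate molecule counts, skipping sequencing. Useful for
#' parameter-recovery experiments at scale.
#'
#' @inheritParams generate_template_library
#' @inheritParams simulate_cut_reaction
#' @inheritParams tabulate_records
#' @return a target-record `data.table` annotated with the planted per
#'   target cleavage probability (`p_true`).
#' @export
simulate_target_records <- function(guide, truth, params = library_params(),
                                    copies = 100, copies_dist = "poisson",
                                    min_uncut = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- generate_template_library(guide, params)
  mol <- simulate_cut_reaction(tpl, truth, copies = copies,
                               copies_dist = copies_dist)
  rec <- tabulate_records(mol, guide = guide, min_uncut = min_uncut)
  ptab <- unique(mol[, .(umi_t, p_true)], by = "umi_t")
  rec[ptab, p_true := i.p_true, on = "umi_t"]
  rec[]
}

## ---- read construction ----

## template-side insert of a molecule, as ligated to the probe
.template_insert <- function(cut, target, umi_t, guide, layout) {
  L <- guide$length
  remnant <- substr(target, L - guide$cut_offset + 1L, L)
  ifelse(cut,
         paste0(remnant, layout$pam, umi_t, layout$downstream_const),
         paste0(layout$uncut_junction, target, layout$pam, umi_t,
                layout$downstream_const))
}

#' Simulate probe ligation, PCR and sequencing
#'
#' Takes a molecule table through ligation (one probe per molecule: random
#' stagger and UMI_P), PCR duplication (1 + Poisson duplicates per ligation
#' event), per-base substitution errors, quality-score assignment and FASTQ
#' output. Uncut (EcoRV-digested) molecules yield reads carrying the fixed
#' EcoRV junction remnant plus the full target; Cas9-cut molecules yield
#' reads carrying only the `cut_offset` PAM-proximal target bases.
#'
#' @param molecules molecule table (needs `umi_t`, `target`, `cut`).
#' @param guide a [guide_spec()].
#' @param layout a [construct_layout()].
#' @param seqp a [sequencing_params()].
#' @param barcode sample barcode for all reads (must be in
#'   `seqp$barcode_set`).
#' @param path output FASTQ path (plain text or `.gz`).
#' @param seed optional integer seed; a fixed seed gives byte-identical
#'   FASTQ output.
#' @return (invisibly) the ligation event table — one row per molecule with
#'   `umi_t`, `umi_p`, `stagger`, `cut_status`, `barcode`, `n_reads` — the
#'   ground truth against which collapsed observations can be compared.
#' @export
simulate_ligation_sequencing <- function(molecules, guide, layout, seqp,
                                         barcode, path, seed = NULL) {
  stopifnot(inherits(guide, "blt_guide"), inherits(layout, "blt_layout"),
            inherits(seqp, "blt_seqparams"))
  if (!barcode %in% seqp$barcode_set)
    stop("barcode not in seqp$barcode_set", call. = FALSE)
  .check_read_span(guide, layout, seqp)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(molecules)
  sr <- seqp$stagger_range
  events <- data.table(
    umi_t = molecules$umi_t,
    umi_p = .random_dna(n, seqp$umi_p_length),
    stagger = sample(seq.int(sr[1], sr[2]), n, replace = TRUE),
    cut_status = ifelse(molecules$cut, "cut", "uncut"),
    barcode = barcode)
  events[, n_reads := 1L + rpois(n, seqp$mean_pcr_duplicates - 1)]

  insert <- .template_insert(molecules$cut, molecules$target,
                             molecules$umi_t, guide, layout)
  stagger_seq <- vapply(events$stagger, function(s)
    paste(sample(DNA_BASES, s, replace = TRUE), collapse = ""), "")
  full <- paste0(stagger_seq, seqp$anchor1, barcode, seqp$anchor2,
                 events$umi_p, seqp$anchor3, insert)
  full <- substr(full, 1L, seqp$read_length)

  ## expand to PCR duplicates
  ridx <- rep.int(seq_len(n), events$n_reads)
  reads <- full[ridx]
  lens <- nchar(reads)
  nr <- length(reads)

  ## substitution errors
  err_pos_list <- vector("list", nr)
  if (seqp$error_rate > 0) {
    nerr <- rbinom(nr, lens, seqp$error_rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(lens[i], nerr[i])
      ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      shift <- sample.int(3L, nerr[i], replace = TRUE)
      ch[pos] <- DNA_BASES[(match(ch[pos], DNA_BASES) - 1L + shift) %% 4L + 1L]
      reads[i] <- paste(ch, collapse = "")
      err_pos_list[[i]] <- pos
    }
  }

  ## qualities: good / bad read regimes, error bases degraded
  bad <- runif(nr) < seqp$bad_read_rate
  total <- sum(lens)
  qmean <- ifelse(bad, seqp$q_bad_mean, seqp$q_good_mean)[rep.int(seq_len(nr), lens)]
  qsd <- ifelse(bad, seqp$q_bad_sd, seqp$q_good_sd)[rep.int(seq_len(nr), lens)]
  q <- pmin(pmax(round(rnorm(total, qmean, qsd)), 2L), 40L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  quals <- character(nr)
  for (i in seq_len(nr)) {
    qi <- q[starts[i]:ends[i]]
    ep <- err_pos_list[[i]]
    if (!is.null(ep))
      qi[ep] <- pmin(pmax(round(rnorm(length(ep), seqp$q_err_mean,
                                      seqp$q_err_sd)), 2L), 40L)
    quals[i] <- intToUtf8(qi + 33L)
  }

  ids <- sprintf("M%d_D%d", ridx, sequence(events$n_reads))
  write_fastq(data.table(id = ids, seq = reads, qual = quals), path)
  invisible(events[])
}

## ---- truth-table and FASTQ I/O ----

#' Persist / load per-template ground truth
#'
#' `write_truth_table()` writes a TSV of per-UMI_T ground truth (target
#' sequence, mismatch annotation, planted probabilities and any molecule
#' counts present); `read_truth_table()` reads it back.
#'
#' @param truth_table a `data.table` (e.g. from [tabulate_records()] or
#'   [simulate_target_records()]).
#' @param path TSV path.
#' @return the file path (write) / the table (read).
#' @export
write_truth_table <- function(truth_table, path) {
  fwrite(truth_table, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  fread(path, sep = "\t")
}

#' FASTQ input/output
#'
#' Thin wrappers around Biostrings' quality-aware FASTQ reader/writer,
#' exchanging a plain `data.table` with columns `id`, `seq`, `qual`
#' (Phred+33).
#'
#' @param x table with columns `id`, `seq`, `qual`.
#' @param path FASTQ file path (`.gz` supported).
#' @return `read_fastq()` returns the `data.table`; `write_fastq()` the
#'   path, invisibly.
#' @export
write_fastq <- function(x, path) {
  dna <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  ## QualityScaledDNAStringSet warns about dropping (empty) mcols
  qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(x$qual)))
  Biostrings::writeQualityScaledXStringSet(
    qs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ## the reader warns about dropping (empty) metadata columns
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.table(id = names(qs),
             seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)))
}
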