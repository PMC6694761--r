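#' Enumerate candidate genomic off-target sites
#'
#' Scans both strands of a genome for positions whose adjacent PAM matches
#' an IUPAC pattern and whose protospacer lies within a mismatch budget of
#' the guide's spacer. PAM-matching is a hard constraint and PAM bases are
#' **not** counted against the budget; the budget applies to the
#' protospacer only. Reverse-strand sites are reported in protospacer
#' orientation. Windows containing non-ACGT genome bases are skipped and
#' counted. Palindromic/overlapping double hits are deduplicated by
#' (sequence, start, strand).
#'
#' @param genome FASTA path or a named `Biostrings::DNAStringSet` /
#'   character vector of sequences.
#' @param guide a [guide_spec()].
#' @param max_mismatches protospacer mismatch budget (default 6).
#' @param pam_pattern IUPAC PAM pattern (default `"NNGRRT"`, S. aureus
#'   Cas9).
#' @return a BED-like `data.table` (0-based half-open coordinates spanning
#'   the protospacer): `chrom`, `start`, `end`, `strand`, `protospacer`,
#'   `pam`, `n_mismatches`; attribute `n_skipped` counts ambiguous-base
#'   windows.
#' @export
enumerate_sites <- function(genome, guide, max_mismatches = 6L,
                            pam_pattern = "NNGRRT") {
  stopifnot(inherits(guide, "blt_guide"))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named", call. = FALSE)
  names(genome) <- sub("\\s.*$", "", names(genome))
  L <- guide$length
  sp <- strsplit(guide$spacer, "", fixed = TRUE)[[1]]
  pam_pat <- Biostrings::DNAString(pam_pattern)
  plen <- nchar(pam_pattern)
  n_skipped <- 0L

  scan_strand <- function(subject, chrom, seqlen, strand) {
    if (length(subject) < L + plen) return(NULL)
    ## ambiguities in the pattern are wildcards; the subject is literal
    hits <- Biostrings::matchPattern(pam_pat, subject, fixed = "subject")
    pstarts <- Biostrings::start(hits)
    pstarts <- pstarts[pstarts > L]
    if (!length(pstarts)) return(NULL)
    proto <- as.character(Biostrings::extractAt(
      subject, IRanges::IRanges(pstarts - L, width = L)))
    pams <- as.character(Biostrings::extractAt(
      subject, IRanges::IRanges(pstarts, width = plen)))
    ok <- !grepl("[^ACGT]", proto)
    n_skipped <<- n_skipped + sum(!ok)
    proto <- proto[ok]; pams <- pams[ok]; pstarts <- pstarts[ok]
    if (!length(pstarts)) return(NULL)
    cm <- .char_matrix(proto, L)
    nmm <- rowSums(cm != matrix(sp, nrow(cm), L, byrow = TRUE))
    sel <- nmm <= max_mismatches
    if (!any(sel)) return(NULL)
    s1 <- pstarts[sel] - L                   # 1-based protospacer start
    if (strand == "+") {
      start0 <- s1 - 1L
    } else {
      ## position i on the reverse complement maps to seqlen - i + 1
      start0 <- seqlen - (s1 + L - 1L)
    }
    data.table(chrom = chrom, start = start0, end = start0 + L,
               strand = strand, protospacer = proto[sel], pam = pams[sel],
               n_mismatches = as.integer(nmm[sel]))
  }

  out <- vector("list", 2L * length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    seqlen <- length(genome[[i]])
    out[[2L * i - 1L]] <- scan_strand(genome[[i]], chrom, seqlen, "+")
    out[[2L * i]] <- scan_strand(
      Biostrings::reverseComplement(genome[[i]]), chrom, seqlen, "-")
  }
  sites <- rbindlist(out)
  if (nrow(sites)) {
    sites <- unique(sites, by = c("chrom", "start", "strand"))
    setorder(sites, chrom, start, strand)
  } else {
    sites <- data.table(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        protospacer = character(0), pam = character(0),
                        n_mismatches = integer(0))
  }
  setattr(sites, "n_skipped", n_skipped)
  sites[]
}

#' Score and rank enumerated sites
#'
#' Scores each site's protospacer with a guide-specific model and ranks
#' all sites by predicted efficiency. Ties are broken deterministically by
#' (score desc, chrom, start, strand). `percentile` is the rank percentile
#' among all enumerated sites (the top site has percentile 100; a single
#' site scores 100).
#'
#' @param sites site table from [enumerate_sites()].
#' @param model a [train_guide_model()] fit for the same guide.
#' @param guide the [guide_spec()] used for encoding.
#' @return the site table with `score`, `rank` (1 = best) and `percentile`
#'   columns, ordered best-first.
#' @export
score_and_rank <- function(sites, model, guide) {
  x <- copy(as.data.table(sites))
  if (!nrow(x)) {
    x[, `:=`(score = numeric(0), rank = integer(0), percentile = numeric(0))]
    return(x[])
  }
  x[, score := predict_eta(model, protospacer, guide)]
  setorder(x, -score, chrom, start, strand)
  n <- nrow(x)
  x[, rank := seq_len(n)]
  x[, percentile := 100 * (n - rank + 1) / n]
  x[]
}

#' Extract the top fraction of a ranked site table
#'
#' @param ranked output of [score_and_rank()].
#' @param top_percent percentage of sites to keep (by rank).
#' @return the top `ceiling(n * top_percent / 100)` rows.
#' @export
top_sites <- function(ranked, top_percent = 5) {
  n <- nrow(ranked)
  head(ranked[order(rank)], ceiling(n * top_percent / 100))
}

#' Compare top-ranked sites across genomes
#'
#' Intersects the top fractions of two rankings made with the same model,
#' keyed by protospacer sequence (coordinate systems of different genomes
#' are not comparable; sequence identity is).
#'
#' @param ranked_a,ranked_b ranked site tables from [score_and_rank()].
#' @param top_percent top fraction (percent) taken from each ranking.
#' @return list with `n_top_a`, `n_top_b`, `n_common` (unique protospacer
#'   sequences in both top sets), `common` (the shared sequences),
#'   `only_a`, `only_b`.
#' @export
compare_genomes <- function(ranked_a, ranked_b, top_percent = 5) {
  ta <- unique(top_sites(ranked_a, top_percent)$protospacer)
  tb <- unique(top_sites(ranked_b, top_percent)$protospacer)
  list(n_top_a = length(ta), n_top_b = length(tb),
       n_common = length(intersect(ta, tb)),
       common = intersect(ta, tb),
       only_a = setdiff(ta, tb), only_b = setdiff(tb, ta))
}
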