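library(data.table)

## shared small fixtures -------------------------------------------------

test_guide <- function(name = "tg", spacer = "GGTGAGTGAGTGTGTGCGTGT",
                       pam = "TTGAAT", cut_offset = 3L) {
  guide_spec(name, spacer, pam, cut_offset)
}

test_layout <- function(guide = test_guide()) construct_layout(pam = guide$pam)

## error-free, duplicate-free sequencing by default: most oracle tests
## want exact reconstruction
test_seqp <- function(error_rate = 0, mean_pcr_duplicates = 1,
                      bad_read_rate = 0, ...) {
  sequencing_params(error_rate = error_rate,
                    mean_pcr_duplicates = mean_pcr_duplicates,
                    bad_read_rate = bad_read_rate, ...)
}

flat_truth <- function(guide, p) {
  cleavage_truth(guide, on_target_prob = p,
                 position_weights = rep(1, guide$length))
}

## independent read-assembly oracle ---------------------------------------
## Re-derives the expected read from first principles: EcoRV cuts GAT|ATC,
## Cas9 cuts cut_offset bp 5' of the PAM, probe fields in fixed order.
oracle_read_suffix <- function(cut, target, umi_t, umi_p, barcode,
                               guide, layout, seqp) {
  ec <- regexpr("GATATC", layout$upstream_const, fixed = TRUE)
  junction <- substring(layout$upstream_const, ec + 3L)
  L <- nchar(guide$spacer)
  insert <- if (cut) {
    paste0(substring(target, L - guide$cut_offset + 1L), layout$pam,
           umi_t, layout$downstream_const)
  } else {
    paste0(junction, target, layout$pam, umi_t, layout$downstream_const)
  }
  paste0(seqp$anchor1, barcode, seqp$anchor2, umi_p, seqp$anchor3, insert)
}

## independent brute-force genome scanner ---------------------------------
iupac_regex <- function(pat) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste0("^", paste(map[strsplit(pat, "")[[1]]], collapse = ""), "$")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

brute_force_scan <- function(seqs, guide, budget, pam_pattern = "NNGRRT") {
  L <- nchar(guide$spacer)
  plen <- nchar(pam_pattern)
  rx <- iupac_regex(pam_pattern)
  out <- list()
  for (chrom in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[chrom]] else revcomp_chr(seqs[[chrom]])
      len <- nchar(s)
      if (len < L + plen) next
      for (i in seq_len(len - L - plen + 1L)) {
        proto <- substr(s, i, i + L - 1L)
        pam <- substr(s, i + L, i + L + plen - 1L)
        if (grepl("[^ACGT]", proto) || !grepl(rx, pam)) next
        d <- hamming(proto, guide$spacer)
        if (d > budget) next
        start0 <- if (strand == "+") i - 1L else len - (i + L - 1L)
        out[[length(out) + 1L]] <- data.table(
          chrom = chrom, start = start0, end = start0 + L, strand = strand,
          protospacer = proto, pam = pam, n_mismatches = d)
      }
    }
  }
  if (!length(out))
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      n_mismatches = integer(0)))
  setorder(unique(rbindlist(out), by = c("chrom", "start", "strand")),
           chrom, start, strand)[]
}

random_genome <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## quick record-level replicate simulation sharing one template library
sim_replicate_records <- function(templates, guide, truth, copies, seed) {
  mol <- simulate_cut_reaction(templates, truth, copies = copies,
                               copies_dist = "poisson", seed = seed)
  tabulate_records(mol, guide = guide)
}
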