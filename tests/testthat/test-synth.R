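test_that("degenerate library statistics follow the per-base mismatch model", {
  g <- test_guide()
  L <- g$length

  ## rate 0: every template is wild type
  tpl0 <- generate_template_library(g, library_params(0, 500L), seed = 1)
  expect_true(all(tpl0$target == g$spacer))
  expect_true(all(tpl0$n_mm == 0L))

  ## rate 0.1, n = 1e5: binomial closed-form oracle
  rate <- 0.10
  n <- 100000L
  tpl <- generate_template_library(g, library_params(rate, n), seed = 42)
  mu <- L * rate                                  # 2.1
  se_mean <- sqrt(L * rate * (1 - rate) / n)
  expect_lt(abs(mean(tpl$n_mm) - mu), 3 * se_mean)

  p0 <- (1 - rate)^L                              # ~0.1094
  se_p0 <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(tpl$n_mm == 0L) - p0), 3 * se_p0)

  ## per-position mismatch frequency within 3 SE at every position
  mm <- mismatch_table(tpl$target, g)
  pos_freq <- mm[, .N, by = pos][order(pos)]
  expect_equal(nrow(pos_freq), L)
  se_pos <- sqrt(rate * (1 - rate) / n)
  expect_true(all(abs(pos_freq$N / n - rate) < 3 * se_pos))

  ## mismatched bases are uniform over the three non-WT bases
  expect_true(all(mm$obs != mm$wt))

  ## histogram matches Binomial(L, rate): chi-square GOF at alpha = 0.01
  obs <- tabulate(tpl$n_mm + 1L, nbins = L + 1L)
  p <- dbinom(0:L, L, rate)
  ## pool the sparse tail so every class has expected count >= 5
  k <- which(cumsum(rev(p * n)) >= 5)[1]
  keep <- seq_len(L + 1L - k)
  obs_p <- c(obs[keep], sum(obs[-keep]))
  exp_p <- c(p[keep], 1 - sum(p[keep]))
  gof <- stats::chisq.test(obs_p, p = exp_p)
  expect_gt(gof$p.value, 0.01)
})

test_that("cutting reaction marks molecules by the planted probability", {
  g <- test_guide()
  tpl <- generate_template_library(g, library_params(0.1, 2000L), seed = 2)

  all_cut <- simulate_cut_reaction(tpl, flat_truth(g, 1), seed = 3)
  expect_true(all(all_cut$cut))
  none_cut <- simulate_cut_reaction(tpl, flat_truth(g, 0), seed = 3)
  expect_false(any(none_cut$cut))

  tpl2 <- generate_template_library(g, library_params(0.1, 10000L), seed = 4)
  half <- simulate_cut_reaction(tpl2, flat_truth(g, 0.5), seed = 5)
  expect_lt(abs(sum(half$cut) - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("error-free reads are reconstructable from molecule and layout", {
  g <- test_guide(); lay <- test_layout(g); sp <- test_seqp()
  tpl <- generate_template_library(g, library_params(0.1, 300L), seed = 6)
  mol <- simulate_cut_reaction(tpl, flat_truth(g, 0.5), seed = 7)
  fq <- withr::local_tempfile(fileext = ".fastq")
  ev <- simulate_ligation_sequencing(mol, g, lay, sp, barcode = "ACTGAC",
                                     path = fq, seed = 8)
  reads <- read_fastq(fq)

  ## duplicates = 1, error_rate = 0: one read per molecule
  expect_equal(nrow(reads), nrow(mol))
  expect_true(all(ev$n_reads == 1L))

  ## every read equals the independent string assembly after its stagger
  for (i in seq_len(nrow(mol))) {
    expected <- oracle_read_suffix(mol$cut[i], mol$target[i], mol$umi_t[i],
                                   ev$umi_p[i], "ACTGAC", g, lay, sp)
    expected <- substr(expected, 1L, sp$read_length - ev$stagger[i])
    expect_identical(substring(reads$seq[i], ev$stagger[i] + 1L), expected)
  }

  ## cut reads carry exactly cut_offset target bases 5' of the PAM;
  ## uncut reads carry the full target between junction and PAM
  icut <- which(mol$cut)[1]
  pam_at <- regexpr(lay$pam, reads$seq[icut], fixed = TRUE)
  remnant <- substr(reads$seq[icut], pam_at - g$cut_offset, pam_at - 1L)
  expect_identical(remnant,
                   substring(mol$target[icut], g$length - g$cut_offset + 1L))
  iun <- which(!mol$cut)[1]
  expect_true(grepl(paste0(lay$uncut_junction, mol$target[iun], lay$pam),
                    reads$seq[iun], fixed = TRUE))
})

test_that("fixed seed gives byte-identical FASTQ output", {
  g <- test_guide(); lay <- test_layout(g)
  sp <- sequencing_params(error_rate = 0.002, mean_pcr_duplicates = 2)
  tpl <- generate_template_library(g, library_params(0.1, 100L), seed = 9)
  mol <- simulate_cut_reaction(tpl, flat_truth(g, 0.5), seed = 10)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_ligation_sequencing(mol, g, lay, sp, "ACTGAC", f1, seed = 11)
  simulate_ligation_sequencing(mol, g, lay, sp, "ACTGAC", f2, seed = 11)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("layouts whose UMI_T falls outside the read are rejected", {
  g <- test_guide(); lay <- test_layout(g)
  sp <- test_seqp(read_length = 60L)
  tpl <- generate_template_library(g, library_params(0.1, 5L), seed = 1)
  mol <- simulate_cut_reaction(tpl, flat_truth(g, 0.5), seed = 1)
  expect_error(
    simulate_ligation_sequencing(mol, g, lay, sp, "ACTGAC",
                                 tempfile(fileext = ".fastq")),
    "read_length too short")
})

test_that("pull-down separates binding from cleavage-given-binding", {
  g <- test_guide()
  tpl <- generate_template_library(g, library_params(0.1, 100000L), seed = 12)
  mk <- function(b, p) cleavage_truth(
    g, binding = list(on = b, position_weights = rep(1, g$length)),
    pcut = list(on = p, position_weights = rep(1, g$length)))

  full <- simulate_pulldown(tpl, mk(1, 1), seed = 13)
  expect_equal(nrow(full$bound), nrow(full$whole))
  expect_true(all(full$bound$cut))

  pd <- simulate_pulldown(tpl, mk(0.5, 0.8), seed = 14)
  nb <- nrow(pd$bound)
  expect_lt(abs(mean(pd$bound$cut) - 0.8), 3 * sqrt(0.8 * 0.2 / nb))
  ## unbound molecules are never cleaved (single-encounter model)
  expect_false(any(pd$whole[bound == FALSE, cut]))

  none <- simulate_pulldown(tpl, mk(0.5, 0), seed = 15)
  expect_false(any(none$bound$cut))
})

test_that("truth tables round-trip through TSV", {
  g <- test_guide()
  rec <- simulate_target_records(g, flat_truth(g, 0.6),
                                 library_params(0.1, 50L), copies = 10,
                                 copies_dist = "fixed", seed = 16)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth_table(rec, f)
  back <- read_truth_table(f)
  expect_equal(nrow(back), 50L)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})
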