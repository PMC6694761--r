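## one shared error-free simulated sample for several parsing tests
.mk_sample <- function(n_templates = 200L, copies = 5L, seed = 20) {
  g <- test_guide(); lay <- test_layout(g); sp <- test_seqp()
  tpl <- generate_template_library(g, library_params(0.1, n_templates),
                                   seed = seed)
  mol <- simulate_cut_reaction(tpl, cleavage_truth(g, 0.85),
                               copies = copies, copies_dist = "fixed",
                               seed = seed + 1)
  fq <- tempfile(fileext = ".fastq")
  ev <- simulate_ligation_sequencing(mol, g, lay, sp, "ACTGAC", fq,
                                     seed = seed + 2)
  list(g = g, lay = lay, sp = sp, tpl = tpl, mol = mol, fq = fq, ev = ev)
}

test_that("error-free reads parse completely and match the ligation truth", {
  s <- .mk_sample()
  parsed <- parse_and_demultiplex(s$fq, s$g, s$lay, s$sp)
  rep <- drop_report(parsed)
  expect_equal(rep$parsed, rep$input)
  expect_equal(nrow(parsed), nrow(s$mol))

  ## reads come back in molecule order here (1 duplicate each): field-level
  ## equality with the ligation event table
  expect_identical(parsed$umi_t, s$ev$umi_t)
  expect_identical(parsed$umi_p, s$ev$umi_p)
  expect_identical(parsed$stagger, s$ev$stagger)
  expect_identical(parsed$cut_status, s$ev$cut_status)
  expect_identical(parsed$target[parsed$cut_status == "uncut"],
                   s$mol$target[!s$mol$cut])
  expect_true(all(is.na(parsed$target[parsed$cut_status == "cut"])))
  expect_true(all(parsed$pam_seq == s$g$pam))
})

test_that("unassignable reads are dropped with reason codes, conserving totals", {
  s <- .mk_sample(n_templates = 40L, copies = 1L, seed = 30)
  reads <- read_fastq(s$fq)
  ## a read with a barcode outside the set, and pure garbage
  foreign <- copy(reads[1])
  foreign[, seq := sub("ACTGAC", "AAAAAA", seq, fixed = TRUE)]
  garbage <- data.table(id = "junk", seq = strrep("A", 150),
                        qual = strrep("I", 150))
  all_reads <- rbind(reads, foreign, garbage)
  parsed <- parse_and_demultiplex(all_reads, s$g, s$lay, s$sp)
  rep <- drop_report(parsed)
  expect_equal(rep$input, nrow(all_reads))
  expect_equal(rep$barcode, 1L)
  expect_equal(rep$anchor, 1L)
  expect_equal(rep$parsed + rep$barcode + rep$anchor, rep$input)
})

test_that("quality filter uses the mean over constant regions only", {
  g <- test_guide(); lay <- test_layout(g); sp <- test_seqp()
  umi_t <- strrep("A", lay$umi_t_length)
  umi_p <- strrep("C", sp$umi_p_length)
  suffix <- oracle_read_suffix(FALSE, g$spacer, umi_t, umi_p, "ACTGAC",
                               g, lay, sp)
  seqstr <- substr(paste0("T", suffix), 1, sp$read_length)  # stagger 1
  n <- nchar(seqstr)

  ## constant regions = UMI_P, PAM, UMI_T; locate them by layout arithmetic
  probe_prefix <- 1 + nchar(sp$anchor1) + 6 + nchar(sp$anchor2)
  upos <- probe_prefix + seq_len(sp$umi_p_length)
  j0 <- probe_prefix + sp$umi_p_length + nchar(sp$anchor3)
  pampos <- j0 + nchar(lay$uncut_junction) + g$length + seq_len(nchar(lay$pam))
  utpos <- max(pampos) + seq_len(lay$umi_t_length)
  mkqual <- function(q_const, q_rest) {
    q <- rep(q_rest, n)
    q[c(upos, pampos, utpos)] <- q_const
    intToUtf8(q + 33L)
  }
  mkread <- function(qual) data.table(id = "r", seq = seqstr, qual = qual)

  parse1 <- function(qual)
    parse_and_demultiplex(mkread(qual), g, lay, sp)

  ## constants Q10, rest Q40 -> the read fails despite a high overall mean
  low_const <- parse1(mkqual(10L, 40L))
  expect_equal(low_const$mean_quality, 10)
  expect_equal(nrow(quality_filter(low_const, 20)), 0L)

  ## all Q30 -> retained; constants exactly Q20 -> retained (not "below")
  expect_equal(nrow(quality_filter(parse1(mkqual(30L, 30L)), 20)), 1L)
  at20 <- parse1(mkqual(20L, 40L))
  expect_equal(at20$mean_quality, 20)
  expect_equal(nrow(quality_filter(at20, 20)), 1L)
})

test_that("collapsing dedups PCR copies, keys on stagger, and is idempotent", {
  g <- test_guide(); lay <- test_layout(g)
  sp <- test_seqp(mean_pcr_duplicates = 4)
  tpl <- generate_template_library(g, library_params(0.1, 150L), seed = 40)
  mol <- simulate_cut_reaction(tpl, cleavage_truth(g, 0.7), copies = 3,
                               copies_dist = "fixed", seed = 41)
  fq <- tempfile(fileext = ".fastq")
  ev <- simulate_ligation_sequencing(mol, g, lay, sp, "ACTGAC", fq, seed = 42)
  parsed <- parse_and_demultiplex(fq, g, lay, sp)
  obs <- collapse_observations(parsed)

  truth_tuples <- unique(ev[, .(umi_t, umi_p, cut_status, stagger)])
  expect_equal(nrow(obs), nrow(truth_tuples))
  expect_equal(sum(obs$n_reads), nrow(parsed))

  ## idempotence
  obs2 <- collapse_observations(obs)
  expect_equal(as.data.frame(obs2[order(umi_t, umi_p, cut_status, stagger)]),
               as.data.frame(obs[order(umi_t, umi_p, cut_status, stagger)]))

  ## same UMI pair, different stagger -> distinct observations
  two <- parsed[1:2]
  two[, `:=`(umi_t = "AAAAAAAAAAAA", umi_p = "CCCCCCCC",
             cut_status = "uncut", target = g$spacer)]
  two[2, stagger := two$stagger[1] %% 8L + 1L]
  expect_equal(nrow(collapse_observations(two)), 2L)
  two[2, stagger := two$stagger[1]]
  expect_equal(nrow(collapse_observations(two)), 1L)
})

test_that("target validation enforces uncut support, spike-ins and collisions", {
  g <- test_guide()
  mkobs <- function(umi_t, status, n, target = g$spacer, umip0 = 0L) {
    data.table(barcode = "ACTGAC", umi_t = umi_t,
               umi_p = sprintf("UP%06d", umip0 + seq_len(n)),
               cut_status = status, stagger = 1L,
               target = ifelse(status == "uncut", target, NA_character_),
               n_reads = 1L)
  }
  ## 2 uncut observations, no spike-in -> excluded
  obs <- rbind(mkobs("T1", "uncut", 2), mkobs("T1", "cut", 5, umip0 = 100))
  rec <- validate_targets(obs, min_uncut = 3)
  expect_false(rec[umi_t == "T1", validated])

  ## 0 sample uncut + 3 spike-in uncut + 10 cut -> validated; cut fraction
  ## from sample observations only
  obs2 <- mkobs("T2", "cut", 10)
  spike <- mkobs("T2", "uncut", 3, umip0 = 500)
  rec2 <- validate_targets(obs2, min_uncut = 3, spikein = spike, guide = g)
  expect_true(rec2[umi_t == "T2", validated])
  expect_equal(rec2[umi_t == "T2", .(n_cut, n_uncut, n_spikein)],
               data.table(n_cut = 10L, n_uncut = 0L, n_spikein = 3L))
  ## ... unless explicitly requested
  rec2b <- validate_targets(obs2, min_uncut = 3, spikein = spike,
                            include_spikein_counts = TRUE)
  expect_equal(rec2b[umi_t == "T2", n_uncut], 3L)

  ## colliding target sequences under one UMI_T (no strict majority) -> drop
  alt <- paste0("A", substring(g$spacer, 2))
  coll <- rbind(mkobs("T3", "uncut", 3, target = g$spacer),
                mkobs("T3", "uncut", 3, target = alt, umip0 = 50))
  rec3 <- validate_targets(coll, min_uncut = 3)
  expect_false("T3" %in% rec3$umi_t)
  expect_equal(attr(rec3, "validation_report")$collisions, 1L)
  ## strict majority wins
  maj <- rbind(mkobs("T4", "uncut", 4, target = g$spacer),
               mkobs("T4", "uncut", 2, target = alt, umip0 = 50))
  expect_equal(validate_targets(maj)[umi_t == "T4", target], g$spacer)

  ## raising min_uncut never grows the validated set
  big <- rbind(mkobs("T5", "uncut", 3), mkobs("T6", "uncut", 5, umip0 = 40),
               mkobs("T7", "uncut", 7, umip0 = 80))
  v <- vapply(1:8, function(m) sum(validate_targets(big, min_uncut = m)$validated),
              integer(1))
  expect_true(all(diff(v) <= 0))
})

test_that("grouping by guide and PAM preserves per-sample counts", {
  g <- test_guide()
  r1 <- data.table(umi_t = "T1", target = g$spacer, n_cut = 3L, n_uncut = 4L,
                   n_obs = 7L, validated = TRUE)
  r2 <- data.table(umi_t = "T1", target = g$spacer, n_cut = 5L, n_uncut = 5L,
                   n_obs = 10L, validated = TRUE)
  info <- data.table(sample = c("s1", "s2"), guide = "tg", pam = "TTGAAT",
                     replicate = c("rep1", "rep2"))
  grp <- group_by_guide_pam(list(s1 = r1, s2 = r2), info)
  expect_equal(nrow(grp), 2L)
  expect_equal(grp[, uniqueN(umi_t)], 1L)
  expect_setequal(grp$n_cut, c(3L, 5L))

  ## order invariance
  grp_rev <- group_by_guide_pam(list(s2 = r2, s1 = r1), info)
  expect_equal(as.data.frame(grp), as.data.frame(grp_rev))

  ## empty input and unknown samples
  empty <- group_by_guide_pam(list(s1 = r1[0]), info)
  expect_equal(nrow(empty), 0L)
  expect_error(group_by_guide_pam(list(sX = r1), info), "sample_info")
})
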