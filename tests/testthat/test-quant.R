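.rec <- function(umi_t, target, n_cut, n_uncut, replicate = NULL) {
  x <- data.table(umi_t = umi_t, target = target, n_cut = as.integer(n_cut),
                  n_uncut = as.integer(n_uncut))
  x[, n_obs := n_cut + n_uncut]
  if (!is.null(replicate)) x[, replicate := replicate]
  x
}

test_that("eta is the on-target-normalized cut fraction", {
  g <- test_guide()
  off <- paste0("A", substring(g$spacer, 2))          # one distal mismatch
  rec <- .rec(c("ON", "OFF"), c(g$spacer, off), c(10, 8), c(0, 2))
  eta <- compute_eta(rec, g)
  expect_equal(eta[umi_t == "OFF", eta], 0.8)
  expect_equal(eta[umi_t == "ON", eta], 1)            # identity by construction

  ## pooled on-target normalization: several perfect-match UMI_Ts
  rec2 <- .rec(c("ON1", "ON2", "OFF"), c(g$spacer, g$spacer, off),
               c(9, 7, 4), c(1, 3, 6))
  eta2 <- compute_eta(rec2, g)
  expect_equal(eta2[umi_t == "OFF", eta], 0.4 * (20 / 16))
  ## eta above 1 is legal and not clipped
  rec3 <- .rec(c("ON", "HOT"), c(g$spacer, off), c(5, 10), c(5, 0))
  expect_equal(compute_eta(rec3, g)[umi_t == "HOT", eta], 2)

  ## zero cleaved on-target observations -> error
  rec4 <- .rec(c("ON", "OFF"), c(g$spacer, off), c(0, 5), c(10, 5))
  expect_error(compute_eta(rec4, g), "on-target")
})

test_that("eta recovers planted relative cleavage probabilities", {
  g <- test_guide()
  truth <- cleavage_truth(g, on_target_prob = 0.9)
  rec <- simulate_target_records(g, truth, library_params(0.1, 300L),
                                 copies = 150, copies_dist = "fixed",
                                 seed = 50)
  eta <- compute_eta(rec, g)
  expect_gt(cor(eta$eta, eta$p_true / 0.9), 0.95)
})

test_that("replicate averaging is the unweighted mean over available replicates", {
  g <- test_guide()
  off <- paste0("A", substring(g$spacer, 2))
  mk <- function(rep, eta_off) {
    .rec(c("ON", "OFF"), c(g$spacer, off), c(10, round(10 * eta_off)),
         c(0, 10 - round(10 * eta_off)), replicate = rep)
  }
  eta <- compute_eta(rbind(mk("r1", 0.2), mk("r2", 0.4), mk("r3", 0.6)), g)
  avg <- replicate_average(eta)
  expect_equal(avg[umi_t == "OFF", eta], 0.4)
  expect_equal(avg[umi_t == "OFF", n_replicates], 3L)

  ## a target missing from one replicate: averaged over where it appears
  part <- rbind(mk("r1", 0.2), mk("r2", 0.4))
  part <- rbind(part, .rec("ON", g$spacer, 10, 0, replicate = "r3"))
  avg2 <- replicate_average(compute_eta(part, g))
  expect_equal(avg2[umi_t == "OFF", eta], 0.3)
  expect_equal(avg2[umi_t == "OFF", n_replicates], 2L)
  expect_equal(avg2[umi_t == "ON", n_replicates], 3L)
})

test_that("reproducibility R^2 behaves like squared Pearson under binomial noise", {
  g <- test_guide()
  truth <- cleavage_truth(g, 0.9)
  tpl <- generate_template_library(g, library_params(0.1, 400L), seed = 60)
  eta_at <- function(copies, seed) {
    compute_eta(sim_replicate_records(tpl, g, truth, copies, seed), g)
  }
  a30 <- eta_at(30, 61); b30 <- eta_at(30, 62)
  a300 <- eta_at(300, 63); b300 <- eta_at(300, 64)

  expect_equal(reproducibility(a30, a30)$r_squared, 1)
  r_shallow <- reproducibility(a30, b30)$r_squared
  r_deep <- reproducibility(a300, b300)$r_squared
  expect_gt(r_deep, r_shallow)           # depth shrinks binomial noise
  expect_gt(r_deep, 0.9)

  ## read filter drops weakly supported targets
  rr <- reproducibility(a30, b30, min_reads = 25)
  expect_lt(rr$n_targets, reproducibility(a30, b30)$n_targets)

  ## disjoint targets -> error
  b_dis <- copy(b30)[, umi_t := paste0("X", umi_t)]
  expect_error(reproducibility(a30, b_dis), "shared targets")
})

test_that("mismatch aggregation exposes position effects and epistasis", {
  g <- test_guide()
  L <- g$length

  ## only on-targets: the N=0 row is exactly 1
  on_only <- compute_eta(.rec(c("A", "B"), rep(g$spacer, 2),
                              c(5, 7), c(5, 3)), g)
  bc <- aggregate_by_mismatch(on_only, g)$by_count
  expect_equal(bc[n_mm == 0, mean_eta], 1)

  ## multiplicative truth at high depth: pairwise epistasis ~ 0 and
  ## PAM-proximal single mismatches cut worse than PAM-distal ones
  truth <- cleavage_truth(g, 0.9)     # seed gradient, no planted epistasis
  rec <- simulate_target_records(g, truth, library_params(0.1, 4000L),
                                 copies = 400, copies_dist = "fixed",
                                 seed = 70)
  eta <- compute_eta(rec, g)
  agg <- aggregate_by_mismatch(eta, g)
  expect_lt(mean(abs(agg$epistasis$epistasis), na.rm = TRUE), 0.06)

  singles <- agg$single_mm_table
  proximal <- singles[pos <= 5, mean(mean_eta)]
  distal <- singles[pos >= L - 4, mean(mean_eta)]
  expect_lt(proximal, distal)

  ## matrix shape: 4 x L with WT cells undefined
  expect_equal(dim(agg$single_mm), c(4L, L))
  wt_rows <- match(rev(strsplit(g$spacer, "")[[1]]), c("A", "C", "G", "T"))
  expect_true(all(is.na(agg$single_mm[cbind(wt_rows, seq_len(L))])))
})

test_that("GIMP implements the literal inclusive sum over mismatch classes", {
  ## class means (0.9, 0.6, 0.3, 0.1) for N = 1..4 -> 1.9 / 3
  x <- data.table(n_mm = 1:4, eta = c(0.9, 0.6, 0.3, 0.1))
  gs <- gimp_score(x)
  expect_equal(gs$gimp, 1.9 / 3)

  ## eta == 0 everywhere -> 0
  expect_equal(gimp_score(data.table(n_mm = 1:4, eta = 0))$gimp, 0)

  ## constant c: literal mode gives 4c/3, mean mode gives c
  const <- data.table(n_mm = 1:4, eta = 0.3)
  expect_equal(gimp_score(const, mode = "literal")$gimp, 0.3 * 4 / 3)
  expect_equal(gimp_score(const, mode = "mean")$gimp, 0.3)

  ## an empty class is an error naming the class
  expect_error(gimp_score(data.table(n_mm = c(1, 2, 4), eta = 0.5)), "3")
})

test_that("GIMP orders promiscuity and ignores absolute on-target efficiency", {
  g <- test_guide()
  gimp_of <- function(w, dose, seed) {
    truth <- cleavage_truth(g, on_target_prob = dose,
                            position_weights = rep(w, g$length))
    rec <- simulate_target_records(g, truth, library_params(0.1, 3000L),
                                   copies = 60, seed = seed)
    gimp_score(compute_eta(rec, g))$gimp
  }
  ## uniformly stronger penalties -> strictly lower GIMP
  hi <- gimp_of(0.8, 0.9, 80)
  lo <- gimp_of(0.3, 0.9, 81)
  expect_gt(hi, lo)

  ## halving every absolute probability (dose) leaves GIMP essentially
  ## unchanged: eta is normalized to the on-target efficiency
  hi_half <- gimp_of(0.8, 0.45, 82)
  expect_lt(abs(hi - hi_half) / hi, 0.1)
})
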