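test_that("site-set definition excludes non-diploid sites with reasons", {
  sites <- variant_sites(rep(c("1", "17"), c(7, 3)),
                         c(1:7 * 100L, 10L, 20L, 30L), "C", "T")
  assign <- rep("AML_root", 10)
  segs <- cn_segments("g", "17", 1L, 1000L, 1L, 0L)
  ss <- define_site_set(sites, assign, "AML_root", segs, "g")
  expect_identical(ss$n_sites, 7L)
  expect_identical(nrow(ss$excluded), 3L)
  expect_match(ss$excluded$reason[1], "non-diploid in g")
  # no CNV overlap -> all included
  ss2 <- define_site_set(sites, assign, "AML_root",
                         cn_segments("g", "2", 1L, 10L, 2L, 1L), "g")
  expect_identical(ss2$n_sites, 10L)
  # interval oracle on random segment/site configurations
  set.seed(41)
  for (rep_i in 1:5) {
    pos <- sample.int(5000, 60)
    st <- sort(sample.int(1000, 3)) + c(0L, 1500L, 3000L); en <- st + 400L
    segs_r <- cn_segments("q", "1", st, en,
                          c(2L, 1L, 3L), c(0L, 0L, 1L))
    sr <- variant_sites(rep("1", 60), pos, "C", "T")
    got <- define_site_set(sr, rep("b", 60), "b", segs_r, "q")
    want <- which(!vapply(pos, function(p)
      any(st <= p & p <= en), TRUE))
    expect_identical(got$site_idx, want)
  }
  expect_error(define_site_set(sites, assign, "nope", segs, "g"), "no SNVs")
})

test_that("panel background estimation is the mean per-sample rate", {
  # fixture: every panel sample at rate exactly 1.6e-4
  n_sites <- 250L; n_panel <- 8L
  d <- matrix(12500L, n_sites, n_panel)
  v <- matrix(0L, n_sites, n_panel); v[1:2, ] <- 250L   # 500/3,125,000
  panel <- make_counts(v, d, sprintf("P%02d", 1:n_panel))
  bg <- estimate_background(seq_len(n_sites), panel)
  expect_equal(bg$eps, 1.6e-4, tolerance = 1e-12)
  expect_equal(unname(bg$per_sample), rep(1.6e-4, n_panel), tolerance = 1e-12)
  # all-zero panel flags the degenerate test
  expect_warning(bg0 <- estimate_background(
    seq_len(10), make_counts(matrix(0L, 10, 3), matrix(100L, 10, 3))),
    "exactly 0")
  expect_identical(bg0$eps, 0)
  # recovery within 20% from a simulated panel (2,000 sites x 100x x 32)
  set.seed(3)
  dp <- matrix(rpois(2000 * 32, 100), 2000, 32)
  vp <- matrix(rbinom(2000 * 32, as.vector(dp), 1.6e-4), 2000, 32)
  bg2 <- estimate_background(seq_len(2000),
                             make_counts(vp, dp, sprintf("P%02d", 1:32)))
  expect_lte(abs(bg2$eps - 1.6e-4) / 1.6e-4, 0.2)
  # zero-depth panel sample dropped with warning
  dz <- dp; dz[, 1] <- 0L; vz <- vp; vz[, 1] <- 0L
  expect_warning(bgd <- estimate_background(
    seq_len(2000), make_counts(vz, dz, sprintf("P%02d", 1:32))), "dropped")
  expect_identical(bgd$n_panel, 31L)
})

test_that("detection test is the exact upper binomial tail with CP interval", {
  r0 <- detect_lineage(0, 1000, 1.6e-4)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$vaf_mle, 0)
  expect_equal(r0$ci_low, 0)
  # log-space summation oracle at V=10, D=10,000
  oracle <- clonetrace:::logsumexp(
    dbinom(10:10000, 10000, 1.6e-4, log = TRUE))
  r <- detect_lineage(10, 10000, 1.6e-4)
  expect_equal(log(r$p_value), oracle, tolerance = 1e-10)
  # agreement with a high-precision oracle across magnitudes, D <= 1e6
  for (case in list(c(5, 1000), c(50, 1e5), c(400, 1e6))) {
    V <- case[1]; D <- case[2]
    lp <- pbinom(V - 1, D, 1.6e-4, lower.tail = FALSE, log.p = TRUE)
    oracle <- clonetrace:::logsumexp(dbinom(V:D, D, 1.6e-4, log = TRUE))
    expect_lte(abs(lp - oracle) / abs(oracle), 1e-8)
    expect_equal(log(detect_lineage(V, D, 1.6e-4)$p_value), lp,
                 tolerance = 1e-10)
  }
  # clone size is twice the VAF, capped
  r2 <- detect_lineage(115, 1000, 1.6e-4)
  expect_equal(r2$clone_size, 0.23)
  expect_true(r2$ci_low <= r2$vaf_mle && r2$vaf_mle <= r2$ci_high)
  r3 <- detect_lineage(900, 1000, 1.6e-4)
  expect_equal(r3$clone_size, 1)
  # degenerate null
  expect_warning(rz <- detect_lineage(1, 100, 0), "degenerate")
  expect_equal(rz$p_value, 0)
  expect_error(detect_lineage(1, 0, 1e-4), "positive")
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(61)
  for (vaf in c(0, 0.0013, 0.1)) {
    D <- 231800L
    V <- rbinom(1000, D, vaf)
    cover <- vapply(V, function(v) {
      ci <- clopper_pearson(v, D)
      ci[["lower"]] <= vaf && vaf <= ci[["upper"]]
    }, TRUE)
    expect_gte(mean(cover), 0.95)
  }
})

test_that("timecourse tracking preserves order, stars, and outlier checks", {
  set.seed(71)
  n_sites <- 300L
  d <- matrix(rpois(n_sites * 3, 100), n_sites, 3)
  v <- matrix(rbinom(n_sites * 3, as.vector(d), 1.6e-4), n_sites, 3)
  # spike sample 2 at VAF 0.0013
  v[, 2] <- rbinom(n_sites, d[, 2], 0.0013)
  cm <- make_counts(v, d, c("early", "spiked", "late"))
  res <- track_lineage_timecourse(seq_len(n_sites), cm, 1.6e-4)
  expect_identical(res$sample_id, c("early", "spiked", "late"))
  expect_lt(res$p_value[2], 1e-6)
  expect_identical(res$stars[2], "***")
  expect_gt(res$p_value[1], 1e-4)
  # outlier report: a single site carrying most variant reads is flagged
  v2 <- v; v2[5, 3] <- 40L; d2 <- d; d2[5, 3] <- max(d2[5, 3], 40L)
  cm2 <- make_counts(v2, d2, c("early", "spiked", "late"))
  res2 <- track_lineage_timecourse(seq_len(n_sites), cm2, 1.6e-4)
  out <- attr(res2, "outliers")
  expect_true(5L %in% out[["late"]]$site)
  expect_error(track_lineage_timecourse(c(1L, 10000L), cm, 1.6e-4), "missing")
})

test_that("detection p-values are super-uniform under the null", {
  set.seed(81)
  D <- 2318L * 100L
  eps <- 1.6e-4
  V <- rbinom(2000, D, eps)
  ps <- vapply(V, function(v) detect_lineage(v, D, eps)$p_value, 1)
  # discreteness makes p stochastically >= uniform; one-sided KS
  ks <- suppressWarnings(stats::ks.test(ps, "punif", alternative = "greater"))
  expect_gte(ks$p.value, 0.01)
  expect_gte(mean(ps), 0.49)
})
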