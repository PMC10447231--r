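test_that("quality filters apply the ASMD/CLPM predicate exactly", {
  cfg <- filter_config()
  s <- variant_sites(rep("1", 3), c(10, 20, 30), "C", "T",
                     ASMD = c(140, 139, 200), CLPM = c(0, 0, 0.5))
  res <- apply_quality_filters(s, cfg)
  expect_identical(res$retained$pos, 10L)           # boundary ASMD = 140 kept
  expect_identical(res$rejections$reason, c("ASMD", "CLPM"))
  # predicate oracle on random annotations
  set.seed(11)
  n <- 100
  s2 <- variant_sites(rep("1", n), seq_len(n) * 10, "C", "T",
                      ASMD = sample(130:150, n, TRUE),
                      CLPM = sample(c(0, 0, 0.3), n, TRUE))
  res2 <- apply_quality_filters(s2, cfg)
  oracle <- s2$ASMD >= 140 & s2$CLPM <= 0
  expect_identical(sort(res2$retained$pos), sort(s2$pos[oracle]))
  # missing annotations: retained with warning by default, rejectable
  s3 <- variant_sites("1", 10, "C", "T")
  expect_warning(r3 <- apply_quality_filters(s3, cfg), "missing")
  expect_identical(nrow(r3$retained), 1L)
  r4 <- apply_quality_filters(s3, filter_config(missing_annotation = "reject"))
  expect_identical(nrow(r4$retained), 0L)
})

test_that("germline test is the exact lower binomial tail", {
  expect_equal(germline_test(0, 30), 2^-30, tolerance = 1e-12)
  expect_equal(germline_test(25, 25), 1)
  # exact enumeration oracle
  oracle <- sum(choose(60, 0:12)) / 2^60
  expect_equal(germline_test(12, 60), oracle, tolerance = 1e-12)
  # larger-depth agreement with direct summation, relative error <= 1e-12
  for (d in c(100L, 1000L, 10000L)) {
    v <- as.integer(d * 0.45)
    oracle <- sum(exp(lchoose(d, 0:v) - d * log(2)))
    expect_equal(germline_test(v, d), oracle, tolerance = 1e-12)
  }
  expect_warning(p0 <- germline_test(0, 0), "undefined")
  expect_equal(p0, 1)
})

test_that("BH q-values match the hand step-up computation", {
  # single site
  cm1 <- make_counts(matrix(0), matrix(20))
  r1 <- classify_germline(cm1, "s1", filter_config(germline_q_cutoff = 1e-5))
  expect_equal(r1$q, r1$p)
  expect_identical(r1$label, "somatic")   # p = 2^-20 < 1e-5
  # hand-computed BH on (0.01, 0.02, 0.03): q = (0.03, 0.03, 0.03)
  p <- c(0.01, 0.02, 0.03)
  m <- 3
  hand <- rev(cummin(rev(m * p / seq_len(m))))
  expect_equal(hand, rep(0.03, 3))
  expect_equal(stats::p.adjust(p, "BH"), hand)
  # q-values non-decreasing in p-rank; permutation invariance of labels
  set.seed(21)
  v <- matrix(rbinom(40, 50, 0.3), 20, 2)
  cm <- make_counts(v, matrix(50L, 20, 2))
  r <- classify_germline(cm)
  expect_true(all(diff(r$q[order(r$p)]) >= -1e-12))
  perm <- sample(20)
  rp <- classify_germline(subset_counts(cm, i = perm))
  expect_identical(rp$label, r$label[perm])
})

test_that("germline/somatic classification is >= 99% accurate on known truth", {
  set.seed(77)
  n_g <- 400; n_s <- 400
  d <- matrix(rpois((n_g + n_s) * 4, 100), ncol = 4)
  truth <- rep(c("germline", "somatic"), c(n_g, n_s))
  vaf <- c(rep(0.5, n_g), rep(0.15, n_s))     # subclonal somatic
  v <- matrix(rbinom(length(d), as.vector(d), rep(vaf, 4)), ncol = 4)
  cm <- make_counts(v, d, paste0("t", 1:4))
  r <- classify_germline(cm)
  expect_gte(mean(r$label == truth), 0.99)
})

test_that("beta-binomial reduces to binomial at rho = 0", {
  for (d in c(10L, 500L, 10000L)) {
    v <- as.integer(d * 0.01) + 1L
    expect_equal(pbetabinom_upper(v, d, 1e-3, 0),
                 pbinom(v - 1, d, 1e-3, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_equal(dbetabinom_log(3, 10, 0.2, 0), dbinom(3, 10, 0.2, log = TRUE))
  # rho > 0 tail via direct summation oracle
  pmf <- exp(dbetabinom_log(0:100, 100, 0.05, 0.1))
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
  expect_equal(pbetabinom_upper(7, 100, 0.05, 0.1), sum(pmf[8:101]),
               tolerance = 1e-10)
})

test_that("error model recovers (eps, rho) and collapses cleanly at rho = 0", {
  set.seed(5)
  n_neg <- 50L
  d <- matrix(rpois(3 * n_neg, 200), 3, n_neg)
  mkcm <- function(v) make_counts(v, d, sprintf("N%02d", 1:n_neg))
  # all-zero site: eps at the pseudocount floor, rho 0
  em0 <- fit_error_model(mkcm(matrix(0L, 3, n_neg)),
                         sprintf("N%02d", 1:n_neg))
  expect_lte(max(abs(em0$eps / (0.5 / (rowSums(d) + 1)) - 1)), 0.05)
  expect_identical(em0$rho, rep(0, 3))
  # parameter recovery from BetaBin(1e-3, 0.05): per-site estimates from 50
  # negatives are noisy, so the recovery bounds hold at the median over sites
  set.seed(6)
  n_site <- 9L
  d9 <- matrix(rpois(n_site * n_neg, 200), n_site, n_neg)
  v9 <- matrix(clonetrace:::.rbetabinom(n_site * n_neg, as.vector(d9),
                                        1e-3, 0.05), n_site, n_neg)
  em <- fit_error_model(make_counts(v9, d9, sprintf("N%02d", 1:n_neg)),
                        sprintf("N%02d", 1:n_neg))
  expect_gt(median(em$eps), 5e-4)
  expect_lt(median(em$eps), 2e-3)
  expect_gte(median(em$rho), 0.01)
  expect_lte(median(em$rho), 0.15)
  # rho = 0 data: the fitted likelihood stays within noise-level gains of
  # the pure binomial MLE (rho is collapsed when the gain is < 0.5)
  set.seed(7)
  vb <- matrix(rbinom(3 * n_neg, as.vector(d), 1e-3), 3, n_neg)
  emb <- fit_error_model(mkcm(vb), sprintf("N%02d", 1:n_neg))
  for (i in 1:3) {
    eps_mle <- max(sum(vb[i, ]) / sum(d[i, ]), 0.5 / (sum(d[i, ]) + 1))
    ll_binom <- sum(dbinom(vb[i, ], d[i, ], eps_mle, log = TRUE))
    expect_gte(emb$loglik[i], ll_binom - 1e-6)
    expect_lte(emb$loglik[i] - ll_binom, 3)
  }
  # < 2 negatives: pooled, flagged
  em1 <- fit_error_model(mkcm(matrix(1L, 3, n_neg)), "N01")
  expect_true(all(em1$low_confidence))
})

test_that("presence calls use the exact tail and control the null FDR", {
  cfg <- filter_config(presence_alpha = 1e-3)
  d <- matrix(100L, 2, 1)
  cm <- make_counts(matrix(c(0L, 30L), 2, 1), d)
  em <- data.frame(eps = c(1e-3, 1e-3), rho = c(0, 0), loglik = 0,
                   n_negative = 10L, low_confidence = FALSE)
  calls <- call_presence(cm, em, cfg)
  expect_equal(calls$p[1L], 1)
  expect_false(calls$present[1L])
  expect_equal(calls$p[2L],
               pbinom(29, 100, 1e-3, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(calls$present[2L])
  # null simulation: no true variants -> empirical FDR <= 5e-3
  set.seed(13)
  n <- 10000L
  dn <- matrix(rpois(n, 100), n, 1)
  vn <- matrix(rbinom(n, as.vector(dn), 1e-3), n, 1)
  cmn <- make_counts(vn, dn)
  emn <- data.frame(eps = rep(1e-3, n), rho = 0, loglik = 0,
                    n_negative = 10L, low_confidence = FALSE)
  calls_n <- call_presence(cmn, emn, cfg)
  expect_lte(mean(calls_n$present), 5e-3)
})
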