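test_that("PWM construction from consensus blocks", {
  m <- build_rss_pwm("CACAGTG", "ACAAAAACC", spacer_len = 12L, pseudocount = 1)
  expect_identical(nrow(m$pwm), 7L + 12L + 9L)
  expect_equal(rowSums(m$pwm), rep(1, 28), tolerance = 1e-12)
  # single sequence, pseudocount 1: consensus base prob (1+1)/(1+4) = 0.4
  expect_equal(unname(m$pwm[1, "C"]), 0.4)
  expect_equal(unname(m$pwm[1, "A"]), 0.2)
  # spacer rows uniform
  expect_true(all(m$pwm[8:19, ] == 0.25))
  # pseudocount -> infinity: uniform
  minf <- build_rss_pwm(spacer_len = 12L, pseudocount = 1e9)
  expect_true(all(abs(minf$pwm - 0.25) < 1e-6))
  # random multi-sequence input rows still sum to 1
  set.seed(2)
  hepts <- replicate(5, paste(sample(c("A", "C", "G", "T"), 7, TRUE),
                              collapse = ""))
  m2 <- build_rss_pwm(hepts, "ACAAAAACC", 23L, 0.25)
  expect_equal(rowSums(m2$pwm), rep(1, 39), tolerance = 1e-12)
  expect_error(build_rss_pwm("CACA", "ACAAAAACC", 12L), "lengths")
})

test_that("window scoring is the per-position log-ratio sum", {
  m <- build_rss_pwm(spacer_len = 12L)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  # uniform pwm, uniform background -> 0
  mu <- m; mu$pwm[] <- 0.25
  expect_equal(score_window(strrep("A", 28), mu, rep(0.25, 4)), 0)
  # consensus sequence attains the maximal score
  cons <- paste(apply(m$pwm, 1, function(r) c("A", "C", "G", "T")[which.max(r)]),
                collapse = "")
  expect_equal(score_window(cons, m, bg),
               sum(log2(apply(m$pwm, 1, max) /
                          bg[apply(m$pwm, 1, which.max)])), tolerance = 1e-12)
  # independent per-position oracle on random sequences
  set.seed(14)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 28, TRUE), collapse = "")
    b <- strsplit(s, "")[[1]]
    oracle <- sum(vapply(seq_len(28), function(p)
      log2(m$pwm[p, b[p]] / bg[match(b[p], c("A", "C", "G", "T"))]), 1))
    expect_equal(score_window(s, m, bg), oracle, tolerance = 1e-10)
  }
  expect_true(is.na(score_window(paste0(strrep("A", 27), "N"), m, bg)))
  expect_error(score_window("ACGT", m, bg), "length")
})

test_that("exact p-values agree with exhaustive enumeration", {
  set.seed(6)
  bases <- c("A", "C", "G", "T")
  for (L in c(4L, 6L)) {
    pwm <- matrix(rexp(4 * L), L, 4)
    pwm <- pwm / rowSums(pwm)
    colnames(pwm) <- bases
    motif <- structure(list(pwm = pwm, spacer_len = 12L), class = "rss_motif")
    bg <- c(0.3, 0.2, 0.2, 0.3)
    seqs <- do.call(expand.grid, rep(list(bases), L))
    allseq <- apply(seqs, 1, paste, collapse = "")
    sc <- vapply(allseq, score_window, 1, motif = motif, background = bg)
    pr <- apply(seqs, 1, function(b) prod(bg[match(b, bases)]))
    enum_p <- vapply(sc, function(t) sum(pr[sc >= t - 1e-9]), 1)
    dp_p <- vapply(sc, score_pvalue, 1, motif = motif, background = bg)
    expect_lte(max(abs(enum_p - dp_p)), 1e-6)
  }
})

test_that("p-values are monotone in score and bounded", {
  m <- build_rss_pwm(spacer_len = 23L)
  bg <- rep(0.25, 4)
  scores <- seq(-40, 25, by = 5)
  ps <- vapply(scores, score_pvalue, 1, motif = m, background = bg)
  expect_true(all(diff(ps) <= 1e-12))
  expect_equal(ps[1], 1)        # score below the attainable minimum
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("reverse-strand scan equals forward scan of the reverse complement", {
  set.seed(17)
  fl <- paste(sample(c("A", "C", "G", "T"), 101, TRUE), collapse = "")
  rc <- clonetrace:::revcomp_chars(fl)
  cfg <- rss_scan_config(background = rep(0.25, 4))
  h1 <- scan_breakpoints(breakpoint_pairs("1", 100, 500, "deletion", fl, fl),
                         cfg = cfg)
  h2 <- scan_breakpoints(breakpoint_pairs("1", 100, 500, "deletion", rc, rc),
                         cfg = cfg)
  for (mot in unique(h1$motif)) for (side in c("low", "high")) {
    a <- h1[h1$motif == mot & h1$side == side, ]
    b <- h2[h2$motif == mot & h2$side == side, ]
    expect_equal(sort(a$score), sort(b$score), tolerance = 1e-10)
    expect_equal(a$score[a$strand == "+"], b$score[b$strand == "-"],
                 tolerance = 1e-10)
  }
})

test_that("planted consensus RSS is recovered at its offset", {
  set.seed(23)
  m23 <- build_rss_pwm(spacer_len = 23L)
  res <- plant_rss_deletion(m23, offset = 10L, side = "high", plant = TRUE)
  hits <- scan_breakpoints(res$bp)
  best <- hits[hits$side == "high" & hits$motif == "RSS23" & hits$strand == "+", ]
  expect_identical(best$offset, 10L)
  expect_lt(best$p, 0.05)
  expect_true(best$hit)
  # reverse-strand plant carries the strand flag
  set.seed(24)
  resm <- plant_rss_deletion(m23, offset = 6L, strand = "-", side = "high")
  hm <- scan_breakpoints(resm$bp)
  hm23 <- hm[hm$side == "high" & hm$motif == "RSS23", ]
  expect_identical(hm23$strand[which.min(hm23$p)], "-")
})

test_that("windows smaller than the motif yield an empty warning result", {
  bp <- breakpoint_pairs("1", 100, 500, "deletion", "ACGTACGT", "ACGTACGT")
  w <- capture_warnings(
    h <- scan_breakpoints(bp, motifs = list(build_rss_pwm(spacer_len = 23L)),
                          cfg = rss_scan_config(window = 4L)))
  expect_true(all(grepl("smaller than", w)))   # one warning per side
  expect_identical(nrow(h), 0L)
})

test_that("MEME motif files round-trip", {
  m <- build_rss_pwm(spacer_len = 12L)
  p <- withr::local_tempfile(fileext = ".meme")
  write_meme_motif(m, p)
  back <- read_meme_motif(p)
  expect_equal(back$pwm, m$pwm, tolerance = 1e-5)
  expect_identical(back$spacer_len, 12L)
})
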