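test_that("expected_vaf follows the purity/copy-number mapping", {
  expect_equal(expected_vaf(1, 1, 1, 1, 1), 0.5)
  expect_equal(expected_vaf(1, 0.8, 1, 1, 1), 0.8 / (1.6 + 0.4))
  expect_equal(expected_vaf(0, 0.8), 0)
  expect_equal(expected_vaf(1, 1, 1, 0, 1), 1, tolerance = 1e-9)  # hemizygous
  expect_equal(expected_vaf(0.5, 0.6, 2, 1, 2),
               0.6 * 0.5 * 2 / (0.6 * 3 + 0.4 * 2))
})

test_that("cluster_config validates iteration counts", {
  expect_error(cluster_config(n_iter = 100, burn_in = 100), "burn_in")
})

test_that("a single clonal population is recovered with calibrated CCF", {
  set.seed(1)
  n <- 300
  d <- matrix(rpois(n * 2, 100), n, 2)
  v <- matrix(rbinom(n * 2, as.vector(d), 0.5), n, 2)
  cl <- gibbs_cluster(make_counts(v, d, c("A", "B")),
                      cfg = cluster_config(n_iter = 600, burn_in = 300, seed = 2))
  expect_identical(nrow(cl$ccf), 1L)
  expect_true(all(abs(cl$ccf - 1) <= 0.05))
  # posterior CCF unbiased within Monte-Carlo error across seeds
  est <- vapply(1:10, function(s) {
    set.seed(s)
    d <- matrix(rpois(n, 100), n, 1)
    v <- matrix(rbinom(n, as.vector(d), 0.5), n, 1)
    cl <- gibbs_cluster(make_counts(v, d),
                        cfg = cluster_config(n_iter = 400, burn_in = 200, seed = s))
    cl$ccf[which.max(cl$n_assigned), 1]
  }, 1)
  expect_lte(abs(mean(est) - 1), 0.02)
})

test_that("two separated clones are recovered with high ARI", {
  sim <- sim_two_clones(101)
  cl <- gibbs_cluster(sim$counts,
                      cfg = cluster_config(n_iter = 600, burn_in = 300, seed = 101))
  expect_identical(nrow(cl$ccf), 2L)
  expect_gte(adjusted_rand_index(cl$assignment, sim$node), 0.9)
  expect_true(all(abs(sort(cl$ccf[, 1]) - c(0.4, 1)) <= 0.05))
})

test_that("single-dimension clustering resolves the 1.0/0.75/0.20 subclones", {
  set.seed(55)
  ccf1 <- c(1, 0.75, 0.2); n1 <- 250
  node <- rep(1:3, each = n1)
  d <- matrix(rpois(3 * n1, 100), ncol = 1)
  v <- matrix(rbinom(3 * n1, as.vector(d), ccf1[node] / 2), ncol = 1)
  cm <- make_counts(v, d, "X")
  cl <- cluster_1d(cm, "X", cfg = cluster_config(n_iter = 800, burn_in = 400,
                                                 seed = 55))
  expect_identical(nrow(cl$ccf), 3L)
  expect_true(all(abs(sort(cl$ccf[, 1]) - c(0.2, 0.75, 1)) <= 0.08))
})

test_that("recovery error decreases with sequencing depth", {
  err_at <- function(depth) {
    mean(vapply(1:4, function(s) {
      set.seed(900 + s)
      ccf1 <- c(1, 0.5); n1 <- 150
      node <- rep(1:2, each = n1)
      d <- matrix(rpois(2 * n1, depth), ncol = 1)
      v <- matrix(rbinom(2 * n1, as.vector(d), ccf1[node] / 2), ncol = 1)
      cl <- gibbs_cluster(make_counts(v, d),
                          cfg = cluster_config(n_iter = 400, burn_in = 200,
                                               seed = s))
      cc <- sort(cl$ccf[, 1], decreasing = TRUE)[1:2]
      mean(abs(sort(cc) - c(0.5, 1)), na.rm = TRUE)
    }, 1))
  }
  expect_lte(err_at(100), err_at(30) + 0.01)
})

test_that("same seed gives bit-identical output; degenerate input errors", {
  sim <- sim_two_clones(7, n = 80)
  cfg <- cluster_config(n_iter = 200, burn_in = 100, seed = 9)
  a <- gibbs_cluster(sim$counts, cfg = cfg)
  b <- gibbs_cluster(sim$counts, cfg = cfg)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$ccf, b$ccf)
  # zero-depth mutation rejected by name
  cm <- sim$counts
  cm$depth[3, ] <- 0L; cm$var_reads[3, ] <- 0L
  expect_error(gibbs_cluster(cm, cfg = cfg), "zero depth")
})

test_that("sampler diagnostics: monotone annealed init, stationary chain", {
  sim <- sim_two_clones(19, n = 150)
  cl <- gibbs_cluster(sim$counts,
                      cfg = cluster_config(n_iter = 800, burn_in = 400, seed = 3))
  init <- cl$diagnostics$init_loglik
  expect_true(all(diff(init) >= -1e-6))
  # Geweke-style z on the post-burn-in log-likelihood trace
  ll <- cl$diagnostics$loglik[401:800]
  a <- ll[1:100]; b <- ll[201:400]
  z <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_lte(abs(z), 3)
})

test_that("consensus clustering is idempotent, splits, and label-invariant", {
  base <- rep(1:3, each = 30)
  ccfs <- rbind(c(1, 1), c(0.6, 0.2), c(0.1, 0.5))
  core <- list(assignment = base, ccf = ccfs)
  class(core) <- "clone_clusters"
  # enrichment identical to core -> output = core partition
  out <- consensus_clustering(core, list(core))
  expect_identical(out$assignment, match(base, sort(unique(base))))
  # enrichment separates a core cluster into two distant groups
  enr_assign <- base
  enr_assign[1:15] <- 4L
  enr <- list(assignment = enr_assign,
              ccf = rbind(c(1, 1), c(0.6, 0.2), c(0.1, 0.5), c(0.55, 1)))
  class(enr) <- "clone_clusters"
  out2 <- consensus_clustering(core, list(enr))
  expect_identical(length(unique(out2$assignment)), 4L)
  expect_identical(nrow(out2$mapping), 1L)
  # relabeling core ids does not change the output partition
  relab <- c(3L, 1L, 2L)[base]
  core2 <- list(assignment = relab, ccf = ccfs[c(2, 3, 1), ])
  class(core2) <- "clone_clusters"
  out3 <- consensus_clustering(core2, list(enr))
  expect_gte(adjusted_rand_index(out3$assignment, out2$assignment), 1)
  # inconsistent universes rejected
  expect_error(consensus_clustering(core, list(list(assignment = 1:5))),
               "universe")
})
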