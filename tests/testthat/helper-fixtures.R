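# Shared fixtures: all built in code at test time.

make_counts <- function(v, d, sample_ids = paste0("s", seq_len(ncol(as.matrix(v)))),
                        purity = 1, chrom = "1") {
  v <- as.matrix(v); d <- as.matrix(d)
  sites <- variant_sites(rep(chrom, nrow(v)), seq_len(nrow(v)) * 10L + 10L,
                         "C", "T")
  count_matrix(sites, sample_meta(sample_ids, purity = purity), v, d)
}

# two-clone, two-sample simulated counts with known assignment
sim_two_clones <- function(seed, n = 200, depth = 100,
                           ccf = rbind(c(1, 1), c(0.4, 0.05))) {
  set.seed(seed)
  node <- rep(seq_len(nrow(ccf)), each = n)
  N <- length(node)
  d <- matrix(stats::rpois(N * 2, depth), N, 2)
  v <- matrix(stats::rbinom(N * 2, as.vector(d), as.vector(ccf[node, ] / 2)), N, 2)
  list(counts = make_counts(v, d, c("A", "B")), node = node)
}

# random pigeonhole-valid clone tree with crossing siblings and small
# residuals, so the feasible tree is unique at exact CCFs
gen_pigeonhole_tree <- function(seed, S = 4L, max_nodes = 7L) {
  set.seed(seed)
  ccf <- matrix(1, 1, S)
  parent <- 0L
  repeat {
    K <- nrow(ccf)
    if (K >= max_nodes - 1L) break
    splittable <- which(apply(ccf, 1L, min) >= 0.5 &
                        !(seq_len(K) %in% parent))
    if (!length(splittable)) break
    p <- splittable[1L]
    f1 <- stats::runif(S, 0.15, 0.35)
    odd <- seq_len(S) %% 2L == 1L
    f1[odd] <- stats::runif(sum(odd), 0.55, 0.75)
    c1 <- ccf[p, ] * f1
    c2 <- ccf[p, ] * (0.95 - f1)
    ccf <- rbind(ccf, c1, c2)
    parent <- c(parent, p, p)
    if (nrow(ccf) >= max_nodes) break
  }
  rownames(ccf) <- paste0("N", seq_len(nrow(ccf)))
  names(parent) <- rownames(ccf)
  list(ccf = ccf, parent = parent)
}

# exhaustive feasibility oracle over all parent vectors (nodes ordered by
# total CCF; a parent must precede its child in that order)
enumerate_feasible_trees <- function(ccf, tol = 0.05) {
  ord <- order(-rowSums(ccf))
  cc <- ccf[ord, , drop = FALSE]
  K <- nrow(cc)
  if (K == 1L) return(list(list(parent = stats::setNames(0L, rownames(cc)))))
  choices <- lapply(seq_len(K - 1L) + 1L, function(i) seq_len(i - 1L))
  grids <- expand.grid(choices)
  out <- list()
  for (r in seq_len(nrow(grids))) {
    par <- c(0L, as.integer(grids[r, ]))
    ok <- TRUE
    for (p in seq_len(K)) {
      ch <- which(par == p)
      if (!length(ch)) next
      if (any(cc[ch, , drop = FALSE] > matrix(cc[p, ], length(ch), ncol(cc),
                                              byrow = TRUE) + tol) ||
          any(colSums(cc[ch, , drop = FALSE]) > cc[p, ] + tol)) {
        ok <- FALSE; break
      }
    }
    if (ok) out[[length(out) + 1L]] <- list(parent = stats::setNames(par, rownames(cc)))
  }
  out
}

# acceptance benchmark world: 6 clones over a tree, 4 samples, every clone
# pair separated by >= 0.1 CCF in at least two samples (identifiability),
# and a diagnostic sample carrying 0.20 / 0.75 subclones
bench6_config <- function(n_per = 120L) {
  samples <- sample_meta(paste0("s", 1:4), purity = 0.9)
  nodes <- c("A", "B", "C", "D", "E", "F")
  parent <- stats::setNames(c(0L, 1L, 1L, 3L, 3L, 3L), nodes)
  ccf <- rbind(A = c(1, 1, 1, 1), B = c(0.20, 0, 0, 0),
               C = c(0.75, 0.85, 0.80, 0.75),
               D = c(0, 0.80, 0.10, 0), E = c(0, 0, 0.70, 0.10),
               F = c(0, 0, 0, 0.65))
  colnames(ccf) <- samples$sample_id
  simulation_config(samples, parent, ccf,
                    branch_n = stats::setNames(rep(n_per, 6L), nodes),
                    branch_sig = matrix(c(0.35, 0.65, 0), 6, 3, byrow = TRUE,
                                        dimnames = list(nodes, NULL)),
                    depth = 100, eps = 1.6e-4, rho = 0.01, n_panel = 2L)
}

# exposure truth for the signature recovery benchmark: one near-pure branch
# per signature plus three mixtures (anchors make the factorization
# identifiable; see the methods vignette)
bench_exposures <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(0.5, 0.5, 0), c(0.1, 0.45, 0.45), c(0.3, 0.2, 0.5))
}

# map clusters to truth nodes by CCF distance and compare tree topologies
topology_matches <- function(tree, truth_parent, truth_ccf, est_ccf) {
  if (nrow(est_ccf) != nrow(truth_ccf)) return(FALSE)
  if (length(tree$parent) != nrow(truth_ccf)) return(FALSE)
  map <- apply(est_ccf, 1L, function(x)
    which.min(colSums((t(truth_ccf) - x)^2)))          # est name -> truth idx
  names(map) <- rownames(est_ccf)
  if (length(unique(map)) != nrow(truth_ccf)) return(FALSE)
  for (nm in names(tree$parent)) {
    want_truth_parent <- truth_parent[[map[[nm]]]]
    got_parent <- tree$parent[[nm]]
    if (want_truth_parent == 0L) {
      if (got_parent != 0L) return(FALSE)
    } else {
      if (got_parent == 0L) return(FALSE)
      got_parent_nm <- names(tree$parent)[got_parent]
      if (map[[got_parent_nm]] != want_truth_parent) return(FALSE)
    }
  }
  TRUE
}
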