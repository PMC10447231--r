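tree_tol_default <- function() 0.05

#' Expected variant allele frequency of a clone
#'
#' Maps a cancer-cell fraction to the expected VAF given purity, local copy
#' number and mutant multiplicity:
#' `xi = purity*ccf*m / (purity*(n_major+n_minor) + (1-purity)*2)`,
#' clipped to `[0, 1)`.
#'
#' @param ccf Cancer-cell fraction (>= 0).
#' @param purity Tumor purity in (0, 1].
#' @param n_major,n_minor Allele-specific copy numbers.
#' @param m Mutant-allele multiplicity (>= 1).
#' @export
expected_vaf <- function(ccf, purity, n_major = 1L, n_minor = 1L, m = 1L) {
  stopifnot(all(ccf >= 0), all(purity > 0), all(purity <= 1))
  xi <- purity * ccf * m / (purity * (n_major + n_minor) + (1 - purity) * 2)
  pmin(pmax(xi, 0), 1 - 1e-12)
}

#' Sampler configuration for Dirichlet-process clustering
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Discarded iterations (`burn_in < n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param conc_shape,conc_rate Gamma prior on the DP concentration.
#' @param max_clusters Stick-breaking truncation.
#' @param grid_size Number of CCF grid points on `[0, ccf_max]`.
#' @param ccf_max Upper CCF bound (slack above 1 absorbs noise).
#' @param xi_floor Emission floor on the expected VAF (absorbs background
#'   sequencing error for CCF-0 clusters).
#' @param overdispersion Beta-binomial overdispersion of the read emission
#'   model; 0 recovers the pure binomial emission.
#' @param min_cluster_frac Clusters holding fewer than this fraction of
#'   mutations are merged into their nearest neighbour.
#' @param init_sweeps Hard-EM sweeps before sampling.
#' @param seed Integer seed; same seed gives bit-identical results.
#' @export
cluster_config <- function(n_iter = 2000L, burn_in = 1000L, thin = 2L,
                           conc_shape = 1, conc_rate = 1,
                           max_clusters = 30L, grid_size = 121L,
                           ccf_max = 1.2, xi_floor = 1e-4,
                           overdispersion = 0.01,
                           min_cluster_frac = 0.01, init_sweeps = 10L,
                           seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), conc_shape = conc_shape,
                 conc_rate = conc_rate, max_clusters = as.integer(max_clusters),
                 grid_size = as.integer(grid_size), ccf_max = ccf_max,
                 xi_floor = xi_floor, overdispersion = overdispersion,
                 min_cluster_frac = min_cluster_frac,
                 init_sweeps = as.integer(init_sweeps), seed = as.integer(seed)),
            class = "cluster_config")
}

# Build the per-(site, sample) CCF->VAF coefficient matrix A, its unique-row
# grouping, and the usable-site mask. Sites on sex chromosomes are excluded
# from sampling (mis-specified emission under unknown X/Y state) and
# reassigned post hoc by maximum likelihood.
.prep_observations <- function(counts, segments = NULL, multiplicity = NULL) {
  ns <- nrow(counts$sites); nk <- nrow(counts$samples)
  A <- matrix(0, ns, nk)
  for (s in seq_len(nk)) {
    if (!is.null(segments)) {
      cn <- lookup_cn(segments, counts$samples$sample_id[s],
                      counts$sites$chrom, counts$sites$pos)
    } else {
      cn <- data.frame(n_major = rep(1L, ns), n_minor = rep(1L, ns))
    }
    m <- if (is.null(multiplicity)) 1L else multiplicity[, s]
    A[, s] <- expected_vaf(1, counts$samples$purity[s],
                           cn$n_major, cn$n_minor, m)
  }
  zero_depth <- rowSums(counts$depth) == 0L
  if (any(zero_depth))
    stop("mutation(s) with zero depth in every sample: rows ",
         paste(utils::head(which(zero_depth), 5L), collapse = ", "))
  sex <- counts$sites$chrom %in% c("X", "Y", "chrX", "chrY")
  key <- apply(round(A, 10), 1L, paste, collapse = ",")
  grp <- as.integer(factor(key, levels = unique(key)))
  Au <- A[!duplicated(key), , drop = FALSE]
  if (is.null(dim(Au))) Au <- matrix(Au, nrow = 1L)
  list(A = A, Au = Au, grp = grp, usable = !sex)
}

#' Cluster mutations with a Dirichlet-process binomial mixture
#'
#' Runs a truncated stick-breaking Gibbs sampler over per-sample
#' (beta-)binomial emissions in CCF space, resolves label switching through
#' the posterior
#' co-clustering matrix (average-linkage hierarchical cut selected by
#' maximum posterior expected adjusted Rand), then consolidates the cut by
#' soft-EM polish: clusters under `min_cluster_frac` are dissolved,
#' superclonal duplicates (indistinguishable once CCF is clamped to 1)
#' merge, and nearby pairs merge unless a mixture likelihood-ratio supports
#' the split. Deterministic given `cfg$seed`.
#'
#' @param counts A [count_matrix()] of force-called mutations.
#' @param segments Optional [cn_segments()] used to set per-site expected
#'   VAF coefficients.
#' @param cfg A [cluster_config()].
#' @param psm_max_sites Above this many usable sites the co-clustering
#'   skeleton is built on a seeded subsample and remaining mutations are
#'   assigned by maximum likelihood.
#' @return Object of class `clone_clusters`: list with `ccf` (K x S matrix),
#'   `assignment`, `posterior`, `n_assigned`, `diagnostics`.
#' @export
gibbs_cluster <- function(counts, segments = NULL, cfg = cluster_config(),
                          psm_max_sites = 4000L) {
  pr <- .prep_observations(counts, segments)
  use <- which(pr$usable)
  if (!length(use)) stop("no usable mutations after preprocessing")
  grid <- seq(0, cfg$ccf_max, length.out = cfg$grid_size)

  # Per-sample emission log-likelihood tables over all sites:
  # M[[s]][i, j] = log p(v[i,s] | cluster CCF at grid point j), under a
  # beta-binomial with mean expected_vaf and the configured overdispersion
  # (exactly binomial at overdispersion 0). The sampler, the soft-EM polish
  # and the final assignment are all lookups into these tables.
  S <- ncol(counts$var_reads)
  M <- vector("list", S)
  for (s in seq_len(S)) {
    Ms <- matrix(0, nrow(counts$sites), cfg$grid_size)
    for (j in seq_len(cfg$grid_size)) {
      mu <- pmin(pmax(pr$A[, s] * grid[j], cfg$xi_floor), 1 - 1e-9)
      Ms[, j] <- dbetabinom_log(counts$var_reads[, s], counts$depth[, s],
                                mu, cfg$overdispersion)
    }
    M[[s]] <- Ms
  }
  Mcube <- array(0, dim = c(length(use), cfg$grid_size, S))
  for (s in seq_len(S)) Mcube[, , s] <- M[[s]][use, , drop = FALSE]

  set.seed(cfg$seed)
  fit <- .gibbs_dp_cpp(Mcube, cfg$max_clusters, cfg$n_iter, cfg$burn_in,
                       cfg$thin, cfg$conc_shape, cfg$conc_rate,
                       cfg$init_sweeps, 4L)
  rm(Mcube)

  n <- length(use)
  sub <- seq_len(n)
  if (n > psm_max_sites) sub <- sort(sample.int(n, psm_max_sites))
  psm <- .psm_cpp(fit$draws[, sub, drop = FALSE])
  hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
  memb <- .maxpear_cut(psm, hc)

  # Soft EM over grid-indexed cluster CCFs (jmat: K x S grid indices).
  em_polish <- function(jmat, w, steps = 30L) {
    idx <- use
    K <- nrow(jmat)
    estep <- function() {
      L <- matrix(0, length(idx), K)
      for (s in seq_len(S))
        L <- L + M[[s]][idx, jmat[, s], drop = FALSE]
      lp <- L + matrix(log(pmax(w, 1e-12)), length(idx), K, byrow = TRUE)
      mx <- do.call(pmax, as.data.frame(lp))
      post <- exp(lp - mx)
      rs <- rowSums(post)
      list(post = post / rs, ll = sum(mx + log(rs)))
    }
    for (st in seq_len(steps)) {
      e <- estep()
      w <- colMeans(e$post)
      for (s in seq_len(S)) {
        gll <- crossprod(M[[s]][idx, , drop = FALSE], e$post)  # grid x K
        jmat[, s] <- max.col(t(gll), ties.method = "first")
      }
    }
    e <- estep()
    list(jmat = jmat, w = w, post = e$post, ll = e$ll,
         hard = max.col(e$post, ties.method = "first"))
  }

  # initial model from the co-clustering cut
  groups <- sort(unique(memb))
  jmat <- matrix(1L, length(groups), S)
  for (gi in seq_along(groups)) {
    idx_g <- use[sub[memb == groups[gi]]]
    for (s in seq_len(S))
      jmat[gi, s] <- which.max(colSums(M[[s]][idx_g, , drop = FALSE]))
  }
  w <- as.numeric(table(factor(memb, levels = groups))) / length(memb)
  cur <- em_polish(jmat, w)

  # Consolidation. Three rules, re-applied to convergence:
  #  (i) clusters holding < min_cluster_frac of the mutations are dissolved;
  #  (ii) clusters indistinguishable after clamping CCF to [0, 1]
  #       (superclonal slack is noise, not evidence of separation) merge
  #       when within merge_tol in every sample;
  #  (iii) nearby pairs merge unless the split is supported by a soft
  #       mixture likelihood-ratio of at least lrt_keep (fragments of one
  #       clone cost ~nothing to merge; clones separated by >= 0.1 CCF at
  #       100x cost hundreds of log-units).
  merge_tol <- tree_tol_default()
  lrt_keep <- 15 + 5 * (S + 1)   # scales with the split's free parameters
  merged_model <- function(cur, a, b) {
    keep <- setdiff(seq_len(nrow(cur$jmat)), b)
    jm <- cur$jmat[keep, , drop = FALSE]
    wn <- cur$w[keep]
    ai <- match(a, keep)
    wn[ai] <- cur$w[a] + cur$w[b]
    em_polish(jm, wn / sum(wn))
  }
  repeat {
    K <- nrow(cur$jmat)
    if (K <= 1L) break
    drop_pair <- NULL
    small <- which(cur$w < cfg$min_cluster_frac)
    if (length(small)) {
      b <- small[which.min(cur$w[small])]
      cc <- pmin(grid[cur$jmat], 1); dim(cc) <- dim(cur$jmat)
      Dm <- as.matrix(stats::dist(cc, method = "maximum"))
      diag(Dm) <- Inf
      a <- which.min(Dm[b, ])
      cur <- merged_model(cur, a, b)
      next
    }
    cc <- pmin(grid[cur$jmat], 1); dim(cc) <- dim(cur$jmat)
    Dm <- as.matrix(stats::dist(cc, method = "maximum"))
    diag(Dm) <- Inf
    if (min(Dm) <= merge_tol) {
      pair <- which(Dm == min(Dm), arr.ind = TRUE)[1L, ]
      pair <- sort(unname(pair))
      cur <- merged_model(cur, pair[1L], pair[2L])
      next
    }
    Dmean <- as.matrix(stats::dist(cc, method = "manhattan")) / S
    diag(Dmean) <- Inf
    cand <- which(Dmean <= 0.5 & upper.tri(Dmean), arr.ind = TRUE)
    if (!nrow(cand)) break
    cand <- cand[order(Dmean[cand]), , drop = FALSE]
    best <- NULL; best_lrt <- Inf
    for (ci in seq_len(min(nrow(cand), 8L))) {
      a <- cand[ci, 1L]; b <- cand[ci, 2L]
      mm <- merged_model(cur, a, b)
      lrt <- 2 * (cur$ll - mm$ll)
      if (lrt < best_lrt) { best_lrt <- lrt; best <- mm }
    }
    if (best_lrt < lrt_keep) cur <- best else break
  }

  # order by mean CCF and assign every site (incl. excluded ones, post hoc)
  ccf <- matrix(grid[cur$jmat], nrow(cur$jmat), S)
  ord <- order(-rowMeans(ccf))
  ccf <- ccf[ord, , drop = FALSE]
  jmat <- cur$jmat[ord, , drop = FALSE]
  w <- cur$w[ord]
  Nall <- nrow(counts$sites)
  L <- matrix(0, Nall, nrow(jmat))
  for (s in seq_len(S)) L <- L + M[[s]][, jmat[, s], drop = FALSE]
  lp <- L + matrix(log(pmax(w, 1e-12)), Nall, nrow(jmat), byrow = TRUE)
  mx <- do.call(pmax, as.data.frame(lp))
  posterior <- exp(lp - mx)
  posterior <- posterior / rowSums(posterior)
  assignment <- max.col(posterior, ties.method = "first")
  excl <- which(!pr$usable)
  rownames(ccf) <- paste0("C", seq_len(nrow(ccf)))
  colnames(ccf) <- counts$samples$sample_id
  structure(list(ccf = ccf, assignment = assignment, posterior = posterior,
                 n_assigned = tabulate(assignment, nrow(ccf)),
                 diagnostics = list(loglik = fit$loglik,
                                    init_loglik = fit$init_loglik,
                                    k_occupied = fit$k_occupied,
                                    alpha = fit$alpha,
                                    excluded_sites = excl)),
            class = "clone_clusters")
}

# Cut the co-clustering dendrogram at the number of groups maximizing the
# posterior expected adjusted Rand index (maxpear; Fritsch & Ickstadt 2009).
.maxpear_cut <- function(psm, hc, kmax = 25L) {
  n <- nrow(psm)
  kmax <- min(kmax, n)
  off <- (sum(psm) - n) / 2            # sum of psi over i<j
  Cn <- n * (n - 1) / 2
  best <- NULL; best_pear <- -Inf
  for (k in seq_len(kmax)) {
    memb <- stats::cutree(hc, k = k)
    sI <- 0; sIpsi <- 0
    for (g in unique(memb)) {
      idx <- which(memb == g)
      m <- length(idx)
      if (m < 2L) next
      sI <- sI + m * (m - 1) / 2
      sIpsi <- sIpsi + (sum(psm[idx, idx]) - m) / 2
    }
    expct <- sI * off / Cn
    denom <- (sI + off) / 2 - expct
    pear <- if (abs(denom) < 1e-12) 0 else (sIpsi - expct) / denom
    if (pear > best_pear) { best_pear <- pear; best <- memb }
  }
  best
}

#' @export
print.clone_clusters <- function(x, ...) {
  cat(sprintf("clone_clusters: %d clusters x %d samples\n",
              nrow(x$ccf), ncol(x$ccf)))
  print(round(x$ccf, 3))
  invisible(x)
}

#' Single-sample Dirichlet-process clustering
#'
#' @param counts A [count_matrix()].
#' @param sample_id The sample to cluster within.
#' @param segments,cfg As in [gibbs_cluster()].
#' @export
cluster_1d <- function(counts, sample_id, segments = NULL,
                       cfg = cluster_config()) {
  gibbs_cluster(subset_counts(counts, j = sample_id), segments, cfg)
}

#' Merge a core clustering with per-time-point enrichment runs
#'
#' The core run defines the cluster skeleton over the shared mutation
#' universe. An enrichment run may split a core cluster only when it
#' partitions that cluster's mutations into groups (each of at least
#' `min_split` mutations) whose CCF centroids, in some enrichment sample,
#' differ by more than `split_threshold`. Output labels are renumbered
#' deterministically; input label identities never matter.
#'
#' @param core A `clone_clusters` (or plain assignment vector).
#' @param enrichment_runs List of `clone_clusters` over the same mutation
#'   universe (possibly different sample subsets).
#' @param enrichment_ccfs List (parallel to `enrichment_runs`) of per-mutation
#'   CCF matrices, or `NULL` to use each run's cluster CCFs.
#' @param split_threshold CCF separation required to accept a split.
#' @param min_split Minimum group size for an accepted split.
#' @return List with `assignment` (integer vector) and `mapping` (data.frame
#'   recording which core clusters were split by which run).
#' @export
consensus_clustering <- function(core, enrichment_runs,
                                 enrichment_ccfs = NULL,
                                 split_threshold = 0.1, min_split = 5L) {
  base <- if (is.list(core)) as.integer(core$assignment) else as.integer(core)
  n <- length(base)
  out <- match(base, sort(unique(base)))   # label-invariant renumbering
  mapping <- data.frame(core_cluster = integer(), run = integer(),
                        n_groups = integer())
  for (r in seq_along(enrichment_runs)) {
    run <- enrichment_runs[[r]]
    ra <- if (is.list(run)) as.integer(run$assignment) else as.integer(run)
    if (length(ra) != n) stop("enrichment run ", r,
                              " has a different mutation universe")
    ccfs <- if (inherits(run, "clone_clusters")) run$ccf else enrichment_ccfs[[r]]
    for (k in sort(unique(out))) {
      idx <- which(out == k)
      sub <- ra[idx]
      tab <- table(sub)
      big <- as.integer(names(tab)[tab >= min_split])
      if (length(big) < 2L) next
      cent <- ccfs[big, , drop = FALSE]
      sep <- 0
      for (a in seq_len(nrow(cent) - 1L))
        for (b in seq(a + 1L, nrow(cent)))
          sep <- max(sep, max(abs(cent[a, ] - cent[b, ])))
      if (sep > split_threshold) {
        new_base <- max(out) + 1L
        grp <- match(sub, big)
        keepers <- !is.na(grp) & grp > 1L
        out[idx[keepers]] <- new_base + grp[keepers] - 2L
        mapping <- rbind(mapping,
                         data.frame(core_cluster = k, run = r,
                                    n_groups = length(big)))
      }
    }
  }
  list(assignment = match(out, sort(unique(out))), mapping = mapping)
}

#' Adjusted Rand index between two partitions
#' @param a,b Integer label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expct) return(1)
  (sij - expct) / (mx - expct)
}

#' Write cluster and assignment tables
#' @param clusters A `clone_clusters`.
#' @param cluster_path,assign_path Output TSV paths.
#' @export
write_clusters <- function(clusters, cluster_path, assign_path) {
  ct <- data.frame(cluster = rownames(clusters$ccf),
                   n_mutations = clusters$n_assigned)
  ct <- cbind(ct, as.data.frame(clusters$ccf))
  data.table::fwrite(ct, cluster_path, sep = "\t")
  at <- data.frame(site = seq_along(clusters$assignment),
                   cluster = clusters$assignment,
                   posterior = clusters$posterior[
                     cbind(seq_along(clusters$assignment),
                           clusters$assignment)])
  data.table::fwrite(at, assign_path, sep = "\t")
  invisible(cluster_path)
}
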