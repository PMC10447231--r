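#' Define the diploid SNV site set of a lineage branch
#'
#' Takes the SNVs assigned to one branch of the clone tree and keeps those
#' lying in regions that are diploid heterozygous (major/minor = 1/1) in all
#' query samples — e.g. excluding sites on a lost 17p arm in the samples
#' that carry the loss. Exclusions are itemized with reasons.
#'
#' @param sites A `variant_sites` data.frame for the whole study.
#' @param assignment Branch/cluster label per site.
#' @param branch Branch id whose sites define the lineage.
#' @param segments A [cn_segments()] table.
#' @param query_samples Sample ids the set will be queried in.
#' @return Object of class `lineage_site_set`: list with `branch`,
#'   `site_idx`, `excluded` (data.frame index + reason), `n_sites`.
#' @export
define_site_set <- function(sites, assignment, branch, segments,
                            query_samples) {
  lab <- as.character(assignment)
  idx <- which(lab == as.character(branch) & sites$var_class == "SNV")
  if (!length(idx)) stop("branch ", branch, " has no SNVs")
  excl <- data.frame(index = integer(), reason = character())
  keep <- rep(TRUE, length(idx))
  for (s in query_samples) {
    cn <- lookup_cn(segments, s, sites$chrom[idx], sites$pos[idx])
    bad <- !(cn$n_major == 1L & cn$n_minor == 1L)
    if (any(bad & keep)) {
      excl <- rbind(excl, data.frame(index = idx[bad & keep],
                                     reason = paste0("non-diploid in ", s)))
      keep <- keep & !bad
    }
  }
  if (!any(keep)) stop("no diploid sites remain for branch ", branch)
  structure(list(branch = branch, site_idx = idx[keep], excluded = excl,
                 n_sites = sum(keep)), class = "lineage_site_set")
}

#' Estimate the aggregate background error rate from a panel
#'
#' Interrogates the lineage site set in unrelated (panel) samples presumed
#' not to carry the lineage: per panel sample the aggregate rate is
#' `sum(V)/sum(D)` over the sites; the model's epsilon is the mean of the
#' per-sample rates, with the full distribution retained for diagnostics.
#'
#' @param site_set A [define_site_set()] result, or an integer site index
#'   vector.
#' @param panel_counts A [count_matrix()] over the same site universe.
#' @return Object of class `background_error_model`: `eps`, `per_sample`,
#'   `n_panel`, `pooled`.
#' @export
estimate_background <- function(site_set, panel_counts) {
  idx <- if (inherits(site_set, "lineage_site_set")) site_set$site_idx else site_set
  V <- colSums(panel_counts$var_reads[idx, , drop = FALSE])
  D <- colSums(panel_counts$depth[idx, , drop = FALSE])
  drop <- D == 0
  if (any(drop)) {
    warning(sum(drop), " panel sample(s) with zero depth dropped")
    V <- V[!drop]; D <- D[!drop]
  }
  if (!length(V)) stop("all panel samples have zero aggregate depth")
  rates <- V / D
  eps <- mean(rates)
  if (eps == 0) warning("panel error rate is exactly 0: detection test degenerates")
  if (eps > 0.01) stop("panel error rate ", signif(eps, 3),
                       " implausibly high (> 0.01): check panel")
  structure(list(eps = eps, per_sample = rates, n_panel = length(rates),
                 pooled = sum(V) / sum(D)), class = "background_error_model")
}

#' One-sided aggregated-count test for lineage presence
#'
#' Tests whether the aggregate variant reads `V` over the lineage site set
#' in one sample exceed what the background error rate explains:
#' `p = P(X >= V)` for `X ~ Binomial(D, eps)`, exact in log space. The VAF
#' maximum-likelihood estimate is `V/D` with an exact Clopper-Pearson 95%
#' CI, and the clone size is `min(1, 2*VAF)` (diploid heterozygous sites),
#' with the CI transformed identically.
#'
#' @param V,D Aggregate variant reads and depth.
#' @param model A [estimate_background()] result (or a bare epsilon).
#' @param sample_id Label carried into the result.
#' @return Object of class `lineage_test`, a one-row data.frame.
#' @export
detect_lineage <- function(V, D, model, sample_id = NA_character_) {
  eps <- if (inherits(model, "background_error_model")) model$eps else model
  if (D <= 0) stop("aggregate depth must be positive")
  if (V < 0 || V > D) stop("need 0 <= V <= D")
  if (eps == 0) {
    if (V > 0) {
      warning("degenerate null (eps = 0) with V > 0: p reported as 0")
      p <- 0; logp <- -Inf
    } else { p <- 1; logp <- 0 }
  } else {
    logp <- pbetabinom_upper(V, D, eps, 0, log.p = TRUE)
    p <- exp(logp)
  }
  ci <- clopper_pearson(V, D)
  vaf <- V / D
  out <- data.frame(sample_id = sample_id, V = V, D = D, eps = eps,
                    p_value = p, log10_p = logp / log(10),
                    vaf_mle = vaf, ci_low = ci[["lower"]], ci_high = ci[["upper"]],
                    clone_size = min(1, 2 * vaf),
                    clone_low = min(1, 2 * ci[["lower"]]),
                    clone_high = min(1, 2 * ci[["upper"]]),
                    stringsAsFactors = FALSE)
  class(out) <- c("lineage_test", "data.frame")
  out
}

#' Track a lineage across all samples of a study
#'
#' Aggregates the site set per sample, runs [detect_lineage()] for each, and
#' assigns significance stars at the conventional figure thresholds
#' (`***` for p < 0.001, `**` < 0.01, `*` < 0.05).
#'
#' @param site_set A [define_site_set()] result or site index vector.
#' @param counts A [count_matrix()] covering all sites and samples.
#' @param model A [estimate_background()] result.
#' @param outlier_frac Any single site contributing more than this fraction
#'   of a sample's aggregate V is reported in the `outliers` attribute.
#' @return data.frame of class `lineage_test`, one row per sample, input
#'   sample order preserved.
#' @export
track_lineage_timecourse <- function(site_set, counts, model,
                                     outlier_frac = 0.05) {
  idx <- if (inherits(site_set, "lineage_site_set")) site_set$site_idx else site_set
  if (any(idx > nrow(counts$sites)))
    stop("sites missing from counts: ",
         paste(utils::head(idx[idx > nrow(counts$sites)], 5L), collapse = ", "))
  res <- lapply(seq_len(nrow(counts$samples)), function(s) {
    detect_lineage(sum(counts$var_reads[idx, s]), sum(counts$depth[idx, s]),
                   model, counts$samples$sample_id[s])
  })
  out <- do.call(rbind, res)
  out$stars <- ifelse(out$p_value < 0.001, "***",
               ifelse(out$p_value < 0.01, "**",
               ifelse(out$p_value < 0.05, "*", "")))
  outliers <- list()
  for (s in seq_len(nrow(counts$samples))) {
    Vtot <- sum(counts$var_reads[idx, s])
    if (Vtot == 0) next
    frac <- counts$var_reads[idx, s] / Vtot
    o <- which(frac > outlier_frac)
    if (length(o))
      outliers[[counts$samples$sample_id[s]]] <-
        data.frame(site = idx[o], frac = frac[o])
  }
  attr(out, "outliers") <- outliers
  class(out) <- c("lineage_test", "data.frame")
  out
}

#' Write a lineage timecourse result as TSV
#' @param result A `lineage_test` data.frame.
#' @param path Output path.
#' @export
write_lineage_result <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  invisible(path)
}
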