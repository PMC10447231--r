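#' Configuration for post-calling variant filters
#'
#' Defaults mirror standard WGS practice for BWA-MEM/CaVEMan output: retain a
#' variant when the median alignment score of its supporting reads is at
#' least 140 (`asmd_min`) and no more than the allowed fraction of supporting
#' reads is clipped (`clpm_max = 0`); remove germline variants at
#' Benjamini-Hochberg `q < 1e-5`; call presence per sample at `q < 1e-3`
#' under the site error model.
#'
#' @param asmd_min Minimum ASMD.
#' @param clpm_max Maximum CLPM.
#' @param germline_q_cutoff BH q cutoff below which a site is called somatic.
#' @param presence_alpha BH q cutoff for per-sample presence.
#' @param missing_annotation `"retain"` (with warning) or `"reject"` for
#'   sites lacking ASMD/CLPM.
#' @export
filter_config <- function(asmd_min = 140, clpm_max = 0,
                          germline_q_cutoff = 1e-5, presence_alpha = 1e-3,
                          missing_annotation = c("retain", "reject")) {
  missing_annotation <- match.arg(missing_annotation)
  stopifnot(is.finite(asmd_min), is.finite(clpm_max),
            germline_q_cutoff > 0, germline_q_cutoff < 1,
            presence_alpha > 0, presence_alpha < 1)
  structure(list(asmd_min = asmd_min, clpm_max = clpm_max,
                 germline_q_cutoff = germline_q_cutoff,
                 presence_alpha = presence_alpha,
                 missing_annotation = missing_annotation),
            class = "filter_config")
}

#' Apply mapping-artifact quality filters
#'
#' A site is retained iff `ASMD >= asmd_min` and `CLPM <= clpm_max`. Sites
#' with missing annotations are retained with a warning (or rejected, per
#' `cfg$missing_annotation`); every rejection is logged with its reason.
#'
#' @param sites A `variant_sites` data.frame (ASMD/CLPM columns optional).
#' @param cfg A [filter_config()].
#' @return List with `retained` (sites subset) and `rejections` (data.frame
#'   of row index + reason).
#' @export
apply_quality_filters <- function(sites, cfg = filter_config()) {
  n <- nrow(sites)
  asmd <- if ("ASMD" %in% names(sites)) sites$ASMD else rep(NA_real_, n)
  clpm <- if ("CLPM" %in% names(sites)) sites$CLPM else rep(NA_real_, n)
  miss <- is.na(asmd) | is.na(clpm)
  if (any(miss)) {
    if (cfg$missing_annotation == "retain")
      warning(sum(miss), " site(s) missing ASMD/CLPM retained by policy")
  }
  fail_asmd <- !is.na(asmd) & asmd < cfg$asmd_min
  fail_clpm <- !is.na(clpm) & clpm > cfg$clpm_max
  reject <- fail_asmd | fail_clpm |
    (miss & cfg$missing_annotation == "reject")
  reason <- character(n)
  reason[fail_clpm] <- "CLPM"
  reason[fail_asmd] <- "ASMD"                      # ASMD takes precedence in the log
  reason[miss & cfg$missing_annotation == "reject"] <- "missing_annotation"
  list(retained = sites[!reject, , drop = FALSE],
       rejections = data.frame(index = which(reject),
                               reason = reason[reject],
                               stringsAsFactors = FALSE))
}

#' One-sided exact binomial test against heterozygous germline
#'
#' Under a heterozygous germline variant in largely diploid samples the
#' aggregated variant-read fraction is 1/2; a small lower-tail probability
#' `P(X <= v)` under `Binomial(d, 0.5)` is evidence the site is somatic.
#'
#' @param v_agg,d_agg Aggregated variant reads and depth.
#' @return The exact lower-tail p-value.
#' @export
germline_test <- function(v_agg, d_agg) {
  stopifnot(length(v_agg) == length(d_agg))
  if (any(v_agg < 0 | v_agg > d_agg)) stop("need 0 <= v <= d")
  p <- stats::pbinom(v_agg, d_agg, 0.5)
  if (any(d_agg == 0)) {
    warning("d = 0: germline test undefined, returning p = 1")
    p[d_agg == 0] <- 1
  }
  p
}

#' Classify sites as germline or somatic
#'
#' Aggregates counts across the designated largely-diploid samples, applies
#' [germline_test()] per site and Benjamini-Hochberg correction over all
#' sites; a site is somatic iff `q < cfg$germline_q_cutoff`.
#'
#' @param counts A [count_matrix()].
#' @param diploid_samples Sample ids to aggregate over. Default: tumor
#'   samples with ploidy in `[1.8, 2.2]`.
#' @param cfg A [filter_config()].
#' @return data.frame with `p`, `q`, `label` per site.
#' @export
classify_germline <- function(counts, diploid_samples = NULL,
                              cfg = filter_config()) {
  if (is.null(diploid_samples)) {
    sm <- counts$samples
    diploid_samples <- sm$sample_id[sm$role == "tumor" &
                                    sm$ploidy >= 1.8 & sm$ploidy <= 2.2]
  }
  if (!length(diploid_samples)) stop("no diploid samples designated")
  j <- match(diploid_samples, counts$samples$sample_id)
  if (anyNA(j)) stop("unknown sample id in diploid_samples")
  if (nrow(counts$sites) == 0L)
    return(data.frame(p = numeric(), q = numeric(), label = character()))
  v <- rowSums(counts$var_reads[, j, drop = FALSE])
  d <- rowSums(counts$depth[, j, drop = FALSE])
  p <- suppressWarnings(germline_test(v, d))
  p[d == 0] <- 1
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q,
             label = ifelse(q < cfg$germline_q_cutoff, "somatic", "germline"),
             stringsAsFactors = FALSE)
}

#' Fit a beta-binomial site-specific error model
#'
#' For each site, `(eps_i, rho_i)` maximize the beta-binomial likelihood of
#' the counts in the designated negative samples (samples presumed not to
#' carry the variant): a profile-likelihood grid over rho (0 plus 25
#' log-spaced points in `[1e-4, 0.5]`) with a 1-d optimum for eps at each
#' grid point, followed by golden-section refinement of rho. `rho_i` is
#' collapsed to 0 when the binomial fits as well (log-likelihood-ratio below
#' `lrt_tol`).
#'
#' @param counts A [count_matrix()].
#' @param negative_samples Sample ids presumed variant-free. May also be a
#'   logical matrix (sites x samples) for per-site designations.
#' @param lrt_tol Log-likelihood improvement below which rho collapses to 0.
#' @return Object of class `error_model`: data.frame with `eps`, `rho`,
#'   `loglik`, `n_negative`, `low_confidence`.
#' @export
fit_error_model <- function(counts, negative_samples, lrt_tol = 0.5) {
  ns <- nrow(counts$sites)
  if (is.matrix(negative_samples)) {
    neg <- negative_samples
  } else {
    j <- match(negative_samples, counts$samples$sample_id)
    if (anyNA(j)) stop("unknown sample id in negative_samples")
    neg <- matrix(FALSE, ns, nrow(counts$samples))
    neg[, j] <- TRUE
  }
  rho_grid <- c(0, exp(seq(log(1e-4), log(0.5), length.out = 25)))
  out <- data.frame(eps = numeric(ns), rho = numeric(ns), loglik = numeric(ns),
                    n_negative = integer(ns), low_confidence = logical(ns))
  for (i in seq_len(ns)) {
    use <- neg[i, ] & counts$depth[i, ] > 0L
    v <- counts$var_reads[i, use]; d <- counts$depth[i, use]
    out$n_negative[i] <- length(v)
    eps_floor <- 0.5 / (sum(d) + 1)
    if (length(v) < 2L) {
      out$eps[i] <- if (length(v)) max(sum(v) / sum(d), eps_floor) else eps_floor
      out$rho[i] <- 0
      out$loglik[i] <- if (length(v))
        sum(stats::dbinom(v, d, out$eps[i], log = TRUE)) else NA_real_
      out$low_confidence[i] <- TRUE
      next
    }
    # eps spans orders of magnitude: profile on the log scale
    nll_leps <- function(leps, rho) -sum(dbetabinom_log(v, d, exp(leps), rho))
    prof <- function(rho) {
      o <- stats::optimize(nll_leps, log(c(eps_floor, 0.499)), rho = rho)
      c(exp(o$minimum), -o$objective)
    }
    fits <- vapply(rho_grid, prof, numeric(2))
    best <- which.max(fits[2L, ])
    rho_hat <- rho_grid[best]; eps_hat <- fits[1L, best]; ll <- fits[2L, best]
    if (best > 1L) {     # golden-section refine around the grid optimum
      lo <- rho_grid[max(best - 1L, 2L)]; hi <- rho_grid[min(best + 1L, length(rho_grid))]
      o <- stats::optimize(function(r) prof(r)[2L], c(lo, hi), maximum = TRUE)
      if (o$objective > ll) {
        rho_hat <- o$maximum; ll <- o$objective; eps_hat <- prof(rho_hat)[1L]
      }
    }
    ll0 <- fits[2L, 1L]
    if (ll - ll0 <= lrt_tol) {   # binomial fits as well
      rho_hat <- 0; eps_hat <- fits[1L, 1L]; ll <- ll0
    }
    out$eps[i] <- eps_hat; out$rho[i] <- rho_hat; out$loglik[i] <- ll
  }
  class(out) <- c("error_model", "data.frame")
  out
}

#' Call per-sample presence of variants under the site error model
#'
#' For each (site, sample), the one-sided tail `P(X >= v)` under
#' `BetaBinomial(d, eps_i, rho_i)`; presence requires `q < presence_alpha`
#' after Benjamini-Hochberg correction within each sample (and at least one
#' variant read).
#'
#' @param counts A [count_matrix()].
#' @param model An `error_model` from [fit_error_model()].
#' @param cfg A [filter_config()].
#' @return data.frame with site, sample, p, q, present.
#' @export
call_presence <- function(counts, model, cfg = filter_config()) {
  ns <- nrow(counts$sites); nk <- nrow(counts$samples)
  if (nrow(model) != ns) stop("error model not fitted for all sites")
  res <- vector("list", nk)
  for (s in seq_len(nk)) {
    p <- vapply(seq_len(ns), function(i) {
      d <- counts$depth[i, s]; v <- counts$var_reads[i, s]
      if (d == 0L || v == 0L) return(1)
      pbetabinom_upper(v, d, model$eps[i], model$rho[i])
    }, 1)
    q <- stats::p.adjust(p, method = "BH")
    res[[s]] <- data.frame(site = seq_len(ns), sample = counts$samples$sample_id[s],
                           p = p, q = q,
                           present = q < cfg$presence_alpha &
                                     counts$var_reads[, s] > 0L,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Write a filter report TSV (site, test, p, q, label)
#' @param report data.frame as returned by the filtering steps.
#' @param path Output path.
#' @export
write_filter_report <- function(report, path) {
  data.table::fwrite(report, path, sep = "\t")
  invisible(path)
}
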