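#' Per-branch 96-channel mutation spectra
#'
#' Counts the trinucleotide-change channel of every assigned SNV per branch.
#' Branches with fewer than `display_min` SNVs are flagged (they are still
#' computed, and still receive exposure refits, but are excluded from
#' de-novo extraction).
#'
#' @param assignment Vector mapping each mutation to a branch/cluster id.
#' @param channels Integer vector of SBS channel indices (1..96) per
#'   mutation; `NA` (non-SNV or N-context) mutations are skipped.
#' @param display_min Branch display/extraction floor (SNV count).
#' @return Object of class `context_spectra`: counts matrix (branches x 96)
#'   plus `total` and `displayed` per branch.
#' @export
branch_spectra <- function(assignment, channels, display_min = 100L) {
  stopifnot(length(assignment) == length(channels))
  keep <- !is.na(channels) & !is.na(assignment)
  br <- sort(unique(as.character(assignment[keep])))
  counts <- matrix(0L, length(br), 96L,
                   dimnames = list(br, sbs_channels()))
  tb <- table(as.character(assignment[keep]), factor(channels[keep], levels = 1:96))
  counts[rownames(tb), ] <- as.integer(tb)
  structure(list(counts = counts, total = rowSums(counts),
                 displayed = rowSums(counts) >= display_min),
            class = "context_spectra")
}

#' @export
print.context_spectra <- function(x, ...) {
  cat(sprintf("context_spectra: %d branches, %d SNVs total\n",
              nrow(x$counts), sum(x$total)))
  invisible(x)
}

# Successive projection algorithm: greedily pick K near-orthogonal extreme
# rows (anchors) of the row-normalized spectra matrix.
.spa_anchors <- function(Xn, K) {
  R <- Xn
  idx <- integer(K)
  for (k in seq_len(K)) {
    idx[k] <- which.max(rowSums(R^2))
    u <- R[idx[k], ] / sqrt(sum(R[idx[k], ]^2))
    R <- R - as.numeric(R %*% u) %o% u
  }
  idx
}

# KL(X || WH) up to the data-only constant, on positive entries of X.
.kl_div <- function(X, WH) {
  pos <- X > 0
  sum(X[pos] * log(X[pos] / WH[pos])) - sum(X) + sum(WH)
}

#' De-novo mutational-signature extraction
#'
#' Non-negative factorization of the branch x 96 count matrix under the
#' Kullback-Leibler (multinomial) objective with multiplicative updates;
#' `n_restarts` random restarts, best objective kept, deterministic given
#' `seed`. Signature rows are normalized to the simplex with the scale
#' folded into the exposures, which are then row-normalized per branch.
#'
#' @param spectra A [branch_spectra()] result (only `displayed` branches are
#'   used) or a plain counts matrix.
#' @param K Number of signatures.
#' @param seed Integer seed.
#' @param n_restarts,max_iter,tol Optimizer controls.
#' @return List with `signatures` (K x 96 simplex rows), `exposures`
#'   (branches x K, rows summing to 1), `objective`, `objective_trace`.
#' @export
extract_signatures <- function(spectra, K, seed = 1L, n_restarts = 20L,
                               max_iter = 2000L, tol = 1e-8) {
  X <- if (inherits(spectra, "context_spectra"))
    spectra$counts[spectra$displayed, , drop = FALSE] else as.matrix(spectra)
  if (K > nrow(X)) stop("K exceeds the number of usable branches")
  if (sum(X) < K * 50) stop("too few SNVs for a ", K, "-signature extraction")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (r == 1L) {
      # anchor initialization (successive projection on normalized spectra):
      # deterministic, and kept unless a random restart clearly beats it —
      # among likelihood ties it pins the factorization to the data's
      # extreme rays instead of an arbitrary point of the solution set
      anchors <- .spa_anchors(X / pmax(rowSums(X), 1), K)
      H <- X[anchors, , drop = FALSE] / pmax(rowSums(X[anchors, , drop = FALSE]), 1) + 1e-6
      anchor_cat <- signature_catalog(H / rowSums(H), paste0("anchor", seq_len(K)))
      W <- matrix(vapply(seq_len(nrow(X)), function(b)
        fit_exposures(X[b, ], anchor_cat), numeric(K)),
        nrow(X), K, byrow = TRUE) * rowSums(X)
    } else {
      W <- matrix(stats::runif(nrow(X) * K, 0.1, 1), nrow(X), K)
      H <- matrix(stats::runif(K * 96L, 0.1, 1), K, 96L)
    }
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      WH <- W %*% H
      W <- pmax(W * ((X / WH) %*% t(H)) /
                  matrix(rowSums(H), nrow(X), K, byrow = TRUE), 1e-12)
      WH <- W %*% H
      H <- pmax(H * (t(W) %*% (X / WH)) / matrix(colSums(W), K, 96L), 1e-12)
      cur <- .kl_div(X, W %*% H)
      obj <- c(obj, cur)
      if (prev - cur < tol * max(1, abs(cur))) break
      prev <- cur
    }
    margin <- if (is.null(best)) Inf else
      max(1e-3 * abs(best$objective), 1e-6)
    if (is.null(best) || cur < best$objective - margin) {
      best <- list(W = W, H = H, objective = cur, objective_trace = obj)
    }
  }
  scale <- rowSums(best$H)
  sig <- best$H / scale
  expo <- best$W * matrix(scale, nrow(X), K, byrow = TRUE)
  expo <- expo / rowSums(expo)
  ord <- order(-colSums(best$W * matrix(scale, nrow(X), K, byrow = TRUE)))
  sig <- sig[ord, , drop = FALSE]
  expo <- expo[, ord, drop = FALSE]
  rownames(sig) <- colnames(expo) <- paste0("S", seq_len(K))
  colnames(sig) <- sbs_channels()
  rownames(expo) <- rownames(X)
  list(signatures = sig, exposures = expo, objective = best$objective,
       objective_trace = best$objective_trace)
}

#' Choose the number of signatures by BIC on the multinomial likelihood
#'
#' @param spectra As in [extract_signatures()].
#' @param k_range Candidate K values.
#' @param seed Seed forwarded to each extraction.
#' @return The K minimizing BIC, with the BIC table as attribute `"bic"`.
#' @export
select_signature_k <- function(spectra, k_range = 2:6, seed = 1L) {
  X <- if (inherits(spectra, "context_spectra"))
    spectra$counts[spectra$displayed, , drop = FALSE] else as.matrix(spectra)
  n <- sum(X)
  bic <- vapply(k_range, function(k) {
    fit <- extract_signatures(X, k, seed = seed, n_restarts = 5L)
    M <- (fit$exposures * rowSums(X)) %*% fit$signatures
    P <- M / rowSums(M)
    ll <- sum(X * log(pmax(P, 1e-300)))
    df <- k * 95 + nrow(X) * (k - 1)
    -2 * ll + df * log(n)
  }, 1)
  out <- k_range[which.min(bic)]
  attr(out, "bic") <- stats::setNames(bic, k_range)
  out
}

#' Refit exposures of one spectrum against a fixed catalog
#'
#' Maximum-likelihood multinomial mixture weights by EM (equivalently
#' simplex-constrained KL minimization); weights sum to 1.
#'
#' @param spectrum A 96-vector of counts (or a row of a spectra matrix).
#' @param catalog A [signature_catalog()].
#' @param max_iter,tol EM controls.
#' @return Named exposure vector over the catalog's signatures.
#' @export
fit_exposures <- function(spectrum, catalog, max_iter = 5000L, tol = 1e-10) {
  x <- as.numeric(spectrum)
  if (sum(x) <= 0) stop("zero-total spectrum: exposures undefined")
  P <- catalog$probs           # K x 96
  K <- nrow(P)
  w <- rep(1 / K, K)
  for (it in seq_len(max_iter)) {
    mix <- as.numeric(t(P) %*% w)           # 96
    resp <- t(P) * matrix(w, 96L, K, byrow = TRUE) / pmax(mix, 1e-300)
    w_new <- as.numeric(t(resp) %*% x)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  stats::setNames(w, catalog$names)
}

#' Log-likelihood of a spectrum under catalog mixture weights
#' @param spectrum 96-vector of counts.
#' @param catalog A [signature_catalog()].
#' @param w Mixture weights on the simplex.
#' @export
exposure_loglik <- function(spectrum, catalog, w) {
  mix <- as.numeric(t(catalog$probs) %*% (w / sum(w)))
  sum(as.numeric(spectrum) * log(pmax(mix, 1e-300)))
}

#' Cosine similarity of two non-negative vectors
#' @param a,b Numeric vectors.
#' @export
cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Match a signature to the closest catalog entry by cosine similarity
#'
#' @param signature A 96-simplex row.
#' @param catalog A [signature_catalog()].
#' @param ambiguous_margin Flag the match ambiguous when the top two
#'   similarities are within this margin.
#' @return List with `name`, `cosine`, `ambiguous`, `all` (named vector).
#' @export
match_catalog <- function(signature, catalog, ambiguous_margin = 0.02) {
  sims <- apply(catalog$probs, 1L, cosine_sim, b = as.numeric(signature))
  o <- order(-sims)
  list(name = catalog$names[o[1L]], cosine = unname(sims[o[1L]]),
       ambiguous = length(sims) > 1L && sims[o[1L]] - sims[o[2L]] < ambiguous_margin,
       all = stats::setNames(sims, catalog$names))
}

#' Write signatures / exposures tables as TSV
#' @param fit Result of [extract_signatures()].
#' @param sig_path,expo_path Output paths.
#' @export
write_signature_fit <- function(fit, sig_path, expo_path) {
  sg <- data.frame(channel = sbs_channels(), t(fit$signatures))
  data.table::fwrite(sg, sig_path, sep = "\t")
  ex <- data.frame(branch = rownames(fit$exposures), fit$exposures)
  data.table::fwrite(ex, expo_path, sep = "\t")
  invisible(sig_path)
}
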