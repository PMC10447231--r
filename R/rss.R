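#' Build a recombination-signal-sequence position weight matrix
#'
#' An RSS is a conserved heptamer, a fixed-length spacer of 12 or 23 bp, and
#' a nonamer. Column base frequencies come from the supplied aligned
#' heptamer/nonamer sequences plus a pseudocount; spacer columns are uniform
#' (uninformative). The shipped default uses the canonical consensus
#' heptamer `CACAGTG` and nonamer `ACAAAAACC`.
#'
#' @param heptamers,nonamers Character vectors of aligned sequences.
#' @param spacer_len 12 or 23.
#' @param pseudocount Added to every base count.
#' @return Object of class `rss_motif`: list with `pwm` (L x 4 rows summing
#'   to 1), `spacer_len`, `pseudocount`.
#' @export
build_rss_pwm <- function(heptamers = "CACAGTG", nonamers = "ACAAAAACC",
                          spacer_len = c(12L, 23L), pseudocount = 0.25) {
  spacer_len <- as.integer(spacer_len[1L])
  if (!spacer_len %in% c(12L, 23L)) stop("spacer_len must be 12 or 23")
  block_pwm <- function(seqs, width) {
    if (length(unique(nchar(seqs))) != 1L || nchar(seqs[1L]) != width)
      stop("inconsistent block lengths (expected ", width, ")")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    cnt <- vapply(seq_len(width), function(j)
      tabulate(match(m[, j], .BASES), 4L), integer(4))
    t(cnt + pseudocount) / (length(seqs) + 4 * pseudocount)
  }
  pwm <- rbind(block_pwm(heptamers, 7L),
               matrix(0.25, spacer_len, 4L),
               block_pwm(nonamers, 9L))
  colnames(pwm) <- .BASES
  structure(list(pwm = pwm, spacer_len = spacer_len,
                 pseudocount = pseudocount), class = "rss_motif")
}

#' Scan configuration for RSS breakpoint searches
#'
#' @param window Bases scanned on each side of a breakpoint.
#' @param p_cutoff Raw p-value threshold taken as evidence.
#' @param background Zero-order base frequencies (A,C,G,T); `NULL` means
#'   estimate from the scanned windows.
#' @param scan_both_strands Scan the reverse complement too.
#' @param bonferroni Apply a per-scan Bonferroni correction (off by default;
#'   raw p-values match the standard FIMO-style usage).
#' @export
rss_scan_config <- function(window = 50L, p_cutoff = 0.05,
                            background = NULL, scan_both_strands = TRUE,
                            bonferroni = FALSE) {
  if (!is.null(background)) {
    stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  }
  structure(list(window = as.integer(window), p_cutoff = p_cutoff,
                 background = background,
                 scan_both_strands = isTRUE(scan_both_strands),
                 bonferroni = isTRUE(bonferroni)), class = "rss_scan_config")
}

#' Log-likelihood-ratio score of one motif-length window
#'
#' `score = sum over positions of log2(pwm[pos, base] / background[base])`.
#' Windows containing N return `NA` (skipped by the scanner).
#'
#' @param seq Character sequence of exactly the motif length.
#' @param motif An `rss_motif`.
#' @param background 4-vector of base frequencies.
#' @export
score_window <- function(seq, motif, background = rep(0.25, 4)) {
  b <- strsplit(toupper(seq), "")[[1L]]
  L <- nrow(motif$pwm)
  if (length(b) != L) stop("sequence length ", length(b),
                           " does not match motif length ", L)
  idx <- match(b, .BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(log2(motif$pwm[cbind(seq_len(L), idx)] / background[idx]))
}

# Per-position score table (L x 4) in bits.
.score_table <- function(motif, background) {
  log2(motif$pwm / matrix(background, nrow(motif$pwm), 4L, byrow = TRUE))
}

#' Exact p-value of a PWM score under a zero-order background
#'
#' Computes `P(S >= score)` for a random background sequence by dynamic
#' programming over the score distribution. For motifs with `4^L <= 2^20`
#' the DP convolves exact score sums (merging numerically equal values), so
#' the p-value is exact to floating-point accuracy; longer motifs use a
#' discretized convolution with bin width `bin` bits and a documented error
#' bound of `L*bin/2` on the score (the tail is evaluated conservatively at
#' `score - L*bin/2`).
#'
#' @param score Observed score (bits).
#' @param motif An `rss_motif`.
#' @param background 4-vector of base frequencies.
#' @param bin Bin width (bits) for the discretized path.
#' @export
score_pvalue <- function(score, motif, background = rep(0.25, 4),
                         bin = 0.01) {
  st <- .score_table(motif, background)
  L <- nrow(st)
  if (4^L <= 2^20) {
    dist <- data.frame(s = st[1L, ], p = background)
    for (pos in seq_len(L)[-1L]) {
      s <- as.numeric(outer(dist$s, st[pos, ], `+`))
      p <- as.numeric(outer(dist$p, background, `*`))
      o <- order(s)
      s <- s[o]; p <- p[o]
      grpd <- cumsum(c(TRUE, diff(s) > 1e-9))
      dist <- data.frame(s = tapply(s, grpd, `[`, 1L),
                         p = tapply(p, grpd, sum))
    }
    return(min(1, sum(dist$p[dist$s >= score - 1e-9])))
  }
  k <- round(st / bin)
  off <- apply(k, 1L, min)
  span <- sum(apply(k, 1L, max) - off)
  prob <- c(1, numeric(span))
  len <- length(prob)
  for (pos in seq_len(L)) {
    sh <- k[pos, ] - min(k[pos, ])
    new <- numeric(len)
    for (b in 1:4) {
      if (background[b] == 0) next
      m <- len - sh[b]
      new[(1L + sh[b]):len] <- new[(1L + sh[b]):len] +
        prob[seq_len(m)] * background[b]
    }
    prob <- new
  }
  base <- sum(apply(k, 1L, min)) * bin
  scores <- base + (seq_along(prob) - 1L) * bin
  min(1, sum(prob[scores >= score - L * bin / 2 - 1e-12]))
}

#' Scan deletion breakpoints for RSS motifs
#'
#' For each breakpoint side, each motif and each strand, the best-scoring
#' placement whose start lies within `window` bases of the breakpoint is
#' reported with its score and exact p-value; a hit requires
#' `p < cfg$p_cutoff`. Flank sequences come from the breakpoint table
#' itself, or from `ref_seqs` when flanks are missing. The zero-order
#' background is estimated from the scanned windows unless fixed in `cfg`.
#'
#' @param bps A [breakpoint_pairs()] table.
#' @param motifs List of `rss_motif` objects (default: 12- and 23-spacer).
#' @param cfg An [rss_scan_config()].
#' @param ref_seqs Optional reference (`DNAStringSet` or FASTA path).
#' @return data.frame of best placements: breakpoint, side, motif, strand,
#'   offset (of placement start relative to the breakpoint), score, p, hit.
#' @export
scan_breakpoints <- function(bps, motifs = list(build_rss_pwm(spacer_len = 12L),
                                                build_rss_pwm(spacer_len = 23L)),
                             cfg = rss_scan_config(), ref_seqs = NULL) {
  if (!is.null(ref_seqs) && is.character(ref_seqs))
    ref_seqs <- Biostrings::readDNAStringSet(ref_seqs)
  get_flank <- function(i, side) {
    fl <- if (side == "low") bps$flank_low_seq[i] else bps$flank_high_seq[i]
    if (!is.na(fl) && nzchar(fl)) return(fl)
    if (is.null(ref_seqs)) stop("no flank sequence and no reference for breakpoint ", i)
    bp <- if (side == "low") bps$bp_low[i] else bps$bp_high[i]
    nm <- sub("\\s.*$", "", names(ref_seqs))
    j <- match(bps$chrom[i], nm)
    if (is.na(j)) stop("chromosome ", bps$chrom[i], " not in reference")
    lo <- bp - cfg$window; hi <- bp + cfg$window
    if (lo < 1L || hi > Biostrings::width(ref_seqs)[j])
      stop("breakpoint ", i, " window outside reference bounds")
    as.character(Biostrings::subseq(ref_seqs[[j]], lo, hi))
  }
  flanks <- list()
  for (i in seq_len(nrow(bps))) for (side in c("low", "high")) {
    fl <- tryCatch(get_flank(i, side), error = function(e) {
      warning(conditionMessage(e)); NA_character_
    })
    flanks[[paste(i, side)]] <- fl
  }
  bg <- cfg$background
  if (is.null(bg)) {
    all_b <- unlist(strsplit(toupper(unlist(flanks)), ""))
    cnt <- tabulate(match(all_b, .BASES), 4L)
    bg <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(0.25, 4)
    bg <- pmax(bg, 1e-6); bg <- bg / sum(bg)
  }
  strands <- if (cfg$scan_both_strands) c("+", "-") else "+"
  rows <- list()
  for (i in seq_len(nrow(bps))) for (side in c("low", "high")) {
    fl <- flanks[[paste(i, side)]]
    if (is.na(fl)) next
    for (mi in seq_along(motifs)) {
      motif <- motifs[[mi]]
      L <- nrow(motif$pwm)
      if (nchar(fl) < L) {
        warning("window smaller than motif (breakpoint ", i, "): no placements")
        next
      }
      for (strand in strands) {
        s <- if (strand == "+") fl else revcomp_chars(fl)
        n_pl <- nchar(s) - L + 1L
        scs <- vapply(seq_len(n_pl), function(o)
          score_window(substr(s, o, o + L - 1L), motif, bg), 1)
        if (all(is.na(scs))) next
        bi <- which.max(scs)
        p <- score_pvalue(scs[bi], motif, bg)
        if (cfg$bonferroni) p <- min(1, p * n_pl * length(strands))
        offset <- if (strand == "+") bi - 1L - cfg$window else
          nchar(s) - (bi - 1L) - L - cfg$window
        rows[[length(rows) + 1L]] <- data.frame(
          breakpoint = i, chrom = bps$chrom[i], side = side,
          motif = paste0("RSS", motif$spacer_len), strand = strand,
          offset = offset, score = scs[bi], p = p,
          hit = p < cfg$p_cutoff, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(breakpoint = integer(), chrom = character(), side = character(),
               motif = character(), strand = character(), offset = integer(),
               score = numeric(), p = numeric(), hit = logical())
  attr(out, "background") <- bg
  out
}

#' Summarize RSS evidence per deletion
#' @param hits Output of [scan_breakpoints()].
#' @return data.frame with per-breakpoint-pair evidence flags.
#' @export
summarize_rss_evidence <- function(hits) {
  if (!nrow(hits)) return(data.frame(breakpoint = integer(),
                                     low_hit = logical(), high_hit = logical()))
  ag <- stats::aggregate(hit ~ breakpoint + side, data = hits, FUN = any)
  lo <- ag$hit[ag$side == "low"][match(unique(ag$breakpoint),
                                       ag$breakpoint[ag$side == "low"])]
  hi <- ag$hit[ag$side == "high"][match(unique(ag$breakpoint),
                                        ag$breakpoint[ag$side == "high"])]
  data.frame(breakpoint = unique(ag$breakpoint),
             low_hit = ifelse(is.na(lo), FALSE, lo),
             high_hit = ifelse(is.na(hi), FALSE, hi))
}

#' Read and write motifs in MEME minimal format
#'
#' Only the probability-matrix block is used; spacer length is recovered
#' from uniform rows when the motif name encodes it (`RSS12`/`RSS23`).
#'
#' @param motif An `rss_motif`.
#' @param path File path.
#' @param name Motif name written to the file.
#' @export
write_meme_motif <- function(motif, path, name = paste0("RSS", motif$spacer_len)) {
  L <- nrow(motif$pwm)
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
             paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", L),
             apply(motif$pwm, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_meme_motif
#' @export
read_meme_motif <- function(path) {
  lines <- readLines(path)
  mi <- grep("^letter-probability matrix", lines)
  if (!length(mi)) stop("no letter-probability matrix in ", path)
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[mi[1L]]))
  rows <- lines[(mi[1L] + 1L):(mi[1L] + w)]
  pwm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  colnames(pwm) <- .BASES
  pwm <- pwm / rowSums(pwm)
  spacer <- w - 16L
  structure(list(pwm = pwm, spacer_len = spacer, pseudocount = NA_real_),
            class = "rss_motif")
}
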