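#' The 96 single-base-substitution channels
#'
#' Channel order follows the COSMIC convention: the six pyrimidine-centred
#' substitution classes in the order C>A, C>G, C>T, T>A, T>C, T>G, and within
#' each class the 16 trinucleotide contexts in lexicographic order of the
#' flanking bases (A, C, G, T upstream-major). Channel 1 is `A[C>A]A`,
#' channel 96 is `T[T>G]T`.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(96)
  i <- 0L
  for (s in subs) for (up in bases) for (dn in bases) {
    i <- i + 1L
    out[i] <- paste0(up, "[", s, "]", dn)
  }
  out
}

.SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chars <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(.COMP[b])), collapse = ""), "")
}

#' Map a trinucleotide context and alternate allele to its SBS channel
#'
#' Contexts whose central reference base is a purine (A or G) are
#' reverse-complemented (together with the alternate allele) so that every
#' channel has a pyrimidine (C or T) centre.
#'
#' @param context Character vector of reference trinucleotides (the site is
#'   the central base).
#' @param alt Character vector of alternate alleles (single bases).
#' @return Integer vector of channel indices in 1..96; `NA` where the context
#'   contains an N (a warning reports how many were skipped).
#' @export
channel_index <- function(context, alt) {
  stopifnot(length(context) == length(alt))
  context <- toupper(context)
  alt <- toupper(alt)
  bad <- !grepl("^[ACGT]{3}$", context) | !alt %in% .BASES
  if (any(bad)) warning(sum(bad), " site(s) with N/invalid context excluded from channel mapping")
  up <- substr(context, 1, 1)
  ref <- substr(context, 2, 2)
  dn <- substr(context, 3, 3)
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    u0 <- up[flip]; d0 <- dn[flip]
    up[flip] <- unname(.COMP[d0])
    dn[flip] <- unname(.COMP[u0])
    ref[flip] <- unname(.COMP[ref[flip]])
    alt[flip] <- unname(.COMP[alt[flip]])
  }
  sub <- paste0(ref, ">", alt)
  si <- match(sub, .SBS_SUBS)
  ui <- match(up, .BASES)
  di <- match(dn, .BASES)
  idx <- (si - 1L) * 16L + (ui - 1L) * 4L + di
  idx[bad | is.na(idx)] <- NA_integer_
  idx
}

#' Trinucleotide context of SNVs from a reference sequence set
#'
#' @param ref_seqs A named `Biostrings::DNAStringSet` (or object coercible via
#'   `as`) holding the reference sequences, or a path to a FASTA file.
#' @param chrom,pos Vectors locating the sites (1-based).
#' @return Character vector of trinucleotides centred on `pos`.
#' @export
trinucleotide_context <- function(ref_seqs, chrom, pos) {
  if (is.character(ref_seqs) && length(ref_seqs) == 1L && file.exists(ref_seqs))
    ref_seqs <- Biostrings::readDNAStringSet(ref_seqs)
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  nm <- sub("\\s.*$", "", names(ref_seqs))
  i <- match(chrom, nm)
  if (anyNA(i)) stop("chromosome(s) not in reference: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  lens <- Biostrings::width(ref_seqs)[i]
  if (any(pos < 2L | pos > lens - 1L))
    stop("site too close to a sequence end for a trinucleotide context")
  v <- Biostrings::subseq(ref_seqs[i], start = pos - 1L, width = 3L)
  as.character(v, use.names = FALSE)
}
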