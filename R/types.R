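#' Construct a table of variant sites
#'
#' Sites are kept as a data.frame, one row per variant, with `var_class`
#' inferred from allele lengths. Quality annotations produced upstream
#' (ASMD: median alignment score of supporting reads; CLPM: soft-clip
#' metric) travel as extra columns.
#'
#' @param chrom,pos,ref,alt Vectors describing the variants (pos 1-based).
#' @param context Optional reference trinucleotide (SNVs only).
#' @param ... Additional annotation columns (e.g. `ASMD`, `CLPM`), recycled.
#' @return data.frame of class `variant_sites`.
#' @export
variant_sites <- function(chrom, pos, ref, alt, context = NA_character_, ...) {
  chrom <- as.character(chrom); ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt)); pos <- as.integer(pos)
  if (any(pos < 1L)) stop("pos must be >= 1")
  if (any(ref == alt)) stop("ref must differ from alt")
  var_class <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
               ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   var_class = var_class, context = as.character(context),
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nmx in names(extra)) df[[nmx]] <- extra[[nmx]]
  ok <- is.na(df$context) | grepl("^[ACGTN]{3}$", df$context)
  if (!all(ok)) stop("context must be a trinucleotide over ACGTN")
  cen <- substr(df$context, 2, 2)
  bad <- !is.na(df$context) & df$var_class == "SNV" & !cen %in% c("C", "T", "A", "G")
  if (any(bad)) stop("SNV context centre must be a base")
  class(df) <- c("variant_sites", "data.frame")
  df
}

#' Sample metadata table
#'
#' @param sample_id,timepoint_label Identifiers.
#' @param purity Tumor purity in (0, 1].
#' @param ploidy Average ploidy (> 0).
#' @param role One of `"tumor"`, `"normal"`, `"panel"`.
#' @export
sample_meta <- function(sample_id, timepoint_label = sample_id, purity = 1,
                        ploidy = 2, role = "tumor") {
  df <- data.frame(sample_id = as.character(sample_id),
                   timepoint_label = as.character(timepoint_label),
                   purity = as.numeric(purity), ploidy = as.numeric(ploidy),
                   role = as.character(role), stringsAsFactors = FALSE)
  if (any(df$purity <= 0 | df$purity > 1)) stop("purity must be in (0, 1]")
  if (any(df$ploidy <= 0)) stop("ploidy must be > 0")
  if (!all(df$role %in% c("tumor", "normal", "panel"))) stop("bad role")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Per-site, per-sample variant-read and depth matrix
#'
#' The universal currency of the pipeline: integer matrices `var_reads` and
#' `depth` (sites x samples), with the base/mapping-quality thresholds under
#' which the counts were extracted recorded as provenance.
#'
#' @param sites A `variant_sites` data.frame.
#' @param samples A `sample_meta` data.frame.
#' @param var_reads,depth Integer matrices, `nrow(sites)` x `nrow(samples)`.
#' @param min_baseq,min_mapq Quality thresholds used when counting.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(sites, samples, var_reads, depth,
                         min_baseq = 25L, min_mapq = 40L) {
  var_reads <- as.matrix(var_reads); storage.mode(var_reads) <- "integer"
  depth <- as.matrix(depth); storage.mode(depth) <- "integer"
  x <- structure(list(sites = sites, samples = samples,
                      var_reads = var_reads, depth = depth,
                      min_baseq = as.integer(min_baseq),
                      min_mapq = as.integer(min_mapq)),
                 class = "count_matrix")
  validate_count_matrix(x)
}

#' @rdname count_matrix
#' @param x A `count_matrix`.
#' @export
validate_count_matrix <- function(x) {
  ns <- nrow(x$sites); nk <- nrow(x$samples)
  if (!all(dim(x$var_reads) == c(ns, nk)) || !all(dim(x$depth) == c(ns, nk)))
    stop("count_matrix dimensions inconsistent with sites/samples")
  if (any(x$var_reads < 0L) || any(x$depth < 0L))
    stop("negative counts")
  bad <- which(x$var_reads > x$depth, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf(
      "var_reads > depth at site %s:%d (%s), sample %s (v=%d, d=%d)",
      x$sites$chrom[b[1L]], x$sites$pos[b[1L]], x$sites$alt[b[1L]],
      x$samples$sample_id[b[2L]], x$var_reads[b[1L], b[2L]], x$depth[b[1L], b[2L]]))
  }
  colnames(x$var_reads) <- colnames(x$depth) <- x$samples$sample_id
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sites x %d samples (baseq >= %d, mapq >= %d)\n",
              nrow(x$sites), nrow(x$samples), x$min_baseq, x$min_mapq))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$var_reads)

#' Subset a count matrix by site and/or sample
#' @param x A `count_matrix`.
#' @param i Site indices.  @param j Sample indices or sample ids.
#' @export
subset_counts <- function(x, i = seq_len(nrow(x$sites)),
                          j = seq_len(nrow(x$samples))) {
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  if (anyNA(j)) stop("unknown sample id")
  count_matrix(x$sites[i, , drop = FALSE], x$samples[j, , drop = FALSE],
               x$var_reads[i, j, drop = FALSE], x$depth[i, j, drop = FALSE],
               x$min_baseq, x$min_mapq)
}

#' Copy-number segment table
#'
#' 1-based inclusive coordinates; segments must not overlap within a
#' (sample, chromosome) pair.
#'
#' @param sample_id,chrom,start,end,n_major,n_minor Vectors, one element per
#'   segment.
#' @export
cn_segments <- function(sample_id, chrom, start, end, n_major, n_minor) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   n_major = as.integer(n_major), n_minor = as.integer(n_minor),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("segment start > end")
  if (any(df$n_major < 0L | df$n_minor < 0L)) stop("negative copy number")
  if (any(df$n_major < df$n_minor)) stop("n_major < n_minor")
  sp <- split(df, paste(df$sample_id, df$chrom, sep = "\r"))
  for (g in sp) {
    o <- order(g$start)
    if (nrow(g) > 1L && any(g$start[o][-1L] <= g$end[o][-nrow(g)]))
      stop("overlapping segments for sample ", g$sample_id[1L],
           " chrom ", g$chrom[1L])
  }
  class(df) <- c("cn_segments", "data.frame")
  df
}

#' Copy-number state at given positions
#'
#' Positions not covered by any segment return the configured default
#' (diploid heterozygous, major/minor = 1/1, unless overridden).
#'
#' @param segments A `cn_segments` table.
#' @param sample_id Single sample id.
#' @param chrom,pos Vectors of positions to query.
#' @param default Length-2 integer `(n_major, n_minor)` for uncovered sites.
#' @return data.frame with columns `n_major`, `n_minor`.
#' @export
lookup_cn <- function(segments, sample_id, chrom, pos, default = c(1L, 1L)) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n); pos <- rep_len(as.integer(pos), n)
  out <- data.frame(n_major = rep.int(as.integer(default[1L]), n),
                    n_minor = rep.int(as.integer(default[2L]), n))
  seg <- segments[segments$sample_id == sample_id, , drop = FALSE]
  if (nrow(seg) == 0L) return(out)
  for (ch in unique(chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) next
    o <- order(s$start); s <- s[o, , drop = FALSE]
    qi <- which(chrom == ch)
    k <- findInterval(pos[qi], s$start)
    hit <- k >= 1L & pos[qi] <= s$end[pmax(k, 1L)]
    out$n_major[qi[hit]] <- s$n_major[k[hit]]
    out$n_minor[qi[hit]] <- s$n_minor[k[hit]]
  }
  out
}

#' Breakpoint pairs with flanking sequence windows
#'
#' @param chrom Chromosome.
#' @param bp_low,bp_high 1-based breakpoint positions, `bp_low < bp_high`.
#' @param sv_type `"deletion"` or `"other"`.
#' @param flank_low_seq,flank_high_seq Sequence windows centred on each
#'   breakpoint (over A/C/G/T/N).
#' @export
breakpoint_pairs <- function(chrom, bp_low, bp_high, sv_type = "deletion",
                             flank_low_seq = NA_character_,
                             flank_high_seq = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), bp_low = as.integer(bp_low),
                   bp_high = as.integer(bp_high),
                   sv_type = as.character(sv_type),
                   flank_low_seq = toupper(as.character(flank_low_seq)),
                   flank_high_seq = toupper(as.character(flank_high_seq)),
                   stringsAsFactors = FALSE)
  if (any(df$bp_low >= df$bp_high)) stop("bp_low must be < bp_high")
  if (!all(df$sv_type %in% c("deletion", "other"))) stop("bad sv_type")
  for (col in c("flank_low_seq", "flank_high_seq")) {
    s <- df[[col]]
    if (any(!is.na(s) & grepl("[^ACGTN]", s))) stop(col, " not over ACGTN")
  }
  class(df) <- c("breakpoint_pairs", "data.frame")
  df
}

#' Reference signature catalog
#'
#' @param probs Numeric matrix, one row per signature over the 96 channels in
#'   the order of [sbs_channels()]; rows must sum to 1.
#' @param names Signature identifiers.
#' @export
signature_catalog <- function(probs, names = rownames(probs)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 96L) stop("catalog must have 96 channels")
  if (any(probs < 0)) stop("negative signature probabilities")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("signature rows must sum to 1")
  rownames(probs) <- names
  colnames(probs) <- sbs_channels()
  structure(list(names = names, probs = probs), class = "signature_catalog")
}
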