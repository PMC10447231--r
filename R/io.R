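#' Read and write force-called count matrices as TSV
#'
#' The column grammar is: `chrom pos ref alt var_class context` followed by a
#' `<sample>_var` / `<sample>_depth` pair per sample, plus any annotation
#' columns. Sample metadata and the counting provenance travel in `#key value`
#' header comment lines so the round trip is lossless.
#'
#' @param path File path.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- character()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  close(con); on.exit()
  dt <- data.table::fread(path, sep = "\t", skip = length(hdr),
                          header = TRUE, data.table = FALSE)
  vcols <- grep("_var$", names(dt), value = TRUE)
  sids <- sub("_var$", "", vcols)
  dcols <- paste0(sids, "_depth")
  if (!all(dcols %in% names(dt)))
    stop("missing depth column(s): ", paste(setdiff(dcols, names(dt)), collapse = ", "))
  meta <- .parse_header_meta(hdr, sids)
  site_cols <- setdiff(names(dt), c(vcols, dcols))
  ctx <- if ("context" %in% site_cols) dt$context else NA_character_
  extra <- setdiff(site_cols, c("chrom", "pos", "ref", "alt", "var_class", "context"))
  sites <- do.call(variant_sites,
                   c(list(chrom = dt$chrom, pos = dt$pos, ref = dt$ref,
                          alt = dt$alt, context = ctx),
                     dt[extra]))
  count_matrix(sites, meta$samples,
               as.matrix(dt[vcols]), as.matrix(dt[dcols]),
               min_baseq = meta$min_baseq, min_mapq = meta$min_mapq)
}

.parse_header_meta <- function(hdr, sids) {
  kv <- function(key, default) {
    ln <- grep(paste0("^#", key, "\t"), hdr, value = TRUE)
    if (length(ln)) strsplit(ln[1L], "\t")[[1L]][-1L] else default
  }
  min_baseq <- as.integer(kv("min_baseq", "25")[1L])
  min_mapq <- as.integer(kv("min_mapq", "40")[1L])
  slines <- grep("^#sample\t", hdr, value = TRUE)
  if (length(slines)) {
    parts <- do.call(rbind, strsplit(slines, "\t"))
    samples <- sample_meta(parts[, 2L], parts[, 3L],
                           as.numeric(parts[, 4L]), as.numeric(parts[, 5L]),
                           parts[, 6L])
    samples <- samples[match(sids, samples$sample_id), , drop = FALSE]
    if (anyNA(samples$sample_id)) stop("header #sample lines do not cover all columns")
  } else {
    samples <- sample_meta(sids)
  }
  list(samples = samples, min_baseq = min_baseq, min_mapq = min_mapq)
}

#' @rdname read_counts_tsv
#' @param x A `count_matrix`.
#' @export
write_counts_tsv <- function(x, path) {
  x <- validate_count_matrix(x)
  hdr <- c(paste0("#min_baseq\t", x$min_baseq),
           paste0("#min_mapq\t", x$min_mapq),
           sprintf("#sample\t%s\t%s\t%.10g\t%.10g\t%s",
                   x$samples$sample_id, x$samples$timepoint_label,
                   x$samples$purity, x$samples$ploidy, x$samples$role))
  df <- as.data.frame(x$sites)
  class(df) <- "data.frame"
  v <- as.data.frame(x$var_reads); names(v) <- paste0(x$samples$sample_id, "_var")
  d <- as.data.frame(x$depth); names(d) <- paste0(x$samples$sample_id, "_depth")
  out <- cbind(df, v, d)
  writeLines(hdr, path)
  suppressWarnings(data.table::fwrite(out, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Read copy-number segments from a BED-like TSV
#'
#' Expected columns: `sample_id chrom start end n_major n_minor`, 1-based
#' inclusive. Pass `bed = TRUE` for 0-based half-open input; the conversion is
#' noted via a message.
#'
#' @param path File path.  @param bed Convert from BED coordinates.
#' @export
read_cn_segments <- function(path, bed = FALSE) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("sample_id", "chrom", "start", "end", "n_major", "n_minor")
  if (!all(need %in% names(dt)))
    stop("CN segment file must have columns: ", paste(need, collapse = ", "))
  if (bed) {
    message("converting BED half-open coordinates to 1-based inclusive")
    dt$start <- dt$start + 1L
  }
  cn_segments(dt$sample_id, dt$chrom, dt$start, dt$end, dt$n_major, dt$n_minor)
}

#' @rdname read_cn_segments
#' @param segments A `cn_segments` table.
#' @export
write_cn_segments <- function(segments, path) {
  df <- as.data.frame(segments); class(df) <- "data.frame"
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read breakpoint pairs from a BEDPE-like TSV
#'
#' Columns: `chrom bp_low bp_high sv_type flank_low_seq flank_high_seq`
#' (flank columns optional when a reference FASTA is supplied to the scanner).
#' @param path File path.
#' @export
read_breakpoints <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "bp_low", "bp_high", "sv_type")
  if (!all(need %in% names(dt)))
    stop("breakpoint file must have columns: ", paste(need, collapse = ", "))
  fl <- if ("flank_low_seq" %in% names(dt)) dt$flank_low_seq else NA_character_
  fh <- if ("flank_high_seq" %in% names(dt)) dt$flank_high_seq else NA_character_
  breakpoint_pairs(dt$chrom, dt$bp_low, dt$bp_high, dt$sv_type, fl, fh)
}

#' @rdname read_breakpoints
#' @param bps A `breakpoint_pairs` table.
#' @export
write_breakpoints <- function(bps, path) {
  df <- as.data.frame(bps); class(df) <- "data.frame"
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a COSMIC-style SBS signature catalog
#'
#' Accepts either the two-column layout (`Type` = substitution such as `C>A`,
#' `SubType` = trinucleotide) or the bracketed layout (`Type` = `A[C>A]A`),
#' with one column per signature; rows are reordered to [sbs_channels()].
#'
#' @param path Tab-separated catalog file.
#' @return A [signature_catalog()].
#' @export
read_signature_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (all(c("Type", "SubType") %in% names(dt))) {
    lab <- paste0(substr(dt$SubType, 1, 1), "[", dt$Type, "]",
                  substr(dt$SubType, 3, 3))
    sig_cols <- setdiff(names(dt), c("Type", "SubType"))
  } else {
    key <- names(dt)[1L]
    lab <- dt[[key]]
    sig_cols <- setdiff(names(dt), key)
  }
  ord <- match(sbs_channels(), lab)
  if (anyNA(ord)) stop("catalog does not cover all 96 channels")
  probs <- t(as.matrix(dt[ord, sig_cols, drop = FALSE]))
  probs <- probs / rowSums(probs)
  signature_catalog(probs, names = sig_cols)
}

#' @rdname read_signature_catalog
#' @param catalog A `signature_catalog`.
#' @export
write_signature_catalog <- function(catalog, path) {
  ch <- sbs_channels()
  df <- data.frame(Type = substr(ch, 3, 5), SubType = paste0(
    substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7)))
  for (i in seq_along(catalog$names)) df[[catalog$names[i]]] <- catalog$probs[i, ]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write sequences to FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
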