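#' Write a count matrix as a multi-sample VCF
#'
#' Emits VCF 4.2 with per-sample `AD` (ref,alt depths) and `DP` FORMAT
#' fields; `ASMD`/`CLPM` annotations, when present on the sites, are written
#' as INFO fields. One record per alt allele.
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @export
write_vcf <- function(x, path) {
  x <- validate_count_matrix(x)
  s <- x$sites
  has_asmd <- "ASMD" %in% names(s); has_clpm <- "CLPM" %in% names(s)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonetrace",
           if (has_asmd) "##INFO=<ID=ASMD,Number=1,Type=Float,Description=\"Median alignment score of supporting reads\">",
           if (has_clpm) "##INFO=<ID=CLPM,Number=1,Type=Float,Description=\"Clipping metric\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples$sample_id), collapse = "\t"))
  info <- rep(".", nrow(s))
  if (has_asmd || has_clpm) {
    parts <- cbind(if (has_asmd) paste0("ASMD=", s$ASMD),
                   if (has_clpm) paste0("CLPM=", s$CLPM))
    info <- apply(parts, 1L, paste, collapse = ";")
  }
  gt <- vapply(seq_len(nrow(s)), function(i) {
    paste(sprintf("%d,%d:%d", x$depth[i, ] - x$var_reads[i, ],
                  x$var_reads[i, ], x$depth[i, ]), collapse = "\t")
  }, "")
  rec <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info,
               "AD:DP", gt, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read variant sites and counts for one sample from a VCF
#'
#' Backed by `VariantAnnotation::readVcf`; multi-allelic records are split
#' into one site per alternate allele (sharing the record's `DP`). Variant
#' reads come from the alt entry of `AD`; depth from `DP`, falling back to
#' the sum of `AD`.
#'
#' @param path VCF path.
#' @param sample_id Sample column to extract.
#' @return A `variant_sites` data.frame with `var_reads` and `depth` columns.
#' @export
read_vcf <- function(path, sample_id) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(VariantAnnotation::readVcf(path),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  smp <- colnames(vcf)
  if (!sample_id %in% smp) stop("sample '", sample_id, "' not in VCF")
  g <- VariantAnnotation::geno(vcf)
  n <- length(rr)
  if (n == 0L) {
    return(cbind(variant_sites(character(), integer(), character(), character()),
                 var_reads = integer(), depth = integer()))
  }
  v <- d <- rep(NA_integer_, n)
  if ("AD" %in% names(g)) {
    ad <- g$AD
    if (length(dim(ad)) == 3L) {               # expanded Number=R field
      v <- as.integer(ad[, sample_id, 2L])
      dsum <- as.integer(rowSums(ad[, sample_id, , drop = FALSE], dims = 1L))
    } else {
      adl <- ad[, sample_id]
      v <- vapply(adl, function(a) as.integer(a[2L]), 1L)
      dsum <- vapply(adl, function(a) as.integer(sum(a)), 1L)
    }
    d <- dsum
  }
  if ("DP" %in% names(g)) {
    dp <- as.integer(g$DP[, sample_id])
    d[!is.na(dp)] <- dp[!is.na(dp)]
  }
  if (anyNA(v) || anyNA(d))
    stop("counts unavailable: VCF lacks usable AD/DP fields for sample ",
         sample_id)
  info <- VariantAnnotation::info(vcf)
  args <- list(chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               ref = as.character(rr$REF),
               alt = as.character(rr$ALT))
  for (k in c("ASMD", "CLPM")) if (k %in% names(info)) args[[k]] <- as.numeric(info[[k]])
  sites <- do.call(variant_sites, args)
  sites$var_reads <- v
  sites$depth <- d
  if (any(sites$var_reads > sites$depth, na.rm = TRUE))
    stop("var_reads exceeds depth in VCF for sample ", sample_id)
  sites
}
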