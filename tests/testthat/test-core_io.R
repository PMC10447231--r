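test_that("channel mapping is a bijection over all 96 classes", {
  bases <- c("A", "C", "G", "T")
  pyr <- c("C", "T")
  seen <- integer(0)
  for (ref in pyr) for (alt in setdiff(bases, ref))
    for (up in bases) for (dn in bases) {
      idx <- channel_index(paste0(up, ref, dn), alt)
      lab <- sbs_channels()[idx]
      expect_identical(lab, paste0(up, "[", ref, ">", alt, "]", dn))
      seen <- c(seen, idx)
    }
  expect_setequal(seen, 1:96)
  # purine-centred contexts map to the reverse complement channel
  expect_identical(channel_index("ACA", "T"), channel_index("TGT", "A"))
  expect_identical(channel_index("TGT", "A"),
                   match("A[C>T]A", sbs_channels()))
  expect_warning(ci <- channel_index("ANA", "T"), "excluded")
  expect_true(is.na(ci))
})

test_that("trinucleotide_context reads flanks from a reference", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTACGT"))
  expect_identical(trinucleotide_context(ref, "chr1", c(3L, 5L)),
                   c("ACG", "GTA"))
  expect_error(trinucleotide_context(ref, "chr1", 1L), "too close")
  expect_error(trinucleotide_context(ref, "chrX", 3L), "not in reference")
})

test_that("variant_sites validates inputs and infers classes", {
  s <- variant_sites(c("1", "1", "2"), c(10, 20, 30),
                     c("C", "CT", "GAA"), c("T", "CTA", "G"))
  expect_identical(s$var_class, c("SNV", "insertion", "deletion"))
  expect_error(variant_sites("1", 0, "C", "T"), "pos")
  expect_error(variant_sites("1", 5, "C", "C"), "differ")
})

test_that("count_matrix rejects v > d with a precise location", {
  sites <- variant_sites(c("1", "1"), c(10, 20), "C", "T")
  sm <- sample_meta(c("a", "b"))
  expect_error(
    count_matrix(sites, sm, matrix(c(1, 5, 2, 2), 2), matrix(3, 2, 2)),
    "1:20.*sample a.*v=5, d=3")
  cm <- count_matrix(sites, sm, matrix(1, 2, 2), matrix(3, 2, 2))
  expect_identical(dim(cm), c(2L, 2L))
})

test_that("counts TSV round-trips losslessly, including sample metadata", {
  sim <- simulate_study(paper_template_config(mutation_scale = 0.01), seed = 4)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, p)
  back <- read_counts_tsv(p)
  expect_identical(back$var_reads, sim$counts$var_reads)
  expect_identical(back$depth, sim$counts$depth)
  expect_identical(back$sites$pos, sim$counts$sites$pos)
  expect_identical(back$sites$context, sim$counts$sites$context)
  expect_equal(back$samples$purity, sim$counts$samples$purity, tolerance = 1e-12)
  expect_identical(back$min_baseq, sim$counts$min_baseq)
})

test_that("VCF writing and reading agree per sample, with annotations", {
  sim <- simulate_study(paper_template_config(mutation_scale = 0.01), seed = 8)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$counts, p)
  for (sid in sim$counts$samples$sample_id[c(1L, 5L)]) {
    back <- read_vcf(p, sid)
    expect_identical(back$var_reads, unname(sim$counts$var_reads[, sid]))
    expect_identical(back$depth, unname(sim$counts$depth[, sid]))
    expect_identical(back$pos, sim$counts$sites$pos)
  }
  back <- read_vcf(p, sim$counts$samples$sample_id[1L])
  expect_true(all(back$ASMD == 141))
  expect_error(read_vcf(p, "nosuch"), "not in VCF")
})

test_that("multi-allelic records split into one site per alt", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tC,T\t.\tPASS\t.\tAD:DP\t30,12,8:50"), p)
  back <- read_vcf(p, "S1")
  expect_identical(nrow(back), 2L)
  expect_identical(back$pos, c(100L, 100L))
  expect_setequal(back$alt, c("C", "T"))
  expect_identical(back$depth, c(50L, 50L))   # record DP shared by both splits
  expect_setequal(back$var_reads, c(12L, 8L))
})

test_that("cn segment lookup matches a brute-force interval oracle", {
  set.seed(31)
  segs <- cn_segments(sample_id = "s1",
                      chrom = rep(c("1", "17"), each = 3),
                      start = c(1, 5000, 9000, 1, 4000, 9500),
                      end = c(4000, 8000, 12000, 2000, 9000, 9900),
                      n_major = c(2, 1, 3, 1, 2, 4),
                      n_minor = c(1, 0, 2, 0, 2, 1))
  q_chrom <- sample(c("1", "17", "5"), 300, replace = TRUE)
  q_pos <- sample.int(13000, 300, replace = TRUE)
  got <- lookup_cn(segs, "s1", q_chrom, q_pos)
  naive <- t(vapply(seq_len(300), function(i) {
    hit <- segs$chrom == q_chrom[i] & segs$start <= q_pos[i] &
      segs$end >= q_pos[i]
    if (any(hit)) c(segs$n_major[hit][1L], segs$n_minor[hit][1L]) else c(1L, 1L)
  }, integer(2)))
  expect_identical(got$n_major, naive[, 1L])
  expect_identical(got$n_minor, naive[, 2L])
  # 17p-style query
  expect_identical(unlist(lookup_cn(segs, "s1", "17", 1500), use.names = FALSE),
                   c(1L, 0L))
  # unknown sample falls back to the diploid default
  expect_identical(unlist(lookup_cn(segs, "zz", "1", 10), use.names = FALSE),
                   c(1L, 1L))
  expect_error(cn_segments("s1", "1", c(1, 50), c(100, 200), 1, 1),
               "overlapping")
})

test_that("signature catalog round-trips through the COSMIC tab format", {
  cat0 <- synthetic_signatures()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_signature_catalog(cat0, p)
  back <- read_signature_catalog(p)
  expect_equal(back$probs, cat0$probs, tolerance = 1e-6)
  expect_identical(back$names, cat0$names)
})
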