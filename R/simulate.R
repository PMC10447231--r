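#' Synthetic stand-in mutational signatures
#'
#' Three 96-simplex generator vectors qualitatively resembling the clock
#' signature SBS1 (C>T at CpG), the flat clock SBS5, and the thiopurine
#' signature SBS87 (T>G / T>A enriched). These are synthetic stand-ins
#' constructed in code — NOT copies of the COSMIC catalog — and are named
#' accordingly.
#'
#' @return A [signature_catalog()] with signatures
#'   `SBS1like_synthetic`, `SBS5like_synthetic`, `SBS87like_synthetic`.
#' @export
synthetic_signatures <- function() {
  ch <- sbs_channels()
  sub <- substr(ch, 3, 5)
  dn <- substr(ch, 7, 7)
  s1 <- rep(0.05, 96)
  s1[sub == "C>T"] <- 1.5                     # deamination clock
  s1[sub == "C>T" & dn == "G"] <- 20          # strongly CpG-focused
  s5 <- rep(1, 96)                            # broad, mildly featured
  s5[sub == "T>C"] <- 2.5
  s5[sub == "C>T"] <- 1.8
  s5[sub == "T>A"] <- 1.2
  s87 <- rep(0.05, 96)
  s87[sub == "T>G"] <- 8                      # thiopurine-like
  s87[sub == "T>A"] <- 5
  s87[sub == "C>A"] <- 0.8
  probs <- rbind(SBS1like_synthetic = s1 / sum(s1),
                 SBS5like_synthetic = s5 / sum(s5),
                 SBS87like_synthetic = s87 / sum(s87))
  signature_catalog(probs)
}

#' Specify a synthetic serial-sampling study
#'
#' The stated world of the generator: a rooted clone tree with per-sample
#' CCFs obeying the pigeonhole constraint, branch mutation sets drawn from
#' mixtures of the three synthetic signatures, Poisson depth around `depth`,
#' beta-binomial carrier reads, binomial background error reads at `eps`,
#' copy-number segments (e.g. a 17p-style loss), a panel of unmatched
#' normals, and RSS-flanked deletion breakpoints.
#'
#' @param samples A [sample_meta()] table.
#' @param parent Named integer parent vector over clone nodes (0 = root).
#' @param ccf Nodes x samples CCF matrix.
#' @param branch_n Named mutation count per node.
#' @param branch_sig Nodes x 3 matrix of signature mixture weights.
#' @param depth Mean sequencing depth.
#' @param eps Background error rate per read.
#' @param rho Carrier-read beta-binomial overdispersion.
#' @param segments Optional [cn_segments()]; sites listed in
#'   `cn_branch_sites` are placed inside the first listed segment region.
#' @param cn_branch_sites Named integer: how many sites of each node fall in
#'   the copy-number-altered region.
#' @param n_panel Number of unmatched panel samples.
#' @param rss_plants data.frame describing planted deletions: columns
#'   `spacer_len`, `offset`, `strand`, `side`, `plant` (logical).
#' @export
simulation_config <- function(samples, parent, ccf, branch_n, branch_sig,
                              depth = 100, eps = 1.6e-4, rho = 0.01,
                              segments = NULL, cn_branch_sites = NULL,
                              n_panel = 32L, rss_plants = NULL) {
  ccf <- as.matrix(ccf)
  stopifnot(nrow(ccf) == length(parent), ncol(ccf) == nrow(samples),
            all(names(parent) == rownames(ccf)),
            all(names(branch_n) == rownames(ccf)),
            nrow(branch_sig) == length(parent))
  # pigeonhole feasibility, exact, before any sampling
  for (p in seq_along(parent)) {
    ch <- which(parent == p)
    if (length(ch) && any(colSums(ccf[ch, , drop = FALSE]) > ccf[p, ] + 1e-9))
      stop("config violates the pigeonhole constraint at node ",
           names(parent)[p])
  }
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("config must have exactly one root")
  structure(list(samples = samples, parent = parent, ccf = ccf,
                 branch_n = branch_n, branch_sig = as.matrix(branch_sig),
                 depth = depth, eps = eps, rho = rho, segments = segments,
                 cn_branch_sites = cn_branch_sites, n_panel = as.integer(n_panel),
                 rss_plants = rss_plants), class = "simulation_config")
}

#' The shipped template configuration
#'
#' Mirrors the structure of the case study the package was designed around:
#' eight samples over six timepoints at ~100x; a diagnostic sample whose
#' dominant lineage carries subclones of 0.20 and 0.75 (0.88 in the second
#' diagnostic sample); an early bifurcation of the relapse and myeloid
#' lineages below a thiopurine-mutagenized progression branch, so
#' thiopurine-like mutations appear both shared and private; a 17p-style
#' loss in the myeloid samples; a myeloid root branch of 2,468 SNVs of which
#' 150 sit in the lost region, leaving 2,318 diploid sites; and that lineage
#' spiked into the second-relapse sample at cell fraction 0.0026
#' (VAF 0.0013).
#'
#' @param mutation_scale Scales all branch mutation counts (runtime control
#'   for tests); the spiked lineage keeps its site count unless scaled below 1.
#' @export
paper_template_config <- function(mutation_scale = 1) {
  samples <- sample_meta(
    sample_id = c("SIM01d", "SIM01i", "SIM01c", "SIM01e",
                  "SIM01j", "SIM01f", "SIM01g", "SIM01h"),
    timepoint_label = c("ALL_diagnosis", "ALL_diagnosis", "ALL_R1", "ALL_R1",
                        "ALL_R2", "MDS", "AML", "AML_late"),
    purity = c(0.92, 0.90, 0.88, 0.85, 0.90, 0.23, 0.90, 0.85),
    ploidy = 2, role = "tumor")
  nodes <- c("ALL_root", "TP53_17p", "KMT2D", "progression",
             "ALL_R1", "ALL_R2", "AML_root", "AML_sub")
  parent <- stats::setNames(c(0L, 1L, 1L, 3L, 4L, 4L, 4L, 7L), nodes)
  spike <- 0.0026 / 0.90      # cell fraction 0.0026 in the R2-analog sample
  ccf <- rbind(
    ALL_root    = c(1, 1, 1, 1, 1, 1, 1, 1),
    TP53_17p    = c(0.20, 0.10, 0, 0, 0, 0, 0, 0),
    KMT2D       = c(0.75, 0.88, 1, 1, 1, 1, 1, 1),
    progression = c(0.03, 0.02, 1, 1, 1, 1, 1, 1),
    ALL_R1      = c(0, 0, 0.95, 0.90, 0, 0, 0, 0),
    ALL_R2      = c(0, 0, 0, 0, 0.95, 0, 0, 0),
    AML_root    = c(0, 0, 0, 0, spike, 1, 1, 1),
    AML_sub     = c(0, 0, 0, 0, 0, 0, 0.45, 0.75))
  colnames(ccf) <- samples$sample_id
  branch_n <- stats::setNames(
    pmax(2L, as.integer(round(c(1500, 250, 400, 350, 300, 300, 2468, 300) *
                              mutation_scale))), nodes)
  branch_sig <- rbind(c(0.35, 0.65, 0), c(0.30, 0.70, 0), c(0.30, 0.70, 0),
                      c(0.10, 0.30, 0.60), c(0.10, 0.40, 0.50),
                      c(0.15, 0.45, 0.40), c(0.10, 0.30, 0.60),
                      c(0.20, 0.50, 0.30))
  rownames(branch_sig) <- nodes
  n17 <- max(1L, as.integer(round(150 * mutation_scale)))
  seg_len <- 20L * n17 + 200L
  segments <- cn_segments(
    sample_id = c("SIM01f", "SIM01g", "SIM01h"),
    chrom = "17", start = 1L, end = seg_len, n_major = 1L, n_minor = 0L)
  rss_plants <- data.frame(
    spacer_len = c(23L, 23L, 12L),
    offset = c(10L, 6L, 8L),
    strand = c("+", "+", "-"),
    side = c("high", "high", "high"),
    plant = c(TRUE, TRUE, FALSE))
  simulation_config(samples, parent, ccf, branch_n, branch_sig,
                    depth = 100, eps = 1.6e-4, rho = 0.01,
                    segments = segments,
                    cn_branch_sites = c(AML_root = n17),
                    n_panel = 32L, rss_plants = rss_plants)
}

.rbetabinom <- function(n, size, mu, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

# channel index -> upstream base, pyrimidine ref, alt, downstream base
.channel_parts <- function(idx) {
  si <- (idx - 1L) %/% 16L + 1L
  rest <- (idx - 1L) %% 16L
  ui <- rest %/% 4L + 1L
  di <- rest %% 4L + 1L
  sub <- .SBS_SUBS[si]
  data.frame(up = .BASES[ui], ref = substr(sub, 1, 1),
             alt = substr(sub, 3, 3), dn = .BASES[di],
             stringsAsFactors = FALSE)
}

#' Plant a consensus RSS next to a synthetic deletion breakpoint
#'
#' Generates random flank windows for a breakpoint pair and writes the motif
#' consensus (heptamer + random spacer + nonamer) starting `offset` bases
#' 3' of the chosen breakpoint; the truth records offset, strand and side.
#' Draws from the current RNG stream.
#'
#' @param motif An `rss_motif`.
#' @param offset Distance of the planted motif start from the breakpoint.
#' @param strand `"+"` or `"-"`.
#' @param side `"low"` or `"high"` breakpoint.
#' @param window Flank half-width.
#' @param chrom,bp_low,bp_high Coordinates for the emitted breakpoint pair.
#' @param plant Set `FALSE` to emit an unplanted (null) breakpoint.
#' @return List with `bp` (a [breakpoint_pairs()] row) and `truth`.
#' @export
plant_rss_deletion <- function(motif, offset = 10L, strand = "+",
                               side = "high", window = 50L,
                               chrom = "9", bp_low = 10000L, bp_high = 200000L,
                               plant = TRUE) {
  L <- nrow(motif$pwm)
  if (plant && offset + L > window)
    stop("offset + motif length exceeds the window")
  rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")
  flanks <- list(low = rand_seq(2L * window + 1L),
                 high = rand_seq(2L * window + 1L))
  if (plant) {
    cons <- apply(motif$pwm, 1L, function(r) .BASES[which.max(r)])
    sp <- 7L + seq_len(motif$spacer_len)
    cons[sp] <- sample(.BASES, motif$spacer_len, replace = TRUE)
    cons <- paste(cons, collapse = "")
    if (strand == "-") cons <- revcomp_chars(cons)
    start <- window + 1L + offset
    s <- flanks[[side]]
    substr(s, start, start + L - 1L) <- cons
    flanks[[side]] <- s
  }
  bp <- breakpoint_pairs(chrom, bp_low, bp_high, "deletion",
                         flanks$low, flanks$high)
  list(bp = bp, truth = list(planted = plant, spacer_len = motif$spacer_len,
                             offset = if (plant) offset else NA_integer_,
                             strand = strand, side = side))
}

#' Simulate a complete synthetic study
#'
#' Draws mutation contexts from the configured signature mixtures, embeds
#' them in a generated reference sequence (so trinucleotide lookup agrees
#' with the truth), samples depths `d ~ Poisson(depth)`, carrier reads
#' `v ~ BetaBinomial(d, expected_vaf(ccf, purity, CN, 1), rho)` and
#' non-carrier background reads `v ~ Binomial(d, eps)`, simulates an
#' unmatched panel at the background rate, and plants RSS-flanked deletions.
#' Fully reproducible from `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List of class `synthetic_study`: `counts` ([count_matrix()]),
#'   `panel` (panel [count_matrix()]), `segments`, `ref` (DNAStringSet),
#'   `breakpoints`, `truth`.
#' @export
simulate_study <- function(config, seed = 1L) {
  set.seed(seed)
  cat96 <- synthetic_signatures()
  nodes <- names(config$parent)
  S <- nrow(config$samples)

  # --- mutations: node, generating signature, channel, locus
  node_of <- rep(nodes, config$branch_n[nodes])
  N <- length(node_of)
  sig_of <- integer(N); chan <- integer(N)
  for (k in seq_along(nodes)) {
    i <- which(node_of == nodes[k])
    w <- config$branch_sig[k, ]
    sig_of[i] <- sample.int(3L, length(i), replace = TRUE, prob = w)
    for (g in 1:3) {
      ig <- i[sig_of[i] == g]
      if (length(ig))
        chan[ig] <- sample.int(96L, length(ig), replace = TRUE,
                               prob = cat96$probs[g, ])
    }
  }
  parts <- .channel_parts(chan)

  # --- loci: most sites on chrom "1"; cn_branch_sites go inside the first
  # configured segment region on its chromosome
  chrom <- rep("1", N)
  in_cn <- rep(FALSE, N)
  if (!is.null(config$cn_branch_sites) && !is.null(config$segments)) {
    seg1 <- config$segments[1L, ]
    for (nd in names(config$cn_branch_sites)) {
      cand <- which(node_of == nd)
      pick <- cand[seq_len(min(config$cn_branch_sites[[nd]], length(cand)))]
      chrom[pick] <- seg1$chrom
      in_cn[pick] <- TRUE
    }
  }
  pos <- integer(N)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- 50L + 20L * (seq_along(i) - 1L)
  }
  # --- reference sequences with the drawn contexts written in
  ref <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    len <- max(pos[i]) + 100L
    s <- sample(.BASES, len, replace = TRUE)
    s[pos[i] - 1L] <- parts$up[i]
    s[pos[i]] <- parts$ref[i]
    s[pos[i] + 1L] <- parts$dn[i]
    ref[[ch]] <- paste(s, collapse = "")
  }
  ref <- Biostrings::DNAStringSet(unlist(ref))

  sites <- variant_sites(chrom, pos, parts$ref, parts$alt,
                         context = paste0(parts$up, parts$ref, parts$dn),
                         ASMD = 141, CLPM = 0)

  # --- counts
  node_idx <- match(node_of, nodes)
  ccf_site <- config$ccf[node_idx, , drop = FALSE]
  v <- d <- matrix(0L, N, S)
  for (s in seq_len(S)) {
    d[, s] <- stats::rpois(N, config$depth)
    nm <- config$samples$sample_id[s]
    if (!is.null(config$segments)) {
      cn <- lookup_cn(config$segments, nm, chrom, pos)
    } else cn <- data.frame(n_major = rep(1L, N), n_minor = rep(1L, N))
    vaf <- expected_vaf(ccf_site[, s], config$samples$purity[s],
                        cn$n_major, cn$n_minor, 1L)
    carrier <- ccf_site[, s] > 0
    v[carrier, s] <- .rbetabinom(sum(carrier), d[carrier, s],
                                 pmax(vaf[carrier], 1e-12), config$rho)
    v[!carrier, s] <- stats::rbinom(sum(!carrier), d[!carrier, s], config$eps)
  }
  counts <- count_matrix(sites, config$samples, v, d)

  # --- unmatched panel at the background rate
  pd <- matrix(stats::rpois(N * config$n_panel, config$depth), N)
  pv <- matrix(stats::rbinom(N * config$n_panel, as.integer(pd), config$eps), N)
  panel <- count_matrix(sites,
                        sample_meta(sprintf("PANEL%02d", seq_len(config$n_panel)),
                                    role = "panel"),
                        pv, pd)

  # --- planted RSS deletions
  bps <- NULL; rss_truth <- list()
  if (!is.null(config$rss_plants)) {
    for (r in seq_len(nrow(config$rss_plants))) {
      pl <- config$rss_plants[r, ]
      motif <- build_rss_pwm(spacer_len = pl$spacer_len)
      res <- plant_rss_deletion(motif, pl$offset, pl$strand, pl$side,
                                window = 50L, chrom = "9",
                                bp_low = 10000L + 1000L * r,
                                bp_high = 200000L + 1000L * r,
                                plant = pl$plant)
      bps <- if (is.null(bps)) res$bp else rbind(bps, res$bp)
      rss_truth[[r]] <- res$truth
    }
    class(bps) <- c("breakpoint_pairs", "data.frame")
  }

  truth <- list(parent = config$parent, ccf = config$ccf,
                node = node_of, signature = cat96$names[sig_of],
                channel = chan,
                purity = stats::setNames(config$samples$purity,
                                         config$samples$sample_id),
                eps = config$eps, rho = config$rho, depth = config$depth,
                in_cn_region = in_cn, rss = rss_truth, seed = seed)
  structure(list(counts = counts, panel = panel, segments = config$segments,
                 ref = ref, breakpoints = bps, truth = truth),
            class = "synthetic_study")
}

#' Write a synthetic study to a directory in standard formats
#'
#' Emits the counts and panel TSVs, CN segments, breakpoints, reference
#' FASTA, a multi-sample VCF and the truth as JSON.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_counts_tsv(sim$panel, file.path(dir, "panel.tsv"))
  if (!is.null(sim$segments))
    write_cn_segments(sim$segments, file.path(dir, "cn_segments.tsv"))
  if (!is.null(sim$breakpoints))
    write_breakpoints(sim$breakpoints, file.path(dir, "breakpoints.tsv"))
  write_fasta(sim$ref, file.path(dir, "reference.fa"))
  write_vcf(sim$counts, file.path(dir, "variants.vcf"))
  tr <- sim$truth
  tr$ccf <- as.data.frame(tr$ccf)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
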