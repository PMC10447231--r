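#' Read a pipeline run configuration
#'
#' Flat `key value` (whitespace-separated) text file, one entry per line,
#' `#` comments allowed. Unknown keys are rejected. Every value is
#' serialized into the run manifest.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  known <- c("counts", "panel", "cn", "fasta", "breakpoints", "catalog",
             "out_dir", "seed", "stages", "branch",
             "asmd_min", "clpm_max", "germline_q", "presence_alpha",
             "tree_tol", "n_signatures", "rss_window", "rss_p_cutoff",
             "n_iter", "burn_in")
  cfg <- list(seed = 1L, stages = "filter,cluster,tree,signatures,rss,track",
              tree_tol = 0.05, n_signatures = 3L, rss_window = 50L,
              rss_p_cutoff = 0.05, asmd_min = 140, clpm_max = 0,
              germline_q = 1e-5, presence_alpha = 1e-3,
              n_iter = 2000L, burn_in = 1000L, branch = NULL)
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "\\s+")[[1L]]
      if (length(kv) < 2L) stop("bad config line: ", ln)
      if (!kv[1L] %in% known) stop("unknown config key: ", kv[1L])
      cfg[[kv[1L]]] <- paste(kv[-1L], collapse = " ")
    }
  }
  for (k in names(overrides)) {
    if (!k %in% known) stop("unknown config key: ", k)
    cfg[[k]] <- overrides[[k]]
  }
  num <- c("seed", "asmd_min", "clpm_max", "germline_q", "presence_alpha",
           "tree_tol", "n_signatures", "rss_window", "rss_p_cutoff",
           "n_iter", "burn_in")
  for (k in num) if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg
}

.stage_log <- function(stage, msg, t0) {
  message(sprintf("[%s] %s (%.1fs)", stage, msg,
                  as.numeric(proc.time()["elapsed"]) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes the stage sequence filter -> cluster -> tree -> signatures ->
#' rss -> track on the configured inputs, writing each stage's outputs and
#' a run manifest (config, input/output md5 hashes) into `out_dir`. A rerun
#' with identical inputs and config reproduces identical outputs.
#'
#' @param cfg A config list from [read_run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stages <- strsplit(cfg$stages, ",")[[1L]]
  if (is.null(cfg$counts)) stop("config must name a counts file")
  for (f in c("counts", "panel", "cn", "fasta", "breakpoints", "catalog")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("missing input file for '", f, "': ", cfg[[f]])
  }
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(proc.time()["elapsed"])
  manifest <- list(config = cfg, inputs = list(), outputs = list())
  for (f in c("counts", "panel", "cn", "fasta", "breakpoints", "catalog"))
    if (!is.null(cfg[[f]]))
      manifest$inputs[[f]] <- unname(tools::md5sum(cfg[[f]]))
  emit <- function(name, path) manifest$outputs[[name]] <<- unname(tools::md5sum(path))

  counts <- read_counts_tsv(cfg$counts)
  segments <- if (!is.null(cfg$cn)) read_cn_segments(cfg$cn) else NULL
  fcfg <- filter_config(cfg$asmd_min, cfg$clpm_max, cfg$germline_q,
                        cfg$presence_alpha)
  keep <- seq_len(nrow(counts$sites))
  assignment <- NULL; tree <- NULL

  if ("filter" %in% stages) {
    qf <- apply_quality_filters(counts$sites, fcfg)
    gl <- classify_germline(counts, cfg = fcfg)
    keep <- setdiff(which(gl$label == "somatic"), qf$rejections$index)
    rep_df <- data.frame(site = seq_len(nrow(counts$sites)),
                         germline_p = gl$p, germline_q = gl$q,
                         label = gl$label)
    p <- file.path(out_dir, "filter_report.tsv")
    write_filter_report(rep_df, p); emit("filter_report", p)
    .stage_log("filter", sprintf("%d/%d sites retained", length(keep),
                                 nrow(counts$sites)), t0)
    counts <- subset_counts(counts, i = keep)
  }
  if ("cluster" %in% stages) {
    ccfg <- cluster_config(n_iter = cfg$n_iter, burn_in = cfg$burn_in,
                           seed = as.integer(cfg$seed))
    cl <- gibbs_cluster(counts, segments, ccfg)
    assignment <- cl$assignment
    p1 <- file.path(out_dir, "clusters.tsv")
    p2 <- file.path(out_dir, "assignments.tsv")
    write_clusters(cl, p1, p2); emit("clusters", p1); emit("assignments", p2)
    .stage_log("cluster", sprintf("%d clusters", nrow(cl$ccf)), t0)
  }
  if ("tree" %in% stages && !is.null(assignment)) {
    # CCF noise scales inversely with purity; escalate the tolerance when
    # no feasible tree exists at the configured value
    tree <- NULL
    for (mult in c(1, 2, 4)) {
      tree <- tryCatch(build_tree(cl$ccf, tol = cfg$tree_tol * mult),
                       error = function(e) NULL)
      if (!is.null(tree)) {
        if (mult > 1)
          message(sprintf("[tree] tolerance raised to %.3g for feasibility",
                          cfg$tree_tol * mult))
        break
      }
    }
    if (is.null(tree)) tree <- build_tree(cl$ccf, tol = cfg$tree_tol)
    bl <- branch_lengths(tree, assignment, counts$sites$var_class)
    p <- file.path(out_dir, "tree.nwk")
    export_newick(tree, bl, p); emit("tree_newick", p)
    p <- file.path(out_dir, "tree.json")
    write_tree_json(tree, p); emit("tree_json", p)
    p <- file.path(out_dir, "clone_sizes.tsv")
    data.table::fwrite(clone_size_timecourse(tree), p, sep = "\t")
    emit("clone_sizes", p)
    .stage_log("tree", sprintf("%d nodes", length(tree$parent)), t0)
  }
  if ("signatures" %in% stages && !is.null(assignment)) {
    ctx <- counts$sites$context
    chans <- ifelse(counts$sites$var_class == "SNV",
                    channel_index(ctx, counts$sites$alt), NA_integer_)
    sp <- branch_spectra(rownames(cl$ccf)[assignment], chans)
    K <- min(as.integer(cfg$n_signatures), sum(sp$displayed))
    if (K < 1L) stop("no branch reaches the 100-SNV extraction floor")
    if (K < cfg$n_signatures)
      message(sprintf("[signatures] only %d branch(es) above the display floor; K lowered to %d",
                      sum(sp$displayed), K))
    fit <- extract_signatures(sp, K = K, seed = as.integer(cfg$seed))
    if (!is.null(cfg$catalog)) {
      catalog <- read_signature_catalog(cfg$catalog)
      matches <- lapply(seq_len(nrow(fit$signatures)), function(i)
        match_catalog(fit$signatures[i, ], catalog))
      mt <- data.frame(signature = rownames(fit$signatures),
                       match = vapply(matches, `[[`, "", "name"),
                       cosine = vapply(matches, `[[`, 1, "cosine"))
      p <- file.path(out_dir, "signature_matches.tsv")
      data.table::fwrite(mt, p, sep = "\t"); emit("signature_matches", p)
    }
    p1 <- file.path(out_dir, "signatures.tsv")
    p2 <- file.path(out_dir, "exposures.tsv")
    write_signature_fit(fit, p1, p2); emit("signatures", p1); emit("exposures", p2)
    .stage_log("signatures", sprintf("K=%d", nrow(fit$signatures)), t0)
  }
  if ("rss" %in% stages && !is.null(cfg$breakpoints)) {
    bps <- read_breakpoints(cfg$breakpoints)
    scfg <- rss_scan_config(window = as.integer(cfg$rss_window),
                            p_cutoff = cfg$rss_p_cutoff)
    hits <- scan_breakpoints(bps, cfg = scfg, ref_seqs = cfg$fasta)
    p <- file.path(out_dir, "rss_hits.tsv")
    data.table::fwrite(hits, p, sep = "\t"); emit("rss_hits", p)
    .stage_log("rss", sprintf("%d hits", sum(hits$hit)), t0)
  }
  if ("track" %in% stages && !is.null(cfg$panel) && !is.null(tree)) {
    branch <- if (!is.null(cfg$branch)) cfg$branch else {
      lens <- branch_lengths(tree, assignment, counts$sites$var_class)
      lens$node[which.max(lens$n_snv * (tree$parent != 0))]
    }
    panel <- read_counts_tsv(cfg$panel)
    sset <- define_site_set(counts$sites, rownames(cl$ccf)[assignment],
                            branch, segments, counts$samples$sample_id)
    # panel shares the original site universe; map through retained rows
    psub <- subset_counts(panel, i = keep)
    bg <- estimate_background(sset, psub)
    res <- track_lineage_timecourse(sset, counts, bg)
    p <- file.path(out_dir, "lineage_timecourse.tsv")
    write_lineage_result(res, p); emit("lineage", p)
    .stage_log("track", sprintf("branch %s, eps %.2g", branch, bg$eps), t0)
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `cluster`, `tree`, `signatures`,
#' `rss`, `track`, `run`. Flags are `--key value` pairs matching the config
#' keys of [read_run_config()]; `--config` names a config file; every flag
#' overrides its config key. `clonetrace --version` prints the package and
#' config-schema versions.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly.
#' @export
clonetrace_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("--help", "-h")) {
    message("usage: clonetrace <simulate|filter|cluster|tree|signatures|rss|track|run> [--key value ...]")
    return(invisible(0L))
  }
  if (args[1L] == "--version") {
    message("clonetrace ", as.character(utils::packageVersion("clonetrace")),
            " (config schema 1)")
    return(invisible(0L))
  }
  cmd <- args[1L]
  flags <- list()
  alias <- c(k = "n_signatures", germline_q = "germline_q")
  i <- 2L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --flag, got ", args[i])
    key <- gsub("-", "_", substring(args[i], 3L))   # --asmd-min == --asmd_min
    if (key %in% names(alias)) key <- alias[[key]]
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg_path <- flags$config; flags$config <- NULL
  if (cmd == "simulate") {
    out <- if (is.null(flags$out_dir)) "." else flags$out_dir
    seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
    scale <- if (is.null(flags$scale)) 1 else as.numeric(flags$scale)
    sim <- simulate_study(paper_template_config(scale), seed)
    write_study(sim, out)
    message("simulated template study written to ", out)
    return(invisible(0L))
  }
  stage_map <- c(filter = "filter", cluster = "cluster", tree = "cluster,tree",
                 signatures = "cluster,tree,signatures", rss = "rss",
                 track = "cluster,tree,track",
                 run = "filter,cluster,tree,signatures,rss,track")
  if (!cmd %in% names(stage_map)) stop("unknown subcommand: ", cmd)
  flags$stages <- unname(stage_map[cmd])
  cfg <- read_run_config(cfg_path, flags)
  run_pipeline(cfg)
  invisible(0L)
}
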