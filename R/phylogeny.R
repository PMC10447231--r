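#' Pigeonhole nesting relation between two clusters
#'
#' `a_contains_b` iff a's CCF is at least b's minus `tol` in every sample and
#' strictly exceeds it by more than `tol` in at least one; `incompatible`
#' when each exceeds the other by more than `tol` in different samples
#' (crossing clusters must sit on distinct branches); otherwise `disjoint`
#' (compatible as siblings).
#'
#' @param a,b Per-sample CCF vectors of equal length.
#' @param tol CCF tolerance.
#' @return One of `"a_contains_b"`, `"b_contains_a"`, `"disjoint"`,
#'   `"incompatible"`.
#' @export
nesting_relation <- function(a, b, tol = 0.05) {
  stopifnot(length(a) == length(b))
  a_ge <- all(a >= b - tol); a_gt <- any(a > b + tol)
  b_ge <- all(b >= a - tol); b_gt <- any(b > a + tol)
  if (a_gt && b_gt) return("incompatible")
  if (a_ge && a_gt) return("a_contains_b")
  if (b_ge && b_gt) return("b_contains_a")
  "disjoint"
}

#' Build a clone tree from cluster CCFs by pigeonhole search
#'
#' Depth-first enumeration of parent assignments consistent with the
#' pigeonhole principle: a child's CCF may not exceed its parent's by more
#' than `tol` in any sample, and the children of any node may not sum to
#' more than the parent plus `tol` in any sample. All feasible trees are
#' ranked by total negative slack (sum over nodes and samples of the amount
#' by which children exceed their parent), then tree depth (shallower
#' preferred), then lexicographic parent order; the top tree is returned.
#' Clusters whose CCF never exceeds `2*tol` are pruned as unplaceable noise.
#'
#' @param ccf K x S matrix of per-sample cluster CCFs (rownames = ids).
#' @param tol CCF tolerance.
#' @param max_trees Enumeration cap (error if exceeded).
#' @return Object of class `clone_tree`: list with `parent` (named integer
#'   vector, 0 = root), `ccf`, `tol`, `feasible` (count), `unplaced`.
#' @export
build_tree <- function(ccf, tol = 0.05, max_trees = 100000L) {
  ccf <- as.matrix(ccf)
  if (is.null(rownames(ccf))) rownames(ccf) <- paste0("C", seq_len(nrow(ccf)))
  ids <- rownames(ccf)
  placeable <- apply(ccf, 1L, max) > 2 * tol
  unplaced <- ids[!placeable]
  ccf_p <- ccf[placeable, , drop = FALSE]
  K <- nrow(ccf_p)
  if (K == 0L) stop("no placeable clusters (all below 2*tol)")
  ord <- order(-rowSums(ccf_p), rownames(ccf_p))
  ccf_o <- ccf_p[ord, , drop = FALSE]
  if (!all(ccf_o[1L, ] >= apply(ccf_o, 2L, max) - tol))
    stop("no truncal cluster: no cluster has maximal CCF in all samples ",
         "(consider raising tol)")
  if (K == 1L) {
    tree <- .new_tree(stats::setNames(0L, rownames(ccf_o)), ccf_o, tol, 1L, unplaced)
    return(tree)
  }

  S <- ncol(ccf_o)
  solutions <- list()
  parent <- integer(K); parent[1L] <- 0L
  child_sum <- matrix(0, K, S)    # running per-sample sum of children CCFs

  recurse <- function(node) {
    if (node > K) {
      solutions[[length(solutions) + 1L]] <<- parent
      if (length(solutions) > max_trees)
        stop("feasible-tree enumeration exceeded max_trees")
      return(invisible())
    }
    for (p in seq_len(node - 1L)) {
      ok_nest <- all(ccf_o[p, ] >= ccf_o[node, ] - tol)
      ok_sum <- all(child_sum[p, ] + ccf_o[node, ] <= ccf_o[p, ] + tol)
      if (ok_nest && ok_sum) {
        parent[node] <<- p
        child_sum[p, ] <<- child_sum[p, ] + ccf_o[node, ]
        recurse(node + 1L)
        child_sum[p, ] <<- child_sum[p, ] - ccf_o[node, ]
      }
    }
    invisible()
  }
  recurse(2L)
  if (!length(solutions))
    stop("no feasible tree at tol = ", tol,
         ": pigeonhole constraints cannot be satisfied; ",
         "consider raising tol")

  score <- function(par) {
    slack <- 0
    for (p in seq_len(K)) {
      ch <- which(par == p)
      if (!length(ch)) next
      exceed <- colSums(ccf_o[ch, , drop = FALSE]) - ccf_o[p, ]
      slack <- slack + sum(pmax(exceed, 0))
    }
    depth <- max(vapply(seq_len(K), function(i) {
      d <- 0L
      while (i != 0L) { i <- par[i]; d <- d + 1L }
      d
    }, 1L))
    c(slack, depth)
  }
  sc <- vapply(solutions, score, numeric(2))
  keymat <- rbind(sc, do.call(rbind, solutions) |> t())
  best <- do.call(order, as.data.frame(t(keymat)))[1L]
  .new_tree(stats::setNames(solutions[[best]], rownames(ccf_o)), ccf_o, tol,
            length(solutions), unplaced)
}

.new_tree <- function(parent, ccf, tol, feasible, unplaced) {
  structure(list(parent = parent, ccf = ccf, tol = tol,
                 feasible = feasible, unplaced = unplaced),
            class = "clone_tree")
}

#' Validate the pigeonhole constraints of a clone tree
#' @param tree A `clone_tree`.
#' @param tol Tolerance (defaults to the tree's own).
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_clone_tree <- function(tree, tol = tree$tol) {
  par <- tree$parent; ccf <- tree$ccf
  if (sum(par == 0L) != 1L) stop("tree must have exactly one root")
  root <- which(par == 0L)
  if (!all(ccf[root, ] >= apply(ccf, 2L, max) - tol))
    stop("root is not maximal in all samples")
  for (p in seq_along(par)) {
    ch <- which(par == p)
    if (!length(ch)) next
    if (any(colSums(ccf[ch, , drop = FALSE]) > ccf[p, ] + tol))
      stop("children of node ", rownames(ccf)[p], " exceed parent CCF")
  }
  invisible(TRUE)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d nodes (%d feasible tree(s) at tol %.3g)\n",
              length(x$parent), x$feasible, x$tol))
  nm <- names(x$parent)
  cat(paste0("  ", nm, " <- ",
             ifelse(x$parent == 0L, "(root)", nm[pmax(x$parent, 1L)]),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Per-branch mutation counts (SNVs, with indels reported separately)
#'
#' @param tree A `clone_tree`.
#' @param assignment Integer/character vector mapping each mutation to a
#'   cluster id (matching `rownames(tree$ccf)`).
#' @param var_class Optional class vector (`"SNV"`/`"insertion"`/`"deletion"`).
#' @return data.frame with `node`, `n_snv`, `n_indel`.
#' @export
branch_lengths <- function(tree, assignment, var_class = NULL) {
  ids <- names(tree$parent)
  lab <- if (is.numeric(assignment)) rownames(tree$ccf)[assignment] else as.character(assignment)
  if (is.null(var_class)) var_class <- rep("SNV", length(lab))
  snv <- table(factor(lab[var_class == "SNV"], levels = ids))
  ind <- table(factor(lab[var_class != "SNV"], levels = ids))
  data.frame(node = ids, n_snv = as.integer(snv), n_indel = as.integer(ind),
             stringsAsFactors = FALSE)
}

#' Exclusive clone sizes per node and sample (fishplot table)
#'
#' The exclusive size of a node in a sample is its CCF minus the summed CCF
#' of its children, floored at 0.
#'
#' @param tree A `clone_tree`.
#' @return data.frame, one row per node, one column per sample.
#' @export
clone_size_timecourse <- function(tree) {
  ccf <- tree$ccf; par <- tree$parent
  out <- ccf
  for (p in seq_along(par)) {
    ch <- which(par == p)
    if (length(ch))
      out[p, ] <- pmax(ccf[p, ] - colSums(ccf[ch, , drop = FALSE]), 0)
  }
  df <- data.frame(node = names(par), stringsAsFactors = FALSE)
  cbind(df, as.data.frame(out, row.names = FALSE))
}

#' Export a clone tree as newick, with SNV counts as branch lengths
#'
#' @param tree A `clone_tree`.
#' @param lengths Optional [branch_lengths()] table; zero lengths otherwise.
#' @param path Optional output path; the newick string is returned invisibly.
#' @export
export_newick <- function(tree, lengths = NULL, path = NULL) {
  par <- tree$parent
  len <- stats::setNames(rep(0L, length(par)), names(par))
  if (!is.null(lengths)) len[lengths$node] <- lengths$n_snv
  build <- function(i) {
    ch <- which(par == i)
    nm <- names(par)[i]
    inner <- if (length(ch)) paste0("(", paste(vapply(ch, build, ""),
                                               collapse = ","), ")") else ""
    paste0(inner, nm, ":", len[i])
  }
  nwk <- paste0(build(which(par == 0L)), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

#' Serialize a clone tree with annotations as JSON
#' @param tree A `clone_tree`.
#' @param path Output path.
#' @param annotations Optional named list (e.g. driver labels) passed through.
#' @export
write_tree_json <- function(tree, path, annotations = NULL) {
  obj <- list(nodes = names(tree$parent),
              parent = ifelse(tree$parent == 0L, NA,
                              names(tree$parent)[pmax(tree$parent, 1L)]),
              ccf = as.data.frame(tree$ccf),
              tol = tree$tol, unplaced = tree$unplaced,
              annotations = annotations)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
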