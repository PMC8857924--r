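## Query placement -----------------------------------------------------------
##
## A query's filtered calls at branch-assigned SNPs are binned per branch
## into support (derived observed) and conflict (ancestral observed).  Two
## placement methods consume the tally: a best-path traversal that walks
## every root-to-tip path, pruning a path at the first branch whose conflict
## count exceeds a threshold, and a per-edge likelihood converted to
## Bayesian posterior probabilities with a conservative 99% placement clade.

#' Bin query calls into per-branch support and conflict counts
#'
#' A derived call at a SNP assigned to branch b supports b; an ancestral
#' call conflicts with it; missing calls are ignored.  Calls at sites that
#' are not assigned (or not present) in \code{assignments} are ignored and
#' counted in the \code{n_ignored} attribute.
#'
#' @param calls calls data frame (see \code{\link{filter_calls}}).
#' @param assignments assignments data frame from \code{\link{assign_all}}
#'   (or a \code{branch_assignment} object).
#' @return data frame with one row per branch that received at least one
#'   call: \code{branch}, \code{support}, \code{conflict}; attribute
#'   \code{n_ignored} counts calls at unassigned sites.
#' @export
tally <- function(calls, assignments) {
  a <- if (inherits(assignments, "branch_assignment"))
    assignments$assignments else assignments
  a <- a[a$status == "assigned", , drop = FALSE]
  akey <- paste(a$chrom, a$pos)
  ckey <- paste(calls$chrom, calls$pos)
  j <- match(ckey, akey)
  informative <- !is.na(j) & calls$state != "missing"
  n_ignored <- sum(is.na(j) & calls$state != "missing")
  br <- a$branch[j[informative]]
  st <- calls$state[informative]
  if (length(br) == 0L) {
    out <- data.frame(branch = integer(0), support = integer(0),
                      conflict = integer(0))
  } else {
    sup <- tapply(st == "derived", br, sum)
    con <- tapply(st == "ancestral", br, sum)
    out <- data.frame(branch = as.integer(names(sup)),
                      support = as.integer(sup),
                      conflict = as.integer(con))
  }
  attr(out, "n_ignored") <- n_ignored
  out
}

## tally data frame -> per-node support/conflict vectors
tally_vectors <- function(tree, tal) {
  sup <- integer(tree$n_node)
  con <- integer(tree$n_node)
  if (nrow(tal)) {
    bad <- !(tal$branch %in% branch_ids(tree))
    if (any(bad)) stop("tally contains unknown branch id(s): ",
                       paste(tal$branch[bad], collapse = ", "))
    sup[tal$branch] <- tal$support
    con[tal$branch] <- tal$conflict
  }
  list(sup = sup, con = con)
}

#' Best-path placement
#'
#' Walks every root-to-tip path.  A path is truncated at the first branch
#' whose conflict count exceeds \code{max_conflict}; the admissible prefix
#' above the stop remains a candidate.  Each prefix is scored by cumulative
#' support, and the winner's best branch is its deepest branch beyond which
#' no further support is added.  Ties in cumulative support are broken by
#' fewer cumulative conflicts, then by the shallower best branch, then by
#' the smallest branch id; the tie flag is set whenever the conflict
#' criterion fails to break a support tie.
#'
#' @param tree a \code{ref_tree}.
#' @param tally per-branch tally from \code{\link{tally}}.
#' @param max_conflict maximum conflicting markers tolerated on a single
#'   branch before the path is stopped (default 3).
#' @return a list of class \code{"best_path_result"}: best \code{branch}
#'   (NA when no call supports any path), counts above and on the branch,
#'   \code{insertion_fraction}, the annotation string
#'   \code{"[sa-ca; so-co]"}, \code{tie}, \code{pruned_paths},
#'   \code{placed}.
#' @export
best_path <- function(tree, tally, max_conflict = 3) {
  tv <- tally_vectors(tree, tally)
  sup <- tv$sup; con <- tv$con
  leaves <- seq_len(tree$n_tip)
  cand <- list()
  pruned <- 0L
  seen <- character(0)
  for (lf in leaves) {
    path <- path_to_root(tree, lf)
    stop_at <- which(con[path] > max_conflict)
    if (length(stop_at)) {
      pruned <- pruned + 1L
      path <- path[seq_len(stop_at[1L] - 1L)]
    }
    if (length(path) == 0L) next
    ## deepest branch beyond which no support is added
    supported <- which(sup[path] > 0L)
    if (length(supported) == 0L) next
    path <- path[seq_len(supported[length(supported)])]
    b <- path[length(path)]
    key <- as.character(b)
    if (key %in% seen) next
    seen <- c(seen, key)
    cand[[length(cand) + 1L]] <- list(
      branch = b,
      support = sum(sup[path]), conflict = sum(con[path]),
      depth = length(path))
  }
  if (length(cand) == 0L) {
    res <- list(branch = NA_integer_, support_above = 0L,
                conflict_above = 0L, support_on = 0L, conflict_on = 0L,
                insertion_fraction = 0.5,
                annotation = "[0-0; 0-0]", tie = TRUE,
                pruned_paths = pruned, placed = FALSE)
    class(res) <- "best_path_result"
    return(res)
  }
  supv <- vapply(cand, `[[`, 0, "support")
  conv <- vapply(cand, `[[`, 0, "conflict")
  depv <- vapply(cand, `[[`, 0, "depth")
  brv <- vapply(cand, `[[`, 0L, "branch")
  ord <- order(-supv, conv, depv, brv)
  top <- ord[1L]
  support_tied <- supv == supv[top]
  tie <- sum(support_tied & conv == conv[top]) > 1L
  b <- brv[top]
  path <- path_to_root(tree, b)
  above <- path[-length(path)]
  s_on <- sup[b]; c_on <- con[b]
  res <- list(
    branch = b,
    support_above = as.integer(sum(sup[above])),
    conflict_above = as.integer(sum(con[above])),
    support_on = as.integer(s_on), conflict_on = as.integer(c_on),
    insertion_fraction = if (s_on + c_on == 0L) 0.5
      else s_on / (s_on + c_on),
    annotation = sprintf("[%d-%d; %d-%d]",
                         sum(sup[above]), sum(con[above]), s_on, c_on),
    tie = tie, pruned_paths = pruned, placed = TRUE)
  class(res) <- "best_path_result"
  res
}

#' @export
print.best_path_result <- function(x, ...) {
  if (!x$placed) cat("Best path: unplaced (no supporting calls)\n")
  else cat("Best path: branch", x$branch, x$annotation,
           if (x$tie) "(tie)" else "", "\n")
  invisible(x)
}

#' Per-edge likelihood placement with Bayesian posteriors
#'
#' For a candidate attachment edge e the query is expected to be derived at
#' SNPs on strict ancestors of e and ancestral everywhere else; SNPs on e
#' itself are ignored (the conservative assumption that mutations on the
#' attachment branch are uninformative about position along it).  Each
#' expected state is observed with probability 1 - epsilon and flipped with
#' probability epsilon.  Posteriors follow from a uniform prior over edges
#' via log-sum-exp normalization.
#'
#' @inheritParams best_path
#' @param epsilon per-call error probability after filtering, in (0, 0.5);
#'   default 0.01 (query calls are noisier than reference genotypes).
#' @param posterior_threshold report branches with posterior above this
#'   (default 0.01).
#' @param clade_p the placement clade is the lowest branch whose
#'   clade-inclusive posterior sum exceeds 1 - \code{clade_p}
#'   (default 0.01, i.e. a 99% clade).
#' @return a list of class \code{"placement_posterior"}: \code{posterior}
#'   data frame (branch, loglik, posterior), \code{best} branch,
#'   \code{reported} branches above the threshold, \code{clade99} branch
#'   (NA when no single root-side clade concentrates the mass).
#' @export
likelihood_place <- function(tree, tally, epsilon = 0.01,
                             posterior_threshold = 0.01, clade_p = 0.01) {
  le <- log_eps(epsilon)
  lm <- le[["match"]]; lx <- le[["mismatch"]]
  tv <- tally_vectors(tree, tally)
  sup <- tv$sup; con <- tv$con
  S <- sum(sup); C <- sum(con)
  bids <- branch_ids(tree)

  ## cumulative support/conflict over strict ancestors, by preorder
  S_anc <- numeric(tree$n_node)
  C_anc <- numeric(tree$n_node)
  for (nd in order_nodes_preorder(tree$root, tree$children, tree$n_node)) {
    p <- tree$parent[nd]
    if (is.na(p)) next
    if (p == tree$root) { S_anc[nd] <- 0; C_anc[nd] <- 0 }
    else { S_anc[nd] <- S_anc[p] + sup[p]; C_anc[nd] <- C_anc[p] + con[p] }
  }
  ll <- S_anc[bids] * lm + C_anc[bids] * lx +
    (S - S_anc[bids] - sup[bids]) * lx +
    (C - C_anc[bids] - con[bids]) * lm
  m <- max(ll)
  post <- exp(ll - m)
  post <- post / sum(post)

  best <- bids[which.max(post)]
  reported <- bids[post > posterior_threshold]

  ## clade-inclusive posterior sums by postorder accumulation
  post_full <- numeric(tree$n_node)
  post_full[bids] <- post
  clade_sum <- post_full
  po <- rev(order_nodes_preorder(tree$root, tree$children, tree$n_node))
  for (nd in po)
    for (ch in tree$children[[nd]])
      clade_sum[nd] <- clade_sum[nd] + clade_sum[ch]
  path <- path_to_root(tree, best)
  qual <- path[clade_sum[path] > 1 - clade_p]
  clade99 <- if (length(qual)) qual[length(qual)] else NA_integer_

  res <- list(
    posterior = data.frame(branch = bids, loglik = ll, posterior = post),
    best = best, reported = reported, clade99 = clade99,
    epsilon = epsilon)
  class(res) <- "placement_posterior"
  res
}

#' @export
print.placement_posterior <- function(x, ...) {
  cat("Likelihood placement: best branch", x$best,
      sprintf("(posterior %.3f)",
              x$posterior$posterior[x$posterior$branch == x$best]), "\n")
  cat("  99% placement clade branch:",
      if (is.na(x$clade99)) "root (ambiguous)" else x$clade99, "\n")
  invisible(x)
}

#' Insert a placed query into the tree with its annotation
#'
#' The query leaf is labelled \code{name} plus the best-path annotation
#' string (e.g. \code{"ASH008 [55-0; 1-0]"}).  When the best-path result is
#' tied and a fallback branch (typically the 99% placement clade branch) is
#' supplied, insertion happens there instead, with a warning.  An unplaced
#' result leaves the tree unchanged.
#'
#' @param tree a \code{ref_tree}.
#' @param result a \code{best_path_result}.
#' @param name query sample name.
#' @param sep separator between name and annotation (default a space).
#' @param fallback_branch branch to use when \code{result$tie} is set
#'   (default NULL: insert at the tied best branch anyway, with a warning).
#' @return the tree with the query inserted (or unchanged if unplaced, with
#'   attribute \code{placed = FALSE}).
#' @export
annotate_and_insert <- function(tree, result, name, sep = " ",
                                fallback_branch = NULL) {
  stopifnot(inherits(result, "best_path_result"))
  if (!result$placed) {
    warning("sample ", name, " unplaced (no supporting calls); ",
            "tree unchanged", call. = FALSE)
    attr(tree, "placed") <- FALSE
    return(tree)
  }
  branch <- result$branch
  fraction <- result$insertion_fraction
  if (result$tie) {
    if (!is.null(fallback_branch) && !is.na(fallback_branch)) {
      warning("tied best path for ", name,
              "; inserting at fallback branch ", fallback_branch,
              call. = FALSE)
      branch <- fallback_branch
      fraction <- 0.5
    } else {
      warning("tied best path for ", name, "; using deterministic tie-break",
              call. = FALSE)
    }
  }
  out <- insert_query(tree, branch, fraction,
                      paste(name, result$annotation, sep = sep))
  attr(out, "placed") <- TRUE
  out
}
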