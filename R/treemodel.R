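#' @importFrom stats setNames rpois runif rbinom
#' @importFrom utils read.delim write.table
NULL

## Reference tree ------------------------------------------------------------
##
## A "ref_tree" wraps an ape "phylo" object with precomputed indices used by
## every downstream step.  Branches are identified with their child node
## (ape node numbering: tips 1..n, internals n+1..; the root carries no
## branch), so "the clade below branch b" is simply the set of tips
## descending from node b.

#' Build an indexed reference tree from an ape phylo object
#'
#' @param phy a rooted object of class \code{"phylo"} with unique, non-empty
#'   tip labels.  Multifurcations are accepted.
#' @return an object of class \code{"ref_tree"}: the \code{phylo} object plus
#'   parent pointers, child lists, per-branch clade membership (a logical
#'   tip-membership matrix), branch depths and optional branch lengths.
#' @export
as_ref_tree <- function(phy) {
  if (!inherits(phy, "phylo"))
    stop("`phy` must be an object of class \"phylo\"")
  lab <- phy$tip.label
  if (any(!nzchar(lab))) stop("empty leaf label in tree")
  if (anyDuplicated(lab)) {
    dup <- unique(lab[duplicated(lab)])
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  n_tip <- length(lab)
  n_node <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("tree must have exactly one root (found ", length(root), ")")
  children <- vector("list", n_node)
  for (i in seq_len(nrow(phy$edge)))
    children[[phy$edge[i, 1L]]] <-
      c(children[[phy$edge[i, 1L]]], phy$edge[i, 2L])

  ## clade membership by postorder accumulation
  clade <- matrix(FALSE, n_node, n_tip)
  clade[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  po <- rev(order_nodes_preorder(root, children, n_node))
  for (nd in po) {
    for (ch in children[[nd]])
      clade[nd, ] <- clade[nd, ] | clade[ch, ]
  }

  depth <- rep(NA_integer_, n_node)
  depth[root] <- 0L
  for (nd in order_nodes_preorder(root, children, n_node))
    if (nd != root) depth[nd] <- depth[parent[nd]] + 1L

  blen <- rep(NA_real_, n_node)
  if (!is.null(phy$edge.length))
    blen[phy$edge[, 2L]] <- phy$edge.length

  structure(list(
    phy = phy, n_tip = n_tip, n_node = n_node, root = root,
    parent = parent, children = children, clade = clade,
    depth = depth, branch_length = blen,
    has_lengths = !is.null(phy$edge.length),
    leaf_names = lab
  ), class = "ref_tree")
}

## preorder node walk (root first); handles multifurcations
order_nodes_preorder <- function(root, children, n_node) {
  out <- integer(n_node)
  stack <- root
  k <- 0L
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- nd
    ch <- children[[nd]]
    if (length(ch)) stack <- c(stack, rev(ch))
  }
  out[seq_len(k)]
}

#' Parse a newick string or file into an indexed reference tree
#'
#' @param x a newick string (must contain a terminating \code{";"}) or the
#'   path of a file holding one.
#' @return a \code{ref_tree}.  Leaf order is the input order; branch lengths
#'   are optional and internal labels are ignored for indexing but preserved
#'   for output.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (grepl(";", x, fixed = TRUE)) x else {
    if (!file.exists(x)) stop("newick file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  validate_newick_syntax(txt)
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) stop("malformed newick: parser returned no tree")
  as_ref_tree(phy)
}

## Cheap syntactic pre-check so parse failures carry a character offset.
validate_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  quoted <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at character ", i)
    }
    if (ch == ";" && depth != 0L)
      stop("malformed newick: ", depth, " unclosed '(' at character ", i)
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at end of input")
  if (!any(chars == ";"))
    stop("malformed newick: missing terminating ';'")
  invisible(TRUE)
}

#' Branch ids of a reference tree
#'
#' Every non-root node carries the branch above it; the root has none.
#' @param tree a \code{ref_tree}.
#' @return integer vector of branch ids.
#' @export
branch_ids <- function(tree) {
  setdiff(seq_len(tree$n_node), tree$root)
}

check_branch <- function(tree, branch) {
  if (!(is.numeric(branch) && length(branch) == 1L &&
        branch %in% seq_len(tree$n_node) && branch != tree$root))
    stop("unknown branch id: ", branch)
  as.integer(branch)
}

#' Leaves below a branch
#'
#' @param tree a \code{ref_tree}.
#' @param branch branch id (child-node id).
#' @return character vector of leaf names in the clade below (and including,
#'   for a leaf branch) the given branch.
#' @export
clade_leaves <- function(tree, branch) {
  branch <- check_branch(tree, branch)
  tree$leaf_names[tree$clade[branch, ]]
}

#' Path from the root to a branch
#'
#' @param tree a \code{ref_tree}.
#' @param branch branch id.
#' @return integer vector of branch ids from the root-adjacent branch down to
#'   \code{branch} inclusive; its length equals the branch depth.
#' @export
path_to_root <- function(tree, branch) {
  branch <- check_branch(tree, branch)
  path <- integer(0)
  nd <- branch
  while (!is.na(tree$parent[nd])) {
    path <- c(nd, path)
    nd <- tree$parent[nd]
  }
  path
}

## strict ancestors of a branch (branch ids above it, root excluded)
strict_ancestors <- function(tree, branch) {
  p <- path_to_root(tree, branch)
  p[-length(p)]
}

is_ancestor_or_self <- function(tree, anc, branch) {
  anc %in% path_to_root(tree, branch)
}

#' Insert a query sample as a new tip along a branch
#'
#' Splits the branch above node \code{branch} at \code{fraction} of its
#' length measured from the parent end (0 = at the parent node, 1 = at the
#' child node) and attaches a new terminal leaf there.  Trees without branch
#' lengths are treated as having unit lengths for the split arithmetic only.
#'
#' @param tree a \code{ref_tree}.
#' @param branch branch id to split.
#' @param fraction position of the new node along the branch, in [0, 1].
#' @param name label for the new leaf; must not collide with an existing one.
#' @return a new \code{ref_tree} with one extra internal node and one extra
#'   leaf; the original topology is otherwise unchanged.
#' @export
insert_query <- function(tree, branch, fraction, name) {
  branch <- check_branch(tree, branch)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction < 0 || fraction > 1)
    stop("`fraction` must be a number in [0, 1]")
  if (name %in% tree$leaf_names)
    stop("leaf name already present in tree: ", name)

  phy <- tree$phy
  n_tip <- tree$n_tip
  had_lengths <- !is.null(phy$edge.length)
  el <- if (had_lengths) phy$edge.length else rep(1, nrow(phy$edge))

  ## Renumber: old tips keep ids, new tip = n_tip + 1, old internals shift
  ## by +1, new internal node gets the last id.
  shift <- function(v) ifelse(v > n_tip, v + 1L, v)
  edge <- cbind(shift(phy$edge[, 1L]), shift(phy$edge[, 2L]))
  new_tip <- n_tip + 1L
  new_int <- n_tip + 1L + phy$Nnode + 1L

  child <- shift(branch)
  irow <- which(edge[, 2L] == child)
  len <- el[irow]
  parent_side <- fraction * len
  child_side <- len - parent_side

  edge_new <- rbind(
    edge[seq_len(irow - 1L), , drop = FALSE],
    c(edge[irow, 1L], new_int),
    c(new_int, child),
    c(new_int, new_tip),
    if (irow < nrow(edge)) edge[(irow + 1L):nrow(edge), , drop = FALSE]
  )
  el_new <- c(el[seq_len(irow - 1L)], parent_side, child_side, child_side,
              if (irow < nrow(edge)) el[(irow + 1L):nrow(edge)])

  phy2 <- list(edge = edge_new, Nnode = phy$Nnode + 1L,
               tip.label = c(phy$tip.label, name))
  if (had_lengths) phy2$edge.length <- el_new
  if (!is.null(phy$node.label)) {
    ## old internal node k (k = n_tip+1 .. ) keeps its label; the new node
    ## (last id) gets an empty label
    phy2$node.label <- c(phy$node.label, "")
  }
  class(phy2) <- "phylo"
  phy2 <- ape::reorder.phylo(phy2, "cladewise")
  as_ref_tree(phy2)
}

#' Serialize a reference tree to newick
#'
#' Unlike \code{ape::write.tree}, leaf labels containing spaces, brackets or
#' other newick-reserved characters are emitted as quoted labels, so
#' annotation suffixes such as \code{"[55-0; 1-0]"} survive round trips
#' through the output file.
#'
#' @param tree a \code{ref_tree}.
#' @param file optional path; when given the newick string is written there.
#' @return the newick string, invisibly when \code{file} is given.
#' @export
write_newick <- function(tree, file = NULL) {
  quote_label <- function(x) {
    if (grepl("[][(),:; '\t]", x))
      paste0("'", gsub("'", "''", x), "'")
    else x
  }
  rec <- function(nd) {
    ch <- tree$children[[nd]]
    lab <- if (nd <= tree$n_tip) quote_label(tree$leaf_names[nd]) else ""
    body <- if (length(ch))
      paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", lab)
    else lab
    if (!is.na(tree$parent[nd]) && tree$has_lengths &&
        !is.na(tree$branch_length[nd]))
      body <- paste0(body, ":", format(tree$branch_length[nd], digits = 12))
    body
  }
  txt <- paste0(rec(tree$root), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Cross-check tree leaves against genotyped sample names
#'
#' Leaf-to-sample matching is exact and case-sensitive.  Reports, without
#' failing, tree leaves that have no genotypes and genotyped samples absent
#' from the tree; fails only when there is no overlap at all.
#'
#' @param tree a \code{ref_tree}.
#' @param samples character vector of genotyped sample names (e.g. VCF
#'   columns).
#' @return (invisibly) a list with components \code{shared},
#'   \code{leaves_without_genotypes} and \code{samples_not_in_tree}.
#' @export
check_samples <- function(tree, samples) {
  shared <- intersect(tree$leaf_names, samples)
  missing_gt <- setdiff(tree$leaf_names, samples)
  extra <- setdiff(samples, tree$leaf_names)
  if (length(shared) == 0L)
    stop("no overlap between tree leaves and genotyped samples")
  if (length(missing_gt))
    warning(length(missing_gt), " tree leaf/leaves without genotypes: ",
            paste(utils::head(missing_gt, 5), collapse = ", "),
            if (length(missing_gt) > 5) ", ..." else "", call. = FALSE)
  if (length(extra))
    warning(length(extra), " genotyped sample(s) absent from tree: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "", call. = FALSE)
  invisible(list(shared = shared,
                 leaves_without_genotypes = missing_gt,
                 samples_not_in_tree = extra))
}

#' @export
print.ref_tree <- function(x, ...) {
  cat("Reference tree:", x$n_tip, "leaves,",
      length(branch_ids(x)), "branches",
      if (x$has_lengths) "(with branch lengths)" else "(no branch lengths)",
      "\n")
  invisible(x)
}
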