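## Haplogroup reconciliation -------------------------------------------------
##
## The genotype-based tree is reconciled with a curated marker nomenclature
## (ISOGG-style): a branch is labelled with a haplogroup when a curated
## marker coincides (position + derived allele) with a SNP assigned to that
## branch.  After placement, curated markers for sublineages below the
## anchor label are tested directly from the query's calls, refining the
## placement to the most specific supported named lineage.  The label
## hierarchy is the long-form name nesting: label X is below Y iff X starts
## with Y.

#' Load a curated marker table
#'
#' Expects a TSV with columns \code{name}, \code{haplogroup}, \code{chrom},
#' \code{pos}, \code{ancestral}, \code{derived} (header required, extra
#' columns ignored).  Non-SNP rows (alleles not single distinct bases) are
#' skipped with a counted warning; duplicates by (pos, derived) are
#' collapsed, keeping all names.  Names carrying provisional/uncertain
#' status suffixes (\code{~} or parentheses) are retained but flagged.
#'
#' @param table path to the TSV, or an equivalent data frame.
#' @return data frame of markers: \code{name} (comma-joined when
#'   collapsed), \code{haplogroup}, \code{chrom}, \code{pos},
#'   \code{ancestral}, \code{derived}, \code{provisional}.
#' @export
load_markers <- function(table) {
  df <- if (is.character(table)) {
    if (!file.exists(table)) stop("marker table not found: ", table)
    utils::read.delim(table, stringsAsFactors = FALSE)
  } else as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("name", "haplogroup", "chrom", "pos", "ancestral", "derived")
  if (!all(need %in% names(df)))
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("marker table is empty")
  bases <- c("A", "C", "G", "T")
  ok <- df$ancestral %in% bases & df$derived %in% bases &
    df$ancestral != df$derived & nzchar(df$haplogroup) &
    !is.na(suppressWarnings(as.integer(df$pos)))
  if (any(!ok))
    warning(sum(!ok), " malformed/non-SNP marker row(s) skipped",
            call. = FALSE)
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no valid markers after filtering")
  df$pos <- as.integer(df$pos)
  df$provisional <- grepl("~|\\(", df$name) | grepl("~|\\(", df$haplogroup)
  key <- paste(df$chrom, df$pos, df$derived)
  if (anyDuplicated(key)) {
    df <- do.call(rbind, lapply(split(df, key), function(g) {
      g1 <- g[1L, , drop = FALSE]
      g1$name <- paste(unique(g$name), collapse = ",")
      g1$provisional <- all(g$provisional)
      g1
    }))
    rownames(df) <- NULL
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
  }
  df
}

#' Label tree branches from curated markers
#'
#' A branch receives a haplogroup label when a curated marker's position and
#' derived allele coincide with a SNP assigned to it.  Labels are used for
#' reporting only and never alter placement.
#'
#' @param tree a \code{ref_tree}.
#' @param assignments assignments from \code{\link{assign_all}}.
#' @param markers marker table from \code{\link{load_markers}}.
#' @return named list: branch id (as character) -> character vector of
#'   labels.
#' @export
label_branches <- function(tree, assignments, markers) {
  a <- if (inherits(assignments, "branch_assignment"))
    assignments$assignments else assignments
  a <- a[a$status == "assigned", , drop = FALSE]
  akey <- paste(a$chrom, a$pos, a$derived)
  mkey <- paste(markers$chrom, markers$pos, markers$derived)
  j <- match(mkey, akey)
  hit <- !is.na(j)
  out <- split(markers$haplogroup[hit], a$branch[j[hit]])
  lapply(out, unique)
}

## X below-or-equal Y in the long-form nomenclature
label_below <- function(x, y) startsWith(x, y)

#' Refine a placement to the most specific supported haplogroup
#'
#' Among curated markers whose labels are hierarchical descendants (or
#' self) of the anchor branch's label, a label is supported when at least
#' one of its markers is observed derived in the query's calls.  The most
#' specific (longest) supported label wins; when two incomparable labels
#' (e.g. sibling sublineages, a damage signature) are both supported, the
#' call falls back to their deepest common supported-or-anchor ancestor and
#' reports both as alternates.  Provisional markers support a label only if
#' no unflagged marker contradicts it (i.e. is observed ancestral for that
#' same label).
#'
#' @param anchor_label the haplogroup label of the placement branch (from
#'   \code{\link{label_branches}}); NA yields a tree-only placement.
#' @param calls query calls including marker sites (the pileup step targets
#'   curated marker positions too); matched by chrom+pos+derived allele.
#' @param markers marker table from \code{\link{load_markers}}.
#' @return a list of class \code{"haplogroup_call"}: \code{terminal} label,
#'   \code{support} (derived-observed marker names on the chosen path),
#'   \code{conflicts} (ancestral-observed markers on the path),
#'   \code{alternates}, \code{no_sublineage_data}, \code{tree_only}.
#' @export
refine_below <- function(anchor_label, calls, markers) {
  res <- list(terminal = NA_character_, support = character(0),
              conflicts = character(0), alternates = character(0),
              no_sublineage_data = FALSE, tree_only = FALSE)
  class(res) <- "haplogroup_call"
  if (is.na(anchor_label) || !nzchar(anchor_label %||% "")) {
    res$tree_only <- TRUE
    return(res)
  }
  res$terminal <- anchor_label
  below <- markers[label_below(markers$haplogroup, anchor_label), ,
                   drop = FALSE]
  if (nrow(below) == 0L) {
    res$no_sublineage_data <- TRUE
    return(res)
  }
  ckey <- paste(calls$chrom, calls$pos)
  j <- match(paste(below$chrom, below$pos), ckey)
  obs_state <- rep("missing", nrow(below))
  has <- !is.na(j)
  ## a call is derived *for the marker* when its base equals the marker's
  ## derived allele (site polarity in the reference panel may differ)
  obs_base <- calls$base[j[has]]
  obs_state[has] <- ifelse(is.na(obs_base), "missing",
                           ifelse(obs_base == below$derived[has], "derived",
                                  ifelse(obs_base == below$ancestral[has],
                                         "ancestral", "missing")))
  if (all(obs_state == "missing")) {
    res$no_sublineage_data <- TRUE
    return(res)
  }
  der <- below[obs_state == "derived", , drop = FALSE]
  anc <- below[obs_state == "ancestral", , drop = FALSE]

  supported <- unique(der$haplogroup)
  ## provisional-only support is vetoed by an unflagged ancestral marker
  ## for the same label
  keep <- vapply(supported, function(lb) {
    der_lb <- der[der$haplogroup == lb, , drop = FALSE]
    if (all(der_lb$provisional)) {
      veto <- anc$haplogroup == lb & !anc$provisional
      !any(veto)
    } else TRUE
  }, TRUE)
  supported <- supported[keep]
  if (length(supported) == 0L) {
    res$no_sublineage_data <- TRUE
    return(res)
  }
  ## maximal supported labels (not a prefix of another supported one)
  maximal <- supported[!vapply(supported, function(x)
    any(supported != x & label_below(supported, x)), TRUE)]
  if (length(maximal) == 1L) {
    res$terminal <- maximal
  } else {
    ## incomparable sublineages: fall back to deepest common supported
    ## ancestor (or the anchor), report all maximal labels as alternates
    common <- anchor_label
    anc_chain <- supported[order(nchar(supported))]
    for (lb in anc_chain)
      if (all(label_below(maximal, lb))) common <- lb
    res$terminal <- common
    res$alternates <- maximal
  }
  on_path <- label_below(res$terminal, below$haplogroup) |
    label_below(below$haplogroup, res$terminal)
  res$support <- below$name[obs_state == "derived" & on_path]
  res$conflicts <- below$name[obs_state == "ancestral" & on_path]
  res
}

#' @export
print.haplogroup_call <- function(x, ...) {
  if (x$tree_only) {
    cat("Haplogroup: tree-only placement (anchor branch has no label)\n")
    return(invisible(x))
  }
  cat("Haplogroup:", x$terminal,
      if (x$no_sublineage_data) "(no sublineage data)" else "", "\n")
  if (length(x$support))
    cat("  supporting markers:", paste(x$support, collapse = ", "), "\n")
  if (length(x$conflicts))
    cat("  conflicting markers:", paste(x$conflicts, collapse = ", "), "\n")
  if (length(x$alternates))
    cat("  alternates:", paste(x$alternates, collapse = ", "), "\n")
  invisible(x)
}
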