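## Self-contained simulator --------------------------------------------------
##
## Generates a random rooted reference tree, an infinite-sites genotype
## panel over its leaves, a branch-consistent curated marker table, and a
## damaged low-coverage query pileup with recorded truth, so that every
## stage of the workflow can be exercised without external data.

#' Simulation configuration
#'
#' @param n_leaves number of reference samples (>= 2).
#' @param n_sites number of biallelic sites to simulate.
#' @param attachment branch id the query diverges from, or \code{"random"}.
#' @param coverage mean reads per site for the query (Poisson).
#' @param base_error per-read probability of a uniform base-call error.
#' @param deamination per-read probability delta of a damage flip: C -> T at
#'   C/T-allele sites and G -> A at G/A-allele sites.
#' @param missing_fraction fraction of reference genotypes set to missing.
#' @param attachment_fraction where along the attachment branch the query
#'   diverges, measured from the parent end in [0, 1]; mutations on the
#'   parent-side portion of the branch are shared with (derived in) the
#'   query.  Default 0.5.
#' @param min_sites_per_branch guarantee at least this many sites on every
#'   branch (the remainder is placed proportionally to branch length);
#'   default 0.
#' @param chrom chromosome name used in all outputs.
#' @param seed integer seed; mandatory for reproducibility.
#' @return a list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_leaves = 16, n_sites = 200, attachment = "random",
                       coverage = 3, base_error = 0, deamination = 0,
                       missing_fraction = 0, attachment_fraction = 0.5,
                       min_sites_per_branch = 0, chrom = "chrY",
                       seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("`seed` is mandatory")
  stopifnot(n_leaves >= 2, n_sites >= 1,
            coverage >= 0, base_error >= 0, base_error <= 1,
            deamination >= 0, deamination <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            attachment_fraction >= 0, attachment_fraction <= 1)
  structure(list(n_leaves = as.integer(n_leaves),
                 n_sites = as.integer(n_sites),
                 attachment = attachment, coverage = coverage,
                 base_error = base_error, deamination = deamination,
                 missing_fraction = missing_fraction,
                 attachment_fraction = attachment_fraction,
                 min_sites_per_branch = as.integer(min_sites_per_branch),
                 chrom = chrom, seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a reference tree and genotype panel
#'
#' Draws a random rooted tree (random splits, uniform branch lengths),
#' places each site on one branch (with an optional per-branch floor,
#' otherwise proportional to branch length; unique positions, infinite
#' sites), and sets each leaf's genotype to derived iff the leaf lies in
#' the branch's clade.  Site polarity is swapped at random (REF = derived)
#' with the swap recorded, to exercise polarity inference downstream.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"sim_reference"}: \code{tree} (a
#'   \code{ref_tree}), \code{genotypes} (sites x leaves matrix of 0/1/NA in
#'   ALT dosage), \code{sites} (chrom, pos, ref, alt), \code{truth} (per
#'   site: branch, ancestral, derived, derived_is_alt), \code{config}.
#' @export
sim_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  phy <- ape::rtree(config$n_leaves)
  phy$tip.label <- sprintf("S%03d", seq_len(config$n_leaves))
  tree <- as_ref_tree(phy)
  bids <- branch_ids(tree)
  B <- length(bids)

  m <- config$min_sites_per_branch
  if (m * B > config$n_sites)
    stop("n_sites too small for min_sites_per_branch (need >= ", m * B, ")")
  site_branch <- rep(bids, m)
  extra <- config$n_sites - length(site_branch)
  if (extra > 0) {
    w <- tree$branch_length[bids]
    w[is.na(w) | w <= 0] <- 1e-6
    site_branch <- c(site_branch,
                     sample(bids, extra, replace = TRUE, prob = w))
  }
  site_branch <- sample(site_branch)          # shuffle along the chromosome

  pos_space <- max(50L * config$n_sites, 1000L)
  pos <- sort(sample.int(pos_space, config$n_sites))

  ancestral <- sample(BASES, config$n_sites, replace = TRUE)
  derived <- vapply(ancestral, function(b)
    sample(setdiff(BASES, b), 1L), "")
  swap <- runif(config$n_sites) < 0.5         # REF = derived where TRUE

  G <- matrix(0L, config$n_sites, tree$n_tip,
              dimnames = list(NULL, tree$leaf_names))
  for (i in seq_len(config$n_sites))
    G[i, tree$clade[site_branch[i], ]] <- 1L   # 1 = derived carrier
  if (config$missing_fraction > 0) {
    drop <- runif(length(G)) < config$missing_fraction
    G[drop] <- NA_integer_
  }
  ## ALT dosage: when polarity is swapped, REF = derived so carriers are 0
  X <- G
  X[swap, ] <- 1L - G[swap, ]

  sites <- data.frame(
    chrom = config$chrom, pos = pos,
    ref = ifelse(swap, derived, ancestral),
    alt = ifelse(swap, ancestral, derived),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    chrom = config$chrom, pos = pos, branch = site_branch,
    ancestral = ancestral, derived = derived,
    derived_is_alt = !swap, stringsAsFactors = FALSE)
  structure(list(tree = tree, genotypes = X, sites = sites,
                 truth = truth, config = config),
            class = "sim_reference")
}

#' Write a simulated reference panel as a haploid VCF
#'
#' @param reference a \code{sim_reference}.
#' @param path output path (plain text VCF).
#' @param include_aa write the known ancestral allele as an \code{AA=} INFO
#'   annotation (default TRUE).  Without it, sites on a root-child branch
#'   are genuinely ambiguous between that branch and its complement with
#'   flipped polarity (both fit the genotypes perfectly), as real panels
#'   are without an outgroup-determined ancestral state.
#' @return the path, invisibly.
#' @export
write_sim_vcf <- function(reference, path, include_aa = TRUE) {
  s <- reference$sites
  X <- reference$genotypes
  gt <- matrix(as.character(X), nrow(X), ncol(X))
  gt[is.na(gt)] <- "."
  info <- if (include_aa) paste0("AA=", reference$truth$ancestral) else "."
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", s$chrom[1L], ">"),
           if (include_aa)
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(X)), collapse = "\t"))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", ".", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Haplogroup-style labels and a marker table consistent with the tree
#'
#' Assigns every branch a nested long-form label (root children get
#' letters, deeper branches alternate numbers and letters, so descendants'
#' labels extend their ancestors'), then emits one curated marker per
#' branch-with-sites, taken from the branch's simulated sites.
#'
#' @param reference a \code{sim_reference}.
#' @return list: \code{labels} (named character vector, branch id ->
#'   label), \code{markers} (a marker table as read by
#'   \code{\link{load_markers}}).
#' @export
sim_markers <- function(reference) {
  tree <- reference$tree
  labels <- character(tree$n_node)
  for (nd in order_nodes_preorder(tree$root, tree$children, tree$n_node)) {
    ch <- tree$children[[nd]]
    for (k in seq_along(ch)) {
      tag <- if (tree$depth[ch[k]] %% 2L == 1L) LETTERS[k]
             else as.character(k)
      labels[ch[k]] <- paste0(labels[nd], tag)
    }
  }
  tr <- reference$truth
  first <- !duplicated(tr$branch)
  mk <- tr[first, , drop = FALSE]
  markers <- data.frame(
    name = paste0("M", mk$pos),
    haplogroup = labels[mk$branch],
    chrom = mk$chrom, pos = mk$pos,
    ancestral = mk$ancestral, derived = mk$derived,
    stringsAsFactors = FALSE)
  bids <- branch_ids(tree)
  list(labels = stats::setNames(labels[bids], bids), markers = markers)
}

#' Simulate a damaged low-coverage query pileup
#'
#' The query diverges from the attachment branch at
#' \code{attachment_fraction} from its parent end: it is derived at all
#' sites on strict ancestors of the branch and at the parent-side share of
#' the branch's own sites, ancestral elsewhere.  Reads are drawn
#' Poisson(coverage) per site; each read's base starts from the query
#' genotype, is flipped to a uniform other base with probability
#' \code{base_error}, and then damage is applied: at sites whose alleles
#' are \{C,T\} a read C becomes T with probability \code{deamination}, at
#' \{G,A\} sites a read G becomes A.
#'
#' @param config a \code{\link{sim_config}}.
#' @param reference the matching \code{\link{sim_reference}}.
#' @return list of class \code{"sim_query"}: \code{pileup} (sites table
#'   with derived allele and A/C/G/T counts), \code{truth} (attachment
#'   branch, per-site query genotype as derived/ancestral).
#' @export
sim_query <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"),
            inherits(reference, "sim_reference"))
  tree <- reference$tree
  set.seed((config$seed + 777L) %% 2147483647L)
  attach_branch <- if (identical(config$attachment, "random"))
    sample(branch_ids(tree), 1L) else check_branch(tree, config$attachment)

  tr <- reference$truth
  anc_set <- strict_ancestors(tree, attach_branch)
  derived_q <- tr$branch %in% anc_set
  ## parent-side share of the attachment branch's own mutations is shared
  on_e <- which(tr$branch == attach_branch)
  if (length(on_e)) {
    k <- round(config$attachment_fraction * length(on_e))
    if (k > 0) derived_q[on_e[seq_len(k)]] <- TRUE
  }
  geno_base <- ifelse(derived_q, tr$derived, tr$ancestral)

  n <- nrow(tr)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  depth <- stats::rpois(n, config$coverage)
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    b <- rep(geno_base[i], depth[i])
    if (config$base_error > 0) {
      err <- runif(depth[i]) < config$base_error
      if (any(err))
        b[err] <- vapply(b[err], function(x)
          sample(setdiff(BASES, x), 1L), "")
    }
    alleles <- sort(c(tr$ancestral[i], tr$derived[i]))
    if (config$deamination > 0) {
      if (identical(alleles, c("C", "T"))) {
        flip <- b == "C" & runif(depth[i]) < config$deamination
        b[flip] <- "T"
      } else if (identical(alleles, c("A", "G"))) {
        flip <- b == "G" & runif(depth[i]) < config$deamination
        b[flip] <- "A"
      }
    }
    tb <- table(factor(b, levels = BASES))
    counts[i, ] <- as.integer(tb)
  }
  pileup <- data.frame(
    chrom = tr$chrom, pos = tr$pos,
    ref = reference$sites$ref, alt = reference$sites$alt,
    derived = tr$derived,
    counts, raw_depth = depth,
    stringsAsFactors = FALSE)
  truth <- list(attachment = attach_branch,
                attachment_fraction = config$attachment_fraction,
                genotype = ifelse(derived_q, "derived", "ancestral"))
  structure(list(pileup = pileup, truth = truth, config = config),
            class = "sim_query")
}

#' Write a simulated query pileup as SAM text
#'
#' Emits one single-base read (CIGAR \code{1M}) per counted base, with
#' mapping quality 60 and base quality 40, so the BAM pileup path can be
#' integration-tested after conversion with \code{Rsamtools::asBam}.
#'
#' @param pileup pileup data frame from \code{\link{sim_query}}.
#' @param path output SAM path.
#' @param sample read-group/sample name.
#' @return the path, invisibly.
#' @export
write_query_sam <- function(pileup, path, sample = "query") {
  chrom <- pileup$chrom[1L]
  maxpos <- max(pileup$pos) + 100L
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", chrom, "\tLN:", maxpos),
             paste0("@RG\tID:", sample, "\tSM:", sample))
  k <- 0L
  for (i in seq_len(nrow(pileup))) {
    for (b in BASES) {
      cnt <- pileup[[b]][i]
      if (cnt == 0L) next
      for (r in seq_len(cnt)) {
        k <- k + 1L
        lines <- c(lines, paste(
          sprintf("read%06d", k), 0L, chrom, pileup$pos[i], 60L, "1M",
          "*", 0L, 0L, b, "I", paste0("RG:Z:", sample), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
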