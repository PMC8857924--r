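# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use only clade_leaves()/path_to_root() set
# arithmetic, never the scoring internals they check.

quartet_tree <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

find_branch <- function(tree, leaves) {
  for (b in branch_ids(tree))
    if (setequal(clade_leaves(tree, b), leaves)) return(b)
  stop("no branch with clade {", paste(leaves, collapse = ","), "}")
}

random_ref_tree <- function(n_tips) {
  phy <- ape::rtree(n_tips)
  phy$tip.label <- sprintf("t%02d", seq_len(n_tips))
  as_ref_tree(phy)
}

# min-mismatch search over every (branch, polarity): the ML assignment for
# epsilon < 0.5 must agree with this
oracle_assign <- function(genotypes, tree) {
  best <- NULL
  for (b in branch_ids(tree)) {
    inside <- names(genotypes) %in% clade_leaves(tree, b)
    for (derived_is_alt in c(TRUE, FALSE)) {
      expected <- ifelse(inside, if (derived_is_alt) 1 else 0,
                         if (derived_is_alt) 0 else 1)
      mism <- sum(genotypes != expected, na.rm = TRUE)
      cand <- list(branch = b, derived_is_alt = derived_is_alt,
                   mismatch = mism)
      if (is.null(best) || mism < best$mismatch) best <- cand
      else if (mism == best$mismatch) best$tied <- TRUE
    }
  }
  best
}

# exhaustive enumeration of every admissible root-to-tip path prefix,
# scored by cumulative support; mirrors the documented pruning and
# tie-break rules from first principles
oracle_best_path <- function(tree, tal, max_conflict = 3) {
  sup <- integer(tree$n_node); con <- integer(tree$n_node)
  if (nrow(tal)) { sup[tal$branch] <- tal$support; con[tal$branch] <- tal$conflict }
  prefixes <- list()
  for (lf in seq_len(tree$n_tip)) {
    path <- path_to_root(tree, lf)
    for (k in seq_along(path)) {
      pre <- path[seq_len(k)]
      if (any(con[pre] > max_conflict)) break   # stopped at first offender
      prefixes[[length(prefixes) + 1L]] <- pre
    }
  }
  if (length(prefixes) == 0L)
    return(list(placed = FALSE))
  score <- vapply(prefixes, function(p) sum(sup[p]), 0)
  if (max(score) == 0L) return(list(placed = FALSE))
  confl <- vapply(prefixes, function(p) sum(con[p]), 0)
  len <- lengths(prefixes)
  term <- vapply(prefixes, function(p) p[length(p)], 0L)
  ord <- order(-score, confl, len, term)
  top <- ord[1L]
  keep <- which(score == score[top] & confl == confl[top])
  # equivalent placements differ in their deepest support-bearing branch;
  # support-free extensions of the same prefix are the same placement
  trim_term <- vapply(prefixes[keep], function(p) {
    p[max(which(sup[p] > 0L))]
  }, 0L)
  list(placed = TRUE, branch = term[top], support = score[top],
       conflict = confl[top],
       tie = length(unique(trim_term)) > 1L)
}

write_mini_vcf <- function(path, records, samples,
                           info = rep(".", length(records))) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrY>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# one-row pileup helper for filter tests
pileup_row <- function(ref, alt, derived, counts) {
  row <- data.frame(chrom = "chrY", pos = 100L, ref = ref, alt = alt,
                    derived = derived, A = 0L, C = 0L, G = 0L, T = 0L,
                    stringsAsFactors = FALSE)
  for (b in names(counts)) row[[b]] <- as.integer(counts[[b]])
  row
}

# run the full simulated pipeline for one seed and return placement results
run_sim_pipeline <- function(cfg, filter_mode = "default",
                             epsilon_place = 0.01, max_conflict = 3) {
  ref <- sim_reference(cfg)
  vcf <- tempfile(fileext = ".vcf")
  on.exit(unlink(vcf))
  write_sim_vcf(ref, vcf)
  ba <- assign_all(vcf, ref$tree)
  qry <- sim_query(cfg, ref)
  pil <- qry$pileup
  pil$derived <- ba$assignments$derived   # inferred, as the pipeline uses
  keep <- ba$assignments$status == "assigned"
  calls <- filter_calls(pil[keep, , drop = FALSE], filter_mode)
  tal <- tally(calls, ba$assignments)
  list(tree = ref$tree, assignments = ba, tally = tal,
       best_path = best_path(ref$tree, tal, max_conflict = max_conflict),
       posterior = likelihood_place(ref$tree, tal, epsilon = epsilon_place),
       truth = qry$truth, reference = ref, query = qry)
}

# acceptance-scale simulation settings: enough SNPs per branch that every
# path branch is informative at the simulated coverage
accept_cfg <- function(seed, n_leaves, base_error = 0, deamination = 0,
                       coverage = 3) {
  b <- 2L * n_leaves - 2L   # branch count of a bifurcating rooted tree
  sim_config(n_leaves = n_leaves, n_sites = 10L * b,
             min_sites_per_branch = 8, coverage = coverage,
             base_error = base_error, deamination = deamination,
             seed = seed)
}
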