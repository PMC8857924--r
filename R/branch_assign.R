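## SNP-to-branch assignment --------------------------------------------------
##
## Each biallelic site is scored on every branch of the reference tree under
## a symmetric genotype-error model: conditional on the mutation having
## occurred on branch b with derived allele d, every leaf inside clade(b) is
## expected to carry d and every leaf outside the ancestral allele; an
## observed genotype matches that expectation with probability 1 - epsilon
## and mismatches with probability epsilon.  Missing genotypes are
## marginalized out (contribute 0 to the log-likelihood).  For epsilon < 0.5
## the maximum-likelihood (branch, polarity) pair is exactly the
## minimum-mismatch pair, which is what the brute-force oracle in the test
## suite exploits.

log_eps <- function(epsilon) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon >= 0.5)
    stop("`epsilon` must lie in (0, 0.5)")
  c(match = log1p(-epsilon), mismatch = log(epsilon))
}

## default exclusion margin: a site is kept only if its best branch implies
## no more than `max_mismatch` flipped genotypes (default 3)
default_margin <- function(epsilon, max_mismatch = 3) {
  le <- log_eps(epsilon)
  (max_mismatch + 0.5) * (le[["match"]] - le[["mismatch"]])
}

#' Log-likelihood of one SNP arising on one branch
#'
#' @param genotypes named vector over tree leaves with values 0 (REF),
#'   1 (ALT) or NA (missing).
#' @param tree a \code{ref_tree}.
#' @param branch candidate branch id.
#' @param derived_is_alt logical; if \code{TRUE} the ALT allele is taken as
#'   the derived state carried by the clade below \code{branch}.
#' @param epsilon genotype error probability, in (0, 0.5).
#' @return log-likelihood in nats.
#' @export
score_snp_on_branch <- function(genotypes, tree, branch, derived_is_alt,
                                epsilon = 0.001) {
  branch <- check_branch(tree, branch)
  le <- log_eps(epsilon)
  x <- genotype_vector(genotypes, tree)
  inside <- tree$clade[branch, ]
  expected <- ifelse(inside, if (derived_is_alt) 1 else 0,
                     if (derived_is_alt) 0 else 1)
  ok <- !is.na(x)
  n_match <- sum(x[ok] == expected[ok])
  n_mism <- sum(ok) - n_match
  n_match * le[["match"]] + n_mism * le[["mismatch"]]
}

## named genotype vector -> vector aligned to tree$leaf_names
genotype_vector <- function(genotypes, tree) {
  if (is.null(names(genotypes)))
    stop("`genotypes` must be named by tree leaf")
  unknown <- setdiff(names(genotypes), tree$leaf_names)
  if (length(unknown))
    stop("genotype(s) for leaves not in tree: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  x <- rep(NA_real_, tree$n_tip)
  x[match(names(genotypes), tree$leaf_names)] <- as.numeric(genotypes)
  bad <- !is.na(x) & !(x %in% c(0, 1))
  if (any(bad)) stop("genotypes must be 0, 1 or NA")
  x
}

## Core scorer: X is a sites x tips matrix in tree leaf order (0/1/NA).
## Returns, per site, the argmax over branches x polarities plus the
## mismatch count it implies.  `force_derived_alt` (NA / TRUE / FALSE)
## restricts the polarity per site (ancestral-allele override).
score_sites_matrix <- function(X, tree, epsilon, force_derived_alt = NULL) {
  le <- log_eps(epsilon)
  bids <- branch_ids(tree)
  M <- tree$clade[bids, , drop = FALSE]
  storage.mode(M) <- "double"
  V1 <- (X == 1); V1[is.na(V1)] <- FALSE; storage.mode(V1) <- "double"
  V0 <- (X == 0); V0[is.na(V0)] <- FALSE; storage.mode(V0) <- "double"
  tM <- t(M); tC <- t(1 - M)
  mism_alt <- V0 %*% tM + V1 %*% tC     # derived = ALT
  mism_ref <- V1 %*% tM + V0 %*% tC     # derived = REF
  n_obs <- rowSums(V1) + rowSums(V0)
  if (!is.null(force_derived_alt)) {
    big <- n_obs + 1
    mism_alt[which(force_derived_alt %in% FALSE), ] <- big[
      which(force_derived_alt %in% FALSE)]
    mism_ref[which(force_derived_alt %in% TRUE), ] <- big[
      which(force_derived_alt %in% TRUE)]
  }
  best_alt <- apply(mism_alt, 1L, which.min)
  best_ref <- apply(mism_ref, 1L, which.min)
  m_alt <- mism_alt[cbind(seq_len(nrow(X)), best_alt)]
  m_ref <- mism_ref[cbind(seq_len(nrow(X)), best_ref)]
  use_alt <- m_alt <= m_ref            # ties favour derived = ALT
  mism <- ifelse(use_alt, m_alt, m_ref)
  data.frame(
    branch = bids[ifelse(use_alt, best_alt, best_ref)],
    derived_is_alt = use_alt,
    n_obs = n_obs,
    n_mismatch = mism,
    loglik = (n_obs - mism) * le[["match"]] + mism * le[["mismatch"]]
  )
}

#' Assign one biallelic SNP to its most likely branch
#'
#' Scores every (branch, polarity) hypothesis and returns the maximum
#' likelihood one.  Sites whose non-missing genotypes are all identical are
#' excluded as monomorphic; sites whose best branch still implies more
#' mismatching genotypes than the margin allows are excluded as
#' low-likelihood (repeated mutation or repeated genotype error).
#'
#' @inheritParams score_snp_on_branch
#' @param loglik_margin exclusion threshold in nats: exclude when the best
#'   log-likelihood falls more than this below the perfect-fit value for the
#'   same number of observed genotypes.  Default corresponds to tolerating
#'   at most 3 implied mismatching genotypes at the given \code{epsilon}.
#' @param force_derived_alt optional logical: force the derived allele to
#'   ALT (\code{TRUE}) or REF (\code{FALSE}), e.g. from an ancestral-allele
#'   annotation; \code{NA} (default) infers polarity by scoring both.
#' @return a one-row data frame with columns \code{branch},
#'   \code{derived_is_alt}, \code{loglik}, \code{n_mismatch}, \code{status}.
#' @export
assign_snp <- function(genotypes, tree, epsilon = 0.001,
                       loglik_margin = NULL, force_derived_alt = NA) {
  if (is.null(loglik_margin)) loglik_margin <- default_margin(epsilon)
  x <- genotype_vector(genotypes, tree)
  obs <- x[!is.na(x)]
  if (length(obs) == 0L)
    stop("site has no non-missing genotypes")
  if (length(unique(obs)) == 1L)
    return(data.frame(branch = NA_integer_, derived_is_alt = NA,
                      loglik = NA_real_, n_mismatch = NA_real_,
                      status = "excluded_monomorphic"))
  sc <- score_sites_matrix(matrix(x, nrow = 1L), tree, epsilon,
                           force_derived_alt = force_derived_alt)
  le <- log_eps(epsilon)
  perfect <- sc$n_obs * le[["match"]]
  status <- if (sc$loglik < perfect - loglik_margin)
    "excluded_low_likelihood" else "assigned"
  data.frame(branch = if (status == "assigned") sc$branch else NA_integer_,
             derived_is_alt = if (status == "assigned") sc$derived_is_alt
               else NA,
             loglik = sc$loglik, n_mismatch = sc$n_mismatch, status = status)
}

#' Assign all sites of a reference VCF to branches
#'
#' Reads a VCF of reference genotypes (haploid, or haploid-coded diploid:
#' heterozygous calls are set to missing with a counted warning), keeps
#' biallelic SNVs, scores each on every branch x polarity, and reports
#' per-status counts.  Records with more than one ALT allele, or with
#' symbolic/indel alleles, are excluded as multiallelic without scoring.
#' An \code{AA=} (ancestral allele) INFO annotation, when present and equal
#' to REF or ALT, fixes the site's polarity instead of inferring it.
#'
#' @param vcf path to a VCF (plain or bgzipped) or a \code{vcfR} object.
#' @param tree a \code{ref_tree}; VCF samples are matched to leaves by exact
#'   name (see \code{\link{check_samples}}).
#' @inheritParams assign_snp
#' @return a list of class \code{"branch_assignment"}: \code{assignments}
#'   (one row per VCF site: chrom, pos, ref, alt, derived, branch, loglik,
#'   n_mismatch, status) and \code{report} (counts per status, total sites,
#'   fraction assigned).
#' @export
assign_all <- function(vcf, tree, epsilon = 0.001, loglik_margin = NULL) {
  if (is.null(loglik_margin)) loglik_margin <- default_margin(epsilon)
  if (is.character(vcf)) {
    if (!file.exists(vcf)) stop("cannot read VCF: ", vcf)
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  n_sites <- nrow(fix)
  if (n_sites == 0L) stop("VCF contains no records")
  gt_raw <- vcf@gt[, -1L, drop = FALSE]
  samples <- colnames(gt_raw)
  check_samples(tree, samples)

  parsed <- parse_gt_matrix(gt_raw)
  X <- matrix(NA_real_, n_sites, tree$n_tip)
  keep <- samples %in% tree$leaf_names
  X[, match(samples[keep], tree$leaf_names)] <- parsed$X[, keep, drop = FALSE]
  if (parsed$n_het > 0L)
    warning(parsed$n_het, " heterozygous genotype call(s) set to missing",
            call. = FALSE)

  bases <- c("A", "C", "G", "T")
  biallelic <- fix$REF %in% bases & fix$ALT %in% bases & fix$REF != fix$ALT
  info <- if ("INFO" %in% names(fix)) fix$INFO else rep(NA_character_, n_sites)
  aa <- sub(".*(?:^|;)AA=([ACGTacgt]).*", "\\1", info, perl = TRUE)
  aa <- ifelse(grepl("(^|;)AA=", info %||% ""), toupper(aa), NA_character_)
  force_alt <- rep(NA, n_sites)
  force_alt[!is.na(aa) & aa == fix$REF] <- TRUE    # ancestral = REF
  force_alt[!is.na(aa) & aa == fix$ALT] <- FALSE   # ancestral = ALT

  status <- rep(NA_character_, n_sites)
  branch <- rep(NA_integer_, n_sites)
  derived_is_alt <- rep(NA, n_sites)
  loglik <- rep(NA_real_, n_sites)
  n_mism <- rep(NA_real_, n_sites)

  status[!biallelic] <- "excluded_multiallelic"
  n_distinct <- apply(X, 1L, function(r) length(unique(r[!is.na(r)])))
  mono <- biallelic & n_distinct < 2L
  status[mono] <- "excluded_monomorphic"

  todo <- which(is.na(status))
  if (length(todo)) {
    sc <- score_sites_matrix(X[todo, , drop = FALSE], tree, epsilon,
                             force_derived_alt = force_alt[todo])
    le <- log_eps(epsilon)
    perfect <- sc$n_obs * le[["match"]]
    ok <- sc$loglik >= perfect - loglik_margin
    status[todo] <- ifelse(ok, "assigned", "excluded_low_likelihood")
    branch[todo[ok]] <- sc$branch[ok]
    derived_is_alt[todo[ok]] <- sc$derived_is_alt[ok]
    loglik[todo] <- sc$loglik
    n_mism[todo] <- sc$n_mismatch
  }

  assignments <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    derived = ifelse(is.na(derived_is_alt), NA_character_,
                     ifelse(derived_is_alt, fix$ALT, fix$REF)),
    branch = branch, loglik = loglik, n_mismatch = n_mism,
    status = status, stringsAsFactors = FALSE
  )
  lv <- c("assigned", "excluded_multiallelic", "excluded_monomorphic",
          "excluded_low_likelihood")
  counts <- table(factor(status, levels = lv))
  report <- list(counts = as.list(as.integer(counts)) |>
                   stats::setNames(lv),
                 total = n_sites,
                 fraction_assigned = unname(counts["assigned"]) / n_sites)
  structure(list(assignments = assignments, report = report),
            class = "branch_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## GT strings -> numeric matrix; haploid "0"/"1", homozygous diploid
## "0/0" etc.; heterozygous -> NA (counted); anything else -> NA
parse_gt_matrix <- function(gt_raw) {
  g <- sub(":.*", "", gt_raw)
  g <- gsub("|", "/", g, fixed = TRUE)
  X <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  X[g %in% c("0", "0/0")] <- 0
  X[g %in% c("1", "1/1")] <- 1
  n_het <- sum(g %in% c("0/1", "1/0"))
  list(X = X, n_het = n_het)
}

#' @export
print.branch_assignment <- function(x, ...) {
  r <- x$report
  cat("Branch assignment of", r$total, "sites:\n")
  for (s in names(r$counts))
    cat(sprintf("  %-26s %d\n", s, r$counts[[s]]))
  cat(sprintf("  fraction assigned: %.4f\n", r$fraction_assigned))
  invisible(x)
}

#' Write assigned sites as a TSV and a BED of targets
#'
#' The TSV holds every record (including excluded ones, with their status);
#' the BED holds only assigned sites as 0-based half-open single-base
#' intervals for pileup targeting.  Reading the TSV back with
#' \code{\link{read_branch_sites}} reproduces the assignments exactly.
#'
#' @param assignments a \code{branch_assignment} or its \code{assignments}
#'   data frame.
#' @param tsv,bed output paths (\code{bed = NULL} skips the BED).
#' @param labels optional map branch id -> haplogroup label (named character
#'   vector) added as a \code{haplogroup} column.
#' @return (invisibly) the TSV path.
#' @export
write_branch_sites <- function(assignments, tsv, bed = NULL, labels = NULL) {
  a <- if (inherits(assignments, "branch_assignment"))
    assignments$assignments else assignments
  out <- a
  out$loglik <- ifelse(is.na(a$loglik), "NA", sprintf("%.17g", a$loglik))
  out$haplogroup <- if (!is.null(labels))
    ifelse(is.na(a$branch), NA_character_,
           unname(labels[as.character(a$branch)])) else NA_character_
  utils::write.table(out, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(bed)) {
    keep <- a$status == "assigned"
    bed_df <- data.frame(chrom = a$chrom[keep], start = a$pos[keep] - 1L,
                         end = a$pos[keep])
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv)
}

#' Read a branch-sites TSV written by \code{write_branch_sites}
#'
#' @param tsv path.
#' @return the assignments data frame.
#' @export
read_branch_sites <- function(tsv) {
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                          colClasses = c(loglik = "character"))
  df$loglik <- as.numeric(df$loglik)
  df$pos <- as.integer(df$pos)
  df$branch <- as.integer(df$branch)
  if ("n_mismatch" %in% names(df)) df$n_mismatch <- as.numeric(df$n_mismatch)
  df
}
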