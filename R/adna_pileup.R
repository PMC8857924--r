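## Query base-call collection and aDNA-aware filtering ----------------------
##
## Ancient-DNA reads carry post-mortem deamination: apparent C->T (and, on
## the other strand, G->A) substitutions.  At transition sites these are
## indistinguishable from true derived/ancestral alleles, so base calls are
## filtered before genotyping: mismatching bases are dropped, singleton
## damage-candidate bases can be dropped ("default" mode), or transition
## sites skipped entirely ("transversions" mode), and a consensus fraction
## decides call vs missing.

#' Collect base counts from a BAM at informative sites
#'
#' Counts A/C/G/T bases from reads passing the base- and mapping-quality
#' thresholds at each site; sites with no passing reads are kept with zero
#' counts.  The BAM must be indexed and its contig names must include the
#' site chromosomes.
#'
#' @param bam path to an indexed BAM.
#' @param sites data frame with at least \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}; a \code{derived} column, when present, is
#'   carried through.
#' @param min_bq minimum base quality (phred), default 20.
#' @param min_mq minimum mapping quality (phred), default 25.
#' @return data frame: one row per site with columns \code{A,C,G,T} (counts
#'   after the quality gates) and \code{raw_depth} (reads before them).
#' @export
pileup_at_sites <- function(bam, sites, min_bq = 20, min_mq = 25) {
  if (!file.exists(bam)) stop("BAM not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam,
         "; index it first (e.g. samtools index)")
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_chr <- setdiff(unique(sites$chrom), names(hdr))
  if (length(missing_chr))
    stop("site chromosome(s) absent from BAM header: ",
         paste(missing_chr, collapse = ", "),
         " (BAM has: ", paste(names(hdr), collapse = ", "), ")")

  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  run_pileup <- function(bq, mq) {
    Rsamtools::pileup(
      bam,
      scanBamParam = Rsamtools::ScanBamParam(which = gr),
      pileupParam = Rsamtools::PileupParam(
        max_depth = 100000L, min_base_quality = as.integer(bq),
        min_mapq = as.integer(mq), min_nucleotide_depth = 1L,
        distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
        include_deletions = FALSE, include_insertions = FALSE))
  }
  p <- run_pileup(min_bq, min_mq)
  raw <- run_pileup(0L, 0L)

  out <- sites
  for (b in c("A", "C", "G", "T")) out[[b]] <- 0L
  out$raw_depth <- 0L
  key <- paste(sites$chrom, sites$pos)
  if (nrow(p)) {
    pk <- paste(p$seqnames, p$pos)
    for (i in seq_len(nrow(p))) {
      j <- match(pk[i], key)
      nb <- as.character(p$nucleotide[i])
      if (!is.na(j) && nb %in% c("A", "C", "G", "T"))
        out[[nb]][j] <- out[[nb]][j] + p$count[i]
    }
  }
  if (nrow(raw)) {
    agg <- tapply(raw$count, paste(raw$seqnames, raw$pos), sum)
    j <- match(names(agg), key)
    ok <- !is.na(j)
    out$raw_depth[j[ok]] <- as.integer(agg[ok])
  }
  out
}

#' Convert site pileups to ancestral/derived/missing calls
#'
#' Applies, per site: (1) drop bases matching neither REF nor ALT;
#' (2) mode-specific deamination handling -- \code{"no-filter"} keeps all
#' remaining calls, \code{"default"} removes a singleton T at C/T sites and
#' a singleton A at G/A sites, \code{"transversions"} sets every C/T and
#' G/A site to missing; (3) call the most frequent remaining base iff it
#' makes up at least \code{consensus_fraction} of the remaining calls
#' (ties and empty sets give missing).  "Singleton" means an exact count of
#' one after step 1, regardless of total depth.
#'
#' @param pileup data frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{derived} and base counts \code{A,C,G,T}
#'   (as from \code{\link{pileup_at_sites}} joined with the sites table).
#' @param mode one of \code{"default"}, \code{"no-filter"},
#'   \code{"transversions"}.
#' @param consensus_fraction consensus threshold in (0.5, 1], default 0.7;
#'   a top-base fraction exactly at the threshold passes.
#' @return data frame of calls: \code{state} in
#'   \{\code{ancestral}, \code{derived}, \code{missing}\}, the supporting
#'   \code{base}, its \code{fraction} of retained calls, counts kept and
#'   dropped, and the mode used.
#' @export
filter_calls <- function(pileup, mode = c("default", "no-filter",
                                          "transversions"),
                         consensus_fraction = 0.7) {
  mode <- match.arg(mode)
  if (!is.numeric(consensus_fraction) || consensus_fraction <= 0.5 ||
      consensus_fraction > 1)
    stop("`consensus_fraction` must lie in (0.5, 1]")
  if (!all(c("ref", "alt", "derived") %in% names(pileup)))
    stop("`pileup` needs ref, alt and derived columns")
  n <- nrow(pileup)
  state <- rep("missing", n)
  base <- rep(NA_character_, n)
  frac <- rep(NA_real_, n)
  n_kept <- integer(n)
  n_dropped <- integer(n)
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileup[, bases])
  for (i in seq_len(n)) {
    ref <- pileup$ref[i]; alt <- pileup$alt[i]
    total <- sum(cnt[i, ])
    keep <- stats::setNames(c(cnt[i, ref], cnt[i, alt]), c(ref, alt))
    n_dropped[i] <- total - sum(keep)
    alleles <- sort(c(ref, alt))
    is_ct <- identical(alleles, c("C", "T"))
    is_ga <- identical(alleles, c("A", "G"))
    if (mode == "transversions" && (is_ct || is_ga)) {
      n_kept[i] <- 0L
      n_dropped[i] <- total
      next
    }
    if (mode == "default") {
      if (is_ct && keep[["T"]] == 1L) {
        keep[["T"]] <- 0L; n_dropped[i] <- n_dropped[i] + 1L
      }
      if (is_ga && keep[["A"]] == 1L) {
        keep[["A"]] <- 0L; n_dropped[i] <- n_dropped[i] + 1L
      }
    }
    n_kept[i] <- sum(keep)
    if (n_kept[i] == 0L) next
    f <- max(keep) / n_kept[i]
    ## a 50/50 tie can never reach the threshold since it exceeds 0.5
    if (f < consensus_fraction) next
    top <- names(keep)[which.max(keep)]
    base[i] <- top
    frac[i] <- f
    state[i] <- if (top == pileup$derived[i]) "derived" else "ancestral"
  }
  data.frame(chrom = pileup$chrom, pos = pileup$pos,
             ref = pileup$ref, alt = pileup$alt,
             derived = pileup$derived,
             state = state, base = base, fraction = frac,
             n_kept = n_kept, n_dropped = n_dropped,
             filter_mode = mode, stringsAsFactors = FALSE)
}

#' Derive site calls from a pre-called query VCF
#'
#' Maps genotypes called by external software at the informative sites to
#' ancestral/derived states via each site's derived allele.  Sites absent
#' from the VCF are missing; records whose alleles match the sites table
#' with REF and ALT swapped are normalized by allele matching; records whose
#' alleles match neither way are dropped with a counted warning.
#'
#' @param query_vcf path to a VCF or a \code{vcfR} object with the query
#'   sample.
#' @param sites assigned-sites data frame (chrom, pos, ref, alt, derived).
#' @param sample sample name to use; default the VCF's single (first)
#'   sample.
#' @return calls data frame in the same shape as \code{\link{filter_calls}}.
#' @export
calls_from_vcf <- function(query_vcf, sites, sample = NULL) {
  if (is.character(query_vcf)) {
    if (!file.exists(query_vcf)) stop("cannot read VCF: ", query_vcf)
    query_vcf <- vcfR::read.vcfR(query_vcf, verbose = FALSE)
  }
  fix <- as.data.frame(vcfR::getFIX(query_vcf), stringsAsFactors = FALSE)
  gt_all <- query_vcf@gt[, -1L, drop = FALSE]
  if (is.null(sample)) sample <- colnames(gt_all)[1L]
  if (!(sample %in% colnames(gt_all)))
    stop("sample not present in query VCF: ", sample)
  g <- parse_gt_matrix(gt_all[, sample, drop = FALSE])$X[, 1L]

  n <- nrow(sites)
  state <- rep("missing", n)
  base <- rep(NA_character_, n)
  n_mismatched_alleles <- 0L
  vkey <- paste(fix$CHROM, fix$POS)
  skey <- paste(sites$chrom, sites$pos)
  hit <- match(skey, vkey)
  for (i in which(!is.na(hit))) {
    j <- hit[i]
    if (is.na(g[j])) next
    vr <- fix$REF[j]; va <- fix$ALT[j]
    if (vr == sites$ref[i] && va == sites$alt[i]) {
      allele <- if (g[j] == 1) va else vr
    } else if (vr == sites$alt[i] && (is.na(va) || va == sites$ref[i])) {
      allele <- if (g[j] == 1) va else vr        # swapped orientation
    } else {
      n_mismatched_alleles <- n_mismatched_alleles + 1L
      next
    }
    if (!(allele %in% c(sites$ref[i], sites$alt[i]))) {
      n_mismatched_alleles <- n_mismatched_alleles + 1L
      next
    }
    base[i] <- allele
    state[i] <- if (allele == sites$derived[i]) "derived" else "ancestral"
  }
  if (n_mismatched_alleles > 0L)
    warning(n_mismatched_alleles,
            " query VCF record(s) with alleles matching neither REF/ALT ",
            "orientation dropped", call. = FALSE)
  data.frame(chrom = sites$chrom, pos = sites$pos,
             ref = sites$ref, alt = sites$alt, derived = sites$derived,
             state = state, base = base,
             fraction = ifelse(state == "missing", NA_real_, 1),
             n_kept = ifelse(state == "missing", 0L, 1L),
             n_dropped = 0L, filter_mode = "vcf",
             stringsAsFactors = FALSE)
}
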