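test_that("branch score equals the stated genotype-error sum", {
  tr <- quartet_tree()
  b_ab <- find_branch(tr, c("A", "B"))
  b_cd <- find_branch(tr, c("C", "D"))
  g <- c(A = 1, B = 1, C = 0, D = 0)
  expect_equal(score_snp_on_branch(g, tr, b_ab, TRUE, 0.001),
               4 * log(0.999))
  expect_equal(score_snp_on_branch(g, tr, b_cd, TRUE, 0.001),
               4 * log(0.001))
  # missing genotypes are marginalized out
  g_na <- c(A = NA, B = NA, C = NA, D = NA)
  for (b in branch_ids(tr))
    expect_equal(score_snp_on_branch(g_na, tr, b, TRUE, 0.001), 0)
  expect_error(score_snp_on_branch(c(A = 1, Z = 0), tr, b_ab, TRUE),
               "not in tree")
  expect_error(score_snp_on_branch(g, tr, b_ab, TRUE, epsilon = 0.7),
               "epsilon")
})

test_that("assign_snp returns the ML branch and applies exclusions", {
  tr <- quartet_tree()
  res <- assign_snp(c(A = 1, B = 1, C = 0, D = 0), tr)
  expect_equal(res$status, "assigned")
  expect_equal(res$branch, find_branch(tr, c("A", "B")))
  expect_true(res$derived_is_alt)

  # homoplasy: best hypothesis still implies 1 mismatch; margin of 5 nats
  # at eps = 0.001 tolerates none
  hom <- assign_snp(c(A = 1, B = 0, C = 1, D = 0), tr, 0.001,
                    loglik_margin = 5)
  expect_equal(hom$status, "excluded_low_likelihood")
  expect_equal(hom$n_mismatch, 1)
  expect_equal(hom$loglik, 3 * log(0.999) + log(0.001))

  expect_equal(assign_snp(c(A = 1, B = 1, C = 1, D = 1), tr)$status,
               "excluded_monomorphic")
  expect_error(assign_snp(c(A = NA, B = NA, C = NA, D = NA), tr),
               "no non-missing")
})

test_that("default margin tolerates up to 3 implied mismatches", {
  # caterpillar with scattered homoplasic carriers: no alternative branch
  # can explain fewer than k mismatches
  tr <- read_newick("(((((((((((A,B),C),D),E),F),G),H),I),J),K),L);")
  g0 <- stats::setNames(rep(0, 12), tr$leaf_names)
  g0[c("A", "B")] <- 1
  scatter <- c("D", "F", "H", "J")
  for (k in 0:4) {
    gg <- g0
    gg[scatter[seq_len(k)]] <- 1
    res <- assign_snp(gg, tr)
    expect_equal(res$n_mismatch, k)
    expect_equal(res$status,
                 if (k <= 3) "assigned" else "excluded_low_likelihood",
                 info = paste("k =", k))
  }
})

test_that("ML assignment agrees with brute-force min-mismatch oracle", {
  set.seed(101)
  for (rep in 1:40) {
    tr <- random_ref_tree(sample(4:16, 1L))
    g <- sample(c(0, 1, NA), tr$n_tip, replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
    names(g) <- tr$leaf_names
    obs <- g[!is.na(g)]
    if (length(obs) == 0L || length(unique(obs)) < 2L) next
    mine <- assign_snp(g, tr, loglik_margin = Inf)
    oracle <- oracle_assign(g, tr)
    expect_equal(mine$n_mismatch, oracle$mismatch)
    if (is.null(oracle$tied)) {
      expect_equal(mine$branch, oracle$branch)
      expect_equal(mine$derived_is_alt, oracle$derived_is_alt)
    }
  }
})

test_that("flipping all genotypes maps to clade or complement by symmetry", {
  set.seed(19)
  for (rep in 1:15) {
    tr <- random_ref_tree(8)
    g <- sample(c(0, 1), tr$n_tip, replace = TRUE)
    if (length(unique(g)) < 2L) next
    names(g) <- tr$leaf_names
    gf <- stats::setNames(1 - g, names(g))
    a <- assign_snp(g, tr, loglik_margin = Inf)
    b <- assign_snp(gf, tr, loglik_margin = Inf)
    expect_equal(a$n_mismatch, b$n_mismatch)  # same fit quality either way
    if (!is.null(oracle_assign(g, tr)$tied)) next  # tie-breaks may differ
    clade_a <- clade_leaves(tr, a$branch)
    clade_b <- clade_leaves(tr, b$branch)
    # same hypothesis expressed on the clade or its complement
    expect_true(setequal(clade_a, clade_b) ||
                  setequal(union(clade_a, clade_b), tr$leaf_names))
  }
})

test_that("adding a mismatching genotype never increases the best loglik", {
  set.seed(23)
  tr <- random_ref_tree(10)
  b <- branch_ids(tr)[4L]
  g <- ifelse(tr$leaf_names %in% clade_leaves(tr, b), 1, 0)
  names(g) <- tr$leaf_names
  prev <- assign_snp(g, tr, loglik_margin = Inf)$loglik
  outside <- which(!(tr$leaf_names %in% clade_leaves(tr, b)))
  for (k in outside[1:3]) {
    g[k] <- 1
    cur <- assign_snp(g, tr, loglik_margin = Inf)$loglik
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
})

test_that("assign_all classifies VCF records and tallies a report", {
  tr <- quartet_tree()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "chrY\t100\t.\tG\tA\t.\t.\t.\tGT\t1\t1\t0\t0",   # clean clade SNP
    "chrY\t200\t.\tG\tA,T\t.\t.\t.\tGT\t1\t0\t0\t0", # triallelic
    "chrY\t300\t.\tC\tT\t.\t.\t.\tGT\t1\t1\t1\t1"    # monomorphic
  ), samples = c("A", "B", "C", "D"))
  ba <- assign_all(vcf, tr)
  expect_equal(ba$report$counts$assigned, 1L)
  expect_equal(ba$report$counts$excluded_multiallelic, 1L)
  expect_equal(ba$report$counts$excluded_monomorphic, 1L)
  expect_equal(ba$report$total, 3L)
  expect_equal(ba$assignments$branch[1L], find_branch(tr, c("A", "B")))
  expect_equal(ba$assignments$derived[1L], "A")
})

test_that("heterozygous diploid calls become missing with a warning", {
  tr <- quartet_tree()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "chrY\t100\t.\tG\tA\t.\t.\t.\tGT\t1/1\t0/1\t0/0\t0/0"
  ), samples = c("A", "B", "C", "D"))
  expect_warning(ba <- assign_all(vcf, tr), "heterozygous")
  expect_equal(ba$assignments$status, "assigned")
  expect_equal(clade_leaves(tr, ba$assignments$branch), "A")
})

test_that("an AA INFO annotation overrides polarity inference", {
  tr <- quartet_tree()
  # carriers {C,D}; without AA the derived allele is ambiguous between the
  # two root children; AA=A forces derived = G on the {C,D} branch
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "chrY\t100\t.\tA\tG\t.\t.\tAA=A\tGT\t0\t0\t1\t1"
  ), samples = c("A", "B", "C", "D"))
  ba <- assign_all(vcf, tr)
  expect_equal(ba$assignments$derived, "G")
  expect_equal(ba$assignments$branch, find_branch(tr, c("C", "D")))
})

test_that("sites tables round-trip losslessly and BED uses 0-based spans", {
  tr <- quartet_tree()
  vcf <- write_mini_vcf(tempfile(fileext = ".vcf"), c(
    "chrY\t100\t.\tG\tA\t.\t.\t.\tGT\t1\t1\t0\t0",
    "chrY\t200\t.\tG\tA,T\t.\t.\t.\tGT\t1\t0\t0\t0"
  ), samples = c("A", "B", "C", "D"))
  ba <- assign_all(vcf, tr)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_branch_sites(ba, tsv, bed = bed)
  back <- read_branch_sites(tsv)
  expect_identical(back$loglik, ba$assignments$loglik)
  expect_identical(back[names(ba$assignments)], ba$assignments)
  bed_lines <- readLines(bed)
  expect_equal(bed_lines, "chrY\t99\t100")  # excluded site absent
})
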