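make_tally <- function(branches, support, conflict) {
  data.frame(branch = as.integer(branches), support = as.integer(support),
             conflict = as.integer(conflict))
}

test_that("tally bins derived/ancestral calls onto assigned branches", {
  tr <- quartet_tree()
  b <- find_branch(tr, c("A", "B"))
  assignments <- data.frame(
    chrom = "chrY", pos = c(100L, 200L, 300L, 400L),
    ref = "G", alt = "A", derived = "A",
    branch = c(b, b, b, NA), loglik = 0,
    status = c(rep("assigned", 3), "excluded_multiallelic"))
  calls <- data.frame(chrom = "chrY", pos = c(100L, 200L, 300L, 400L),
                      state = c("derived", "derived", "ancestral",
                                "derived"))
  tal <- tally(calls, assignments)
  expect_equal(tal$support[tal$branch == b], 2L)
  expect_equal(tal$conflict[tal$branch == b], 1L)
  expect_equal(attr(tal, "n_ignored"), 1L)   # call at the excluded site

  empty <- tally(data.frame(chrom = character(0), pos = integer(0),
                            state = character(0)), assignments)
  expect_equal(nrow(empty), 0L)
})

test_that("best path prunes at conflicts and renders the annotation", {
  tr <- quartet_tree()
  b_ab <- find_branch(tr, c("A", "B"))
  b_a <- find_branch(tr, "A")
  # conflicts on the leaf branch stop the path above it
  res <- best_path(tr, make_tally(c(b_ab, b_a), c(5, 0), c(0, 4)),
                   max_conflict = 3)
  expect_equal(res$branch, b_ab)
  expect_equal(res$annotation, "[0-0; 5-0]")
  expect_equal(res$pruned_paths, 1L)

  # deep support path: 55 above, 1 on branch, no conflict
  cat_tree <- read_newick("(((((A,B),C),D),E),F);")
  path <- path_to_root(cat_tree, find_branch(cat_tree, "A"))
  sup <- c(rep(0L, 0), 14L, 14L, 14L, 13L, 1L)  # 55 above the leaf branch
  res2 <- best_path(cat_tree, make_tally(path, sup, rep(0L, 5)))
  expect_equal(res2$branch, find_branch(cat_tree, "A"))
  expect_equal(res2$annotation, "[55-0; 1-0]")
  expect_equal(res2$support_above + res2$support_on, 56L)

  # symmetric support on the two root children: tie flagged
  res3 <- best_path(tr, make_tally(c(b_ab, find_branch(tr, c("C", "D"))),
                                   c(3, 3), c(0, 0)))
  expect_true(res3$tie)

  # empty tally: unplaced
  res4 <- best_path(tr, make_tally(integer(0), integer(0), integer(0)))
  expect_false(res4$placed)
  expect_equal(res4$annotation, "[0-0; 0-0]")
  expect_true(res4$tie)
})

test_that("insertion fraction follows on-branch support/conflict", {
  tr <- quartet_tree()
  b_a <- find_branch(tr, "A")
  b_ab <- find_branch(tr, c("A", "B"))
  res <- best_path(tr, make_tally(c(b_ab, b_a), c(4, 3), c(0, 1)))
  expect_equal(res$branch, b_a)
  expect_equal(res$insertion_fraction, 3 / 4)
  res2 <- best_path(tr, make_tally(b_ab, 5, 0))
  expect_equal(res2$insertion_fraction, 1)
})

test_that("best path agrees with exhaustive prefix enumeration", {
  set.seed(202)
  for (rep in 1:60) {
    tr <- random_ref_tree(sample(4:32, 1L))
    bids <- branch_ids(tr)
    n <- length(bids)
    tal <- make_tally(bids,
                      rpois(n, 0.8) * rbinom(n, 1, 0.4),
                      rpois(n, 1.2))
    mine <- best_path(tr, tal, max_conflict = 3)
    oracle <- oracle_best_path(tr, tal, max_conflict = 3)
    expect_equal(mine$placed, oracle$placed)
    if (oracle$placed) {
      expect_equal(mine$support_above + mine$support_on, oracle$support)
      if (!oracle$tie) expect_equal(mine$branch, oracle$branch)
      expect_equal(mine$tie, oracle$tie)
    }
  }
})

test_that("per-edge likelihood matches closed-form on the quartet", {
  tr <- quartet_tree()
  b_ab <- find_branch(tr, c("A", "B"))
  eps <- 0.001
  lp <- likelihood_place(tr, make_tally(b_ab, 10, 0), epsilon = eps)
  # closed form over the 6 edges: A and B see the 10 SNPs as expected
  # derived (strict ancestor); the AB edge ignores its own SNPs; all other
  # edges see them as mismatches
  ll <- function(b) {
    if (b == b_ab) 0
    else if (b %in% c(find_branch(tr, "A"), find_branch(tr, "B")))
      10 * log(1 - eps)
    else 10 * log(eps)
  }
  expected_ll <- vapply(lp$posterior$branch, ll, 0)
  expect_equal(lp$posterior$loglik, expected_ll)
  w <- exp(expected_ll - max(expected_ll))
  expect_equal(lp$posterior$posterior, w / sum(w), tolerance = 1e-12)
  # mass concentrates in the AB clade; the 99% clade is its branch
  expect_equal(lp$clade99, b_ab)
  expect_true(all(c(find_branch(tr, "A"), find_branch(tr, "B"), b_ab)
                  %in% lp$reported))
})

test_that("no data gives a uniform posterior and an ambiguous clade", {
  tr <- quartet_tree()
  lp <- likelihood_place(tr, make_tally(integer(0), integer(0), integer(0)))
  expect_equal(lp$posterior$posterior, rep(1 / 6, 6))
  expect_true(is.na(lp$clade99))  # no root-side clade concentrates the mass
})

test_that("homoplasy-like symmetric support escalates the 99% clade", {
  tr <- read_newick("((((A,B),(C,D)),E),F);")
  b1 <- find_branch(tr, c("A", "B"))
  b2 <- find_branch(tr, c("C", "D"))
  lp <- likelihood_place(tr, make_tally(c(b1, b2), c(6, 6), c(0, 0)),
                         epsilon = 0.01)
  post <- lp$posterior
  mass_below <- function(b) {
    below <- vapply(post$branch, function(x)
      b %in% path_to_root(tr, x), TRUE)
    sum(post$posterior[below])
  }
  # bimodal: the two sibling clades carry equal mass
  expect_equal(mass_below(b1), mass_below(b2), tolerance = 1e-9)
  # so the 99% clade escalates to their common ancestor branch
  expect_equal(lp$clade99, find_branch(tr, c("A", "B", "C", "D")))

  # fully mirrored clades across the root leave no qualifying branch
  tr2 <- read_newick("(((A,B),(C,D)),((E,F),(G,H)));")
  lp2 <- likelihood_place(
    tr2, make_tally(c(find_branch(tr2, c("A", "B")),
                      find_branch(tr2, c("E", "F"))),
                    c(6, 6), c(0, 0)), epsilon = 0.01)
  expect_true(is.na(lp2$clade99))
})

test_that("posteriors normalize and clade99 contains the best branch", {
  set.seed(303)
  for (rep in 1:200) {
    tr <- random_ref_tree(sample(4:24, 1L))
    bids <- branch_ids(tr)
    n <- length(bids)
    tal <- make_tally(bids, rpois(n, 1), rpois(n, 1))
    lp <- likelihood_place(tr, tal, epsilon = 0.01)
    expect_equal(sum(lp$posterior$posterior), 1, tolerance = 1e-9)
    expect_true(lp$best %in% lp$reported)
    if (!is.na(lp$clade99)) {
      path <- path_to_root(tr, lp$best)
      expect_true(lp$clade99 %in% path)
      # it is the lowest qualifying branch on that path
      below <- function(b) {
        inb <- vapply(lp$posterior$branch, function(x)
          b %in% path_to_root(tr, x), TRUE)
        sum(lp$posterior$posterior[inb])
      }
      expect_gt(below(lp$clade99), 0.99)
      deeper <- path[which(path == lp$clade99) + 1L]
      if (length(deeper) && !is.na(deeper))
        expect_lte(below(deeper), 0.99)
    }
  }
})

test_that("annotated insertion builds the labelled leaf", {
  tr <- quartet_tree()
  b_ab <- find_branch(tr, c("A", "B"))
  res <- best_path(tr, make_tally(b_ab, 5, 0))
  t2 <- annotate_and_insert(tr, res, "ASH008")
  expect_true(sprintf("ASH008 %s", res$annotation) %in% t2$leaf_names)

  unpl <- best_path(tr, make_tally(integer(0), integer(0), integer(0)))
  expect_warning(t3 <- annotate_and_insert(tr, unpl, "Q"), "unplaced")
  expect_equal(t3$n_tip, tr$n_tip)
  expect_false(attr(t3, "placed"))

  tied <- best_path(tr, make_tally(c(b_ab, find_branch(tr, c("C", "D"))),
                                   c(3, 3), c(0, 0)))
  expect_warning(t4 <- annotate_and_insert(tr, tied, "Q",
                                           fallback_branch = b_ab),
                 "fallback")
  expect_true(any(grepl("^Q ", t4$leaf_names)))
})
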