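test_that("nodal shift statistic has exact boundary and degenerate values", {
  expect_equal(node_shift_loglr(2, 1), 0)
  for (n in c(5, 17, 278, 1000))
    expect_equal(node_shift_loglr(n, n - 1), log(n - 1))
  expect_equal(node_shift_loglr(278, 277), log(277), tolerance = 1e-12)
  # near-central splits carry almost no shift evidence
  expect_lt(node_shift_loglr(277, 138), 0.01)
  expect_gte(node_shift_loglr(277, 138), 0)
  expect_error(node_shift_loglr(5, 5), "out of range")
  expect_error(node_shift_loglr(5, 0), "out of range")
  expect_error(node_shift_loglr(1, 1), "n must be")
})

test_that("nodal shift statistic matches a bracketed optimizer oracle", {
  oracle <- function(n, i) {
    m <- n - 1
    f <- function(logr) {
      ell <- (1:m) * logr
      i * logr - (max(ell) + log(sum(exp(ell - max(ell))))) + log(m)
    }
    opt <- optimize(f, c(-25, 25), maximum = TRUE, tol = 1e-10)
    max(opt$objective, 0)
  }
  set.seed(55)
  for (k in 1:40) {
    n <- sample(3:200, 1)
    i <- sample(2:(n - 2 + (n == 3)), 1)
    expect_equal(node_shift_loglr(n, i), oracle(n, i), tolerance = 1e-6)
  }
})

test_that("nodal shift statistic is symmetric and center-monotone", {
  for (n in 3:200) {
    v <- node_shift_loglr(rep(n, n - 1), 1:(n - 1))
    expect_equal(v, rev(v))  # reflection symmetry i <-> n-i
    half <- v[1:ceiling((n - 1) / 2)]
    expect_true(all(diff(half) <= 1e-9))  # non-increasing toward center
  }
})

test_that("local triplets extract outgroup and basal ingroup sizes", {
  # ((A 3 tips, B 2 tips), C 4 tips): branch above (A,B)
  tr <- parse_newick("(((a1,(a2,a3)),(b1,b2)),((c1,c2),(c3,c4)));")
  ab <- ape::getMRCA(tr, c("a1", "b1"))
  tri <- local_triplet(tr, ab)
  expect_equal(tri$n_O, 4)
  expect_setequal(c(tri$n_L, tri$n_R), c(3, 2))
  expect_equal(tri$n, 9)

  t4 <- parse_newick("(((a,b),c),d);")
  cherry <- ape::getMRCA(t4, c("a", "b"))
  tri2 <- local_triplet(t4, ape::getMRCA(t4, c("a", "c")))
  expect_equal(c(tri2$n_O, sort(c(tri2$n_L, tri2$n_R))), c(1, 1, 2))
  expect_error(local_triplet(t4, cladeshift:::.root_of(t4)), "root")
  expect_error(local_triplet(t4, 1L), "tip")
  # a branch above a cherry is eligible: the triplet is (1, 1, 1)
  tri3 <- local_triplet(t4, cherry)
  expect_equal(c(tri3$n_O, tri3$n_L, tri3$n_R), c(1, 1, 1))
})

test_that("delta-1 matches closed forms and is symmetric in the ingroups", {
  expect_equal(delta1(c(1, 1, 1)), log(2))
  d <- delta1(c(1, 138, 139))
  expect_equal(d, log(277) - node_shift_loglr(277, 138))
  expect_lt(abs(d - log(277)), 0.01)
  expect_equal(delta1(c(4, 3, 2)), delta1(c(4, 2, 3)))
  tr <- parse_newick("(((a,b),c),d);")
  tri <- local_triplet(tr, ape::getMRCA(tr, c("a", "c")))
  expect_equal(delta1(tri),
               node_shift_loglr(4, 3) - node_shift_loglr(3, 2))
})

test_that("the shift scan depends on shape only and ranks planted shifts", {
  expect_error(scan_shifts(bal4(), n_null = 10), "n_null")
  set.seed(66)
  tr <- simulate_erm_tree(40)
  null40 <- make_delta1_null(40, 1000, seed = 1)
  sc1 <- scan_shifts(tr, null = null40, seed = 2)
  tr2 <- tr
  tr2$tip.label <- sample(tr$tip.label)  # permute labels, same shape
  sc2 <- scan_shifts(tr2, null = null40, seed = 2)
  expect_equal(sort(sc1$delta1), sort(sc2$delta1))
  expect_equal(sort(sc1$p), sort(sc2$p))

  # fully balanced tree: every split is even, nothing approaches the
  # upper null tail
  balsc <- scan_shifts(balanced_tree(7), null = make_delta1_null(128, 1000,
                                                                 seed = 3))
  expect_equal(sum(balsc$class == "significant"), 0L)

  # a strong planted shift gives its stem branch the top delta-1
  tr8 <- plant_rate_shift(150, lambda = 0.2, s = 8, shift_at_k = 6,
                          seed = 10)
  sc8 <- scan_shifts(tr8, null = make_delta1_null(150, 1000, seed = 4))
  expect_lte(which(sc8$branch == attr(tr8, "shift_node")),
             ceiling(0.05 * nrow(sc8)))
})

test_that("soft polytomies are aggregated across resolutions", {
  poly <- parse_newick("((a,b,c,d,e,f,g),(h,i));")
  sc <- scan_shifts(poly, n_null = 500, n_resolutions = 30, seed = 9)
  expect_equal(attr(sc, "n_resolutions"), 30L)
  expect_true(all(sc$delta1_low <= sc$delta1_high))
  expect_true(all(sc$p > 0 & sc$p <= 1))
  # the polytomy node itself is an eligible original branch
  expect_true(any(sc$n_O == 2))
})

test_that("shift counting respects nesting and the smallest-clade rule", {
  set.seed(77)
  tr <- simulate_erm_tree(60)
  sc <- scan_shifts(tr, null = make_delta1_null(60, 1000, seed = 5))
  sets <- cladeshift:::.clade_tips(tr)
  root <- cladeshift:::.root_of(tr)
  all_tips <- tr$tip.label
  # pick an internal clade and nest it inside the full tip set
  inner <- sets[[sc$branch[1]]]
  counts <- count_sdr(sc, list(inner = inner, everything = all_tips))
  flagged <- sc[sc$class %in% c("significant", "marginal"), ]
  expect_equal(sum(counts$significant) + sum(counts$marginal),
               nrow(flagged))
  # a shift strictly inside `inner` must be counted there, not in the
  # enclosing clade
  bt <- attr(sc, "branch_tips")
  in_inner <- vapply(as.character(flagged$branch),
                     function(b) all(bt[[b]] %in% inner), logical(1))
  expect_equal(counts$significant[counts$clade == "inner"] +
                 counts$marginal[counts$clade == "inner"],
               sum(in_inner))
  # overlapping non-nested definitions are rejected
  expect_error(
    count_sdr(sc, list(x = all_tips[1:10], y = all_tips[5:20])),
    "overlap without nesting")
  # empty result set gives all-zero counts
  empty <- sc[sc$p > 2, ]
  attr(empty, "branch_tips") <- attr(sc, "branch_tips")
  class(empty) <- class(sc)
  c0 <- count_sdr(empty, list(everything = all_tips))
  expect_true(all(c0$significant == 0) && all(c0$marginal == 0))
})
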