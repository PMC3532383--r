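test_that("IC and B1 match closed forms on reference shapes", {
  expect_equal(colless_index(cat4()), 3L)
  expect_equal(colless_index(bal4()), 0L)
  expect_equal(colless_index(caterpillar(5)), 6L)  # (n-1)(n-2)/2 maximum
  expect_equal(b1_index(cat4()), 1.5)
  expect_equal(b1_index(bal4()), 2.0)
  expect_equal(b1_index(parse_newick("((a,b),c);")), 1.0)
  poly <- parse_newick("((a,b,c),d);")
  expect_error(colless_index(poly), "resolve_polytomies")
  expect_error(b1_index(poly), "resolve_polytomies")
})

test_that("nodal log-probability summaries match the ERM split law", {
  expect_equal(nodal_logprob_stats(bal4()),
               c(MPi = log(1 / 3), Msig = 0))
  expect_equal(nodal_logprob_stats(cat4()),
               c(MPi = log(2 / 3) / 2, Msig = -log(2 / 3) / 2))
  set.seed(31)
  for (k in 1:20) {
    st <- nodal_logprob_stats(simulate_erm_tree(sample(4:60, 1)))
    expect_lte(st[["MPi"]], 0)
    expect_gte(st[["Msig"]], 0)
  }
})

test_that("per-node ERM probabilities multiply to the shape law", {
  # over all unlabeled shapes of size n, exp(sum of per-node log split
  # probabilities) must be a probability distribution; the per-shape
  # probability is recomputed independently from ape::balance
  for (n in 5:7) {
    tot <- 0
    for (nw in all_shapes_newick(n)) {
      tr <- parse_newick(nw)
      bal <- ape::balance(tr)
      p_oracle <- prod(ifelse(bal[, 1] == bal[, 2], 1, 2) /
                         (rowSums(bal) - 1))
      st <- nodal_logprob_stats(tr)
      n_informative <- sum(rowSums(bal) >= 3)
      expect_equal(exp(st[["MPi"]] * n_informative), p_oracle,
                   tolerance = 1e-12)
      tot <- tot + p_oracle
    }
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("streaming indices equal naive per-node recomputation", {
  set.seed(404)
  for (k in 1:500) {
    tr <- simulate_erm_tree(sample(4:80, 1))
    bal <- ape::balance(tr)
    expect_equal(colless_index(tr), sum(abs(bal[, 1] - bal[, 2])))
    # naive B1: max edge-count depth per non-root internal node
    ntip <- length(tr$tip.label)
    kids <- cladeshift:::.children(tr)
    maxdep <- function(v) {
      if (v <= ntip) return(0L)
      1L + max(vapply(kids[[v]], maxdep, integer(1)))
    }
    root <- cladeshift:::.root_of(tr)
    internals <- setdiff((ntip + 1):(ntip + tr$Nnode), root)
    expect_equal(b1_index(tr),
                 sum(1 / vapply(internals, maxdep, integer(1))))
  }
})

test_that("IC decreases as the root split becomes more even", {
  # trees (cat_a, cat_b) with a + b = 12: IC has the closed form
  # (a-1)(a-2)/2 + (b-1)(b-2)/2 + |a-b|, strictly decreasing toward a = b
  ics <- vapply(2:6, function(a) {
    b <- 12L - a
    nwa <- sub(";$", "", write_newick(caterpillar(a)))
    nwb <- gsub("t", "s", sub(";$", "", write_newick(caterpillar(b))))
    ic <- colless_index(parse_newick(paste0("(", nwa, ",", nwb, ");")))
    expect_equal(ic, (a - 1) * (a - 2) / 2 + (b - 1) * (b - 2) / 2 +
                   abs(a - b))
    ic
  }, numeric(1))
  expect_true(all(diff(ics) < 0))
})

test_that("ERM simulation reproduces exact small-tree laws", {
  t2 <- simulate_erm_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2L)
  set.seed(17)
  # n = 3: each labeled topology (identified by the odd tip out) 1/3
  odd <- replicate(6000, {
    tr <- simulate_erm_tree(3)
    sets <- cladeshift:::.clade_tips(tr)
    setdiff(tr$tip.label, sets[lengths(sets) == 2][[1]])
  })
  expect_gt(suppressWarnings(chisq.test(table(odd))$p.value), 0.001)
  # n = 4: root split (2,2) with probability 1/3
  even <- replicate(6000, {
    tr <- simulate_erm_tree(4)
    st <- cladeshift:::tree_shape_cpp(tr$edge, 4)
    min(st$tip_counts[cladeshift:::.children(tr)[[st$root]]]) == 2
  })
  expect_lt(abs(mean(even) - 1 / 3), 3 * sqrt(2 / 9 / 6000))
})

test_that("Monte-Carlo IC null matches complete enumeration", {
  for (n in c(6L, 8L)) {
    d <- erm_ic_distribution(n)
    expect_equal(sum(d$prob), 1)
    set.seed(n)
    mc <- cladeshift:::erm_shape_stats_cpp(n, 20000)[, 1]
    counts <- table(factor(mc, levels = d$ic))
    expect_gt(suppressWarnings(
      chisq.test(as.integer(counts), p = d$prob)$p.value), 0.001)
  }
})

test_that("whole-tree test calibrates extremes correctly", {
  expect_error(whole_tree_test(bal4(), n_null = 50), "n_null")
  cat64 <- caterpillar(64)
  wt <- whole_tree_test(cat64, n_null = 1000, seed = 3)
  icrow <- wt$table[wt$table$index == "IC", ]
  expect_equal(icrow$p_low, 1 / 1001)  # maximal imbalance
  expect_equal(icrow$low, (63 * 62) / 2)

  bal64 <- balanced_tree(6)
  wt2 <- whole_tree_test(bal64, n_null = 1000, seed = 4)
  expect_gte(wt2$table$p_low[wt2$table$index == "IC"], 0.99)

  # report invariants: low <= high, 0 < p <= 1, polytomies aggregated
  poly <- parse_newick("((a,b,c,d,e),(f,g),(h,i,j));")
  wt3 <- whole_tree_test(poly, n_null = 500, n_resolutions = 40, seed = 5)
  expect_true(all(wt3$table$low <= wt3$table$high))
  expect_true(all(wt3$table$p_low > 0 & wt3$table$p_high <= 1))
  expect_equal(wt3$n_resolutions, 40L)
})
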