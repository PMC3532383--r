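test_that("grafting attaches missing species at the right rank and node", {
  # single sampled congener -> new cherry
  tr <- parse_newick("((a1,b1),c1);")
  tax <- toy_taxonomy()
  comp <- graft_missing_species(tr, tax)
  expect_setequal(comp$tip.label, tax$species)
  expect_equal(comp$origin[comp$tip.label == "a2"], "grafted")
  pair <- ape::getMRCA(comp, c("a1", "a2"))
  expect_equal(length(ape::extract.clade(comp, pair)$tip.label), 2L)

  # monophyletic genus with two sampled members -> polytomy at the MRCA
  tr2 <- parse_newick("((a1,a2),c1);")
  tax2 <- rbind(toy_taxonomy()[c(1, 2, 4), ],
                data.frame(species = "a3", genus = "A", tribe = NA,
                           subfamily = NA, family = "F1", clade = "X",
                           sampled = FALSE))
  tax2$sampled[tax2$species == "a2"] <- TRUE
  comp2 <- graft_missing_species(tr2, tax2)
  kids <- cladeshift:::.children(comp2)
  mrca <- ape::getMRCA(comp2, c("a1", "a2"))
  expect_equal(length(kids[[mrca]]), 3L)

  # no sampled member anywhere in the family -> reported ungraftable
  tax3 <- rbind(toy_taxonomy(),
                data.frame(species = "z1", genus = "Z", tribe = NA,
                           subfamily = NA, family = "F9", clade = "X",
                           sampled = FALSE))
  expect_message(comp3 <- graft_missing_species(tr, tax3),
                 "could not be grafted")
  expect_equal(attr(comp3, "ungraftable"), "z1")
  expect_false("z1" %in% comp3$tip.label)

  # tree tip missing from the taxonomy
  expect_error(graft_missing_species(parse_newick("((q,b1),c1);"), tax),
               "absent from taxonomy")
  expect_error(graft_missing_species(tr, tax[0, ]), "empty taxonomy")
})

test_that("grafting preserves the induced topology and conserves tips", {
  set.seed(202)
  for (k in 1:15) {
    tree <- simulate_yule_dated(sample(20:80, 1), lambda = 0.25)
    sim <- simulate_taxonomy_and_sampling(tree, f = 0.56)
    comp <- suppressMessages(graft_missing_species(sim$sampled_tree,
                                                   sim$taxonomy))
    graftable <- nrow(sim$taxonomy) - sum(sim$taxonomy$sampled) -
      length(attr(comp, "ungraftable"))
    expect_equal(length(comp$tip.label),
                 sum(sim$taxonomy$sampled) + graftable)
    induced <- ape::keep.tip(comp, sim$sampled_tree$tip.label)
    expect_true(ape::all.equal.phylo(induced, sim$sampled_tree,
                                     use.edge.length = FALSE))
  }
})

test_that("random polytomy resolution is ERM-consistent", {
  # binary trees pass through unchanged
  b <- bal4()
  expect_identical(resolve_polytomies(b, seed = 5), b)

  # trichotomy: each of the 3 resolutions with frequency 1/3
  tri <- parse_newick("((a,b,c),d);")
  set.seed(7)
  cherries <- replicate(3000, {
    r <- resolve_polytomies(tri)
    expect_true(cladeshift:::.is_binary(r))
    sets <- cladeshift:::.clade_tips(r)
    two <- sets[lengths(sets) == 2]
    two <- two[vapply(two, function(s) !"d" %in% s, logical(1))]
    paste(sort(two[[1]]), collapse = "")
  })
  counts <- table(factor(cherries, levels = c("ab", "ac", "bc")))
  expect_gt(suppressWarnings(chisq.test(as.integer(counts))$p.value), 0.001)

  # degree-4 polytomy: all 15 labeled resolutions occur, following the
  # ERM shape law (unbalanced 1/18 each, balanced 1/9 each)
  quad <- parse_newick("(a,b,c,d);")
  set.seed(8)
  keys <- replicate(20000, {
    r <- resolve_polytomies(quad)
    sets <- cladeshift:::.clade_tips(r)
    nontrivial <- sets[lengths(sets) %in% 2:3]
    paste(sort(vapply(nontrivial, function(s) paste(sort(s), collapse = ""),
                      character(1))), collapse = "|")
  })
  tab <- table(keys)
  expect_equal(length(tab), 15L)
  # balanced resolutions have two 2-sets, caterpillars a 2-set and a 3-set
  exp_prob <- vapply(names(tab), function(k) {
    ln <- nchar(strsplit(k, "|", fixed = TRUE)[[1]])
    if (all(ln == 2)) 1 / 9 else 1 / 18
  }, numeric(1))
  expect_gt(suppressWarnings(
    chisq.test(as.integer(tab), p = exp_prob)$p.value), 0.001)

  # the multiset of tips below a formerly polytomous node is preserved
  big <- parse_newick("((a,b,c,d,e,f),(g,h));")
  r <- resolve_polytomies(big, seed = 11)
  map <- attr(r, "node_map")
  sets0 <- cladeshift:::.clade_tips(big)
  sets1 <- cladeshift:::.clade_tips(r)
  for (v in (length(big$tip.label) + 1):(length(big$tip.label) + big$Nnode))
    expect_setequal(sets1[[map[v]]], sets0[[v]])
})

test_that("coverage summary reports counts and rounded percentages", {
  tab <- toy_taxonomy()
  cov <- coverage_summary(tab, groups = "family")
  f1 <- cov[cov$group == "F1", ]
  expect_equal(f1$n_species, 3L)
  expect_equal(f1$n_species_sampled, 2L)
  expect_equal(f1$species_coverage_pct, 67)  # round(66.7)
  expect_equal(f1$n_genera, 2L)
  expect_equal(f1$n_genera_sampled, 2L)      # a1 sampled covers genus A
  f2 <- cov[cov$group == "F2", ]
  expect_equal(f2$species_coverage_pct, 100)
  tot <- cov[cov$group == "Total", ]
  expect_equal(tot$n_species, 4L)
  expect_error(coverage_summary(tab, groups = "order"), "unknown group")
})

test_that("count tables expand into taxonomies that restore the counts", {
  counts <- data.frame(
    group = c("Fam1", "Fam2"), clade = c("C1", "C1"),
    n_genera = c(5L, 3L), n_genera_sampled = c(3L, 0L),
    n_species = c(20L, 7L), n_species_sampled = c(11L, 0L))
  tax <- taxonomy_from_counts(counts)
  cov <- coverage_summary(tax, groups = "family")
  for (r in 1:2) {
    row <- cov[cov$group == counts$group[r], ]
    expect_equal(row$n_genera, counts$n_genera[r])
    expect_equal(row$n_genera_sampled, counts$n_genera_sampled[r])
    expect_equal(row$n_species, counts$n_species[r])
    expect_equal(row$n_species_sampled, counts$n_species_sampled[r])
  }
  bad <- counts; bad$n_species_sampled[1] <- 19L  # leaves no species for
  expect_error(taxonomy_from_counts(bad), "infeasible") # unsampled genera
})
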