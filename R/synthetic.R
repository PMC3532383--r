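# Generators for dated trees, planted rate shifts and nested taxonomies.
# These emulate the statistical structure the analysis assumes (ERM/Yule
# clade growth, partial species sampling) so the whole pipeline can be
# exercised and calibrated without any external data.

#' Simulate a dated Yule (pure-birth) tree
#'
#' Grows a crown group from 2 lineages: with `k` lineages alive the waiting
#' time to the next speciation is Exponential(`k * lambda`) and the
#' splitting lineage is chosen uniformly, so the topology is marginally
#' equal-rates Markov.  After the `n`-th tip is born the tips are extended
#' by a final Exponential(`n * lambda`) draw, and node ages are assigned so
#' that all tips are extant (age 0).
#'
#' @param n_tips number of tips (>= 2).
#' @param lambda speciation rate per lineage per Myr.
#' @param seed optional integer seed.
#' @return an ultrametric `phylo` with `edge.length` (Myr) and `node.ages`.
#' @export
simulate_yule_dated <- function(n_tips, lambda = 0.2, seed = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  .set_seed_if(seed)
  .grow_birth_tree(n_tips, lambda, s = 1, trigger_k = NULL,
                   shift_time = NULL)$tree
}

#' Simulate a dated tree with a planted diversification-rate shift
#'
#' Two-rate pure-birth growth: all lineages speciate at rate `lambda`
#' until a trigger point, when one extant lineage (chosen uniformly) and
#' all its descendants switch to rate `s * lambda`.  Growth stops at
#' `n_tips`.  The trigger is either a lineage count (`shift_at_k`: the
#' moment `k` lineages are alive) or an absolute time (`shift_time`, Myr
#' after the crown split; if the tree reaches `n_tips` first the
#' simulation is resampled, with the retry count reported).
#'
#' @param n_tips number of tips.
#' @param lambda base speciation rate per lineage per Myr.
#' @param s rate multiplier inside the shifted clade (`s = 1` reduces to
#'   [simulate_yule_dated()]).
#' @param shift_at_k lineage-count trigger (default 8); ignored when
#'   `shift_time` is given.
#' @param shift_time optional time trigger in Myr after the crown split.
#' @param seed optional integer seed.
#' @param max_retry resampling budget for the time trigger.
#' @return a dated `phylo` with attributes `shift_node` (ape id of the
#'   shifted clade's root: the ground-truth branch is the one above it),
#'   `shift_tips` (its tip labels) and `retries`.
#' @export
plant_rate_shift <- function(n_tips, lambda = 0.2, s = 8, shift_at_k = 8,
                             shift_time = NULL, seed = NULL,
                             max_retry = 50) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (!is.numeric(s) || s < 0) stop("s must be >= 0")
  if (is.null(shift_time)) {
    if (shift_at_k < 2L || shift_at_k > n_tips)
      stop("shift_at_k must be in 2..n_tips")
  }
  .set_seed_if(seed)
  retries <- 0L
  repeat {
    res <- .grow_birth_tree(n_tips, lambda, s,
                            trigger_k = if (is.null(shift_time)) shift_at_k
                            else NULL,
                            shift_time = shift_time)
    if (!is.null(res$shift_node)) break
    retries <- retries + 1L
    if (retries > max_retry)
      stop("shifted clade never born before stopping after ", max_retry,
           " retries; lower shift_time")
  }
  tree <- res$tree
  attr(tree, "shift_node") <- res$shift_node
  attr(tree, "shift_tips") <- res$shift_tips
  attr(tree, "retries") <- retries
  if (retries > 0L) message("time trigger missed ", retries, " time(s); resampled")
  tree
}

# shared pure-birth growth engine; returns NULL shift_node if a time
# trigger was requested but never reached
.grow_birth_tree <- function(n_tips, lambda, s, trigger_k, shift_time) {
  n_all <- 2L * n_tips - 1L
  parent <- integer(n_all)
  split_time <- rep(NA_real_, n_all)
  shifted <- logical(n_all)
  want_mark <- !is.null(trigger_k) || !is.null(shift_time)

  parent[2:3] <- 1L
  split_time[1] <- 0
  leaves <- c(2L, 3L)
  next_id <- 3L
  t <- 0
  marked <- NA_integer_

  mark_now <- function() {
    i <- sample.int(length(leaves), 1L)
    leaves[i]
  }
  if (want_mark && !is.null(trigger_k) && trigger_k == 2L) {
    marked <- mark_now()
    shifted[marked] <- TRUE
  }

  while (length(leaves) < n_tips) {
    rate <- lambda * (length(leaves) + (s - 1) * sum(shifted[leaves]))
    dt <- rexp(1, rate)
    if (want_mark && is.na(marked) && !is.null(shift_time) &&
        t + dt > shift_time) {
      marked <- mark_now()
      shifted[marked] <- TRUE
      # waiting time is memoryless: redraw from the post-shift rate
      t <- shift_time
      next
    }
    t <- t + dt
    w <- ifelse(shifted[leaves], s, 1)
    idx <- sample.int(length(leaves), 1L, prob = w)
    x <- leaves[idx]
    y <- next_id + 1L
    z <- next_id + 2L
    next_id <- next_id + 2L
    parent[y] <- x
    parent[z] <- x
    shifted[y] <- shifted[z] <- shifted[x]
    split_time[x] <- t
    leaves[idx] <- y
    leaves <- c(leaves, z)
    if (want_mark && is.na(marked) && !is.null(trigger_k) &&
        length(leaves) == trigger_k) {
      marked <- mark_now()
      shifted[marked] <- TRUE
    }
  }
  rate <- lambda * (n_tips + (s - 1) * sum(shifted[leaves]))
  t_end <- t + rexp(1, rate)

  labs <- character(n_all)
  labs[leaves] <- sample(paste0("t", seq_len(n_tips)))
  built <- .phylo_from_parents(parent, labs)
  tree <- built$tree
  map <- built$map
  ntip <- n_tips
  ages <- numeric(ntip + tree$Nnode)
  internal <- which(!is.na(split_time))
  ages[map[internal]] <- t_end - split_time[internal]
  tree$node.ages <- ages
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]

  out <- list(tree = tree, shift_node = NULL, shift_tips = NULL)
  if (want_mark) {
    if (is.na(marked)) return(list(tree = tree, shift_node = NULL))
    node <- map[marked]
    out$shift_node <- node
    out$shift_tips <- .clade_tips(tree)[[node]]
  }
  out
}

#' Simulate a nested taxonomy and partial species sampling
#'
#' Clusters the tips of a dated tree into genera and families by cutting
#' the tree at two heights (all groups are monophyletic by construction,
#' and ranks nest because the family cut is older than the genus cut);
#' major clades are the two children of the root.  Each species is then
#' sampled independently with probability `f`, emulating the partial
#' coverage of real sequence databases, and the tree is pruned to the
#' sampled tips.
#'
#' @param tree a dated `phylo` with `node.ages`.
#' @param f sampling fraction in (0, 1].
#' @param genus_frac,family_frac cut heights as fractions of tree height
#'   (genus cut must be younger than family cut, which must be younger
#'   than the root).
#' @param seed optional integer seed.
#' @return list with `taxonomy` (a validated taxonomy table) and
#'   `sampled_tree` (the dated tree pruned to sampled species).  Families
#'   in which no species was sampled are legitimate outputs: their species
#'   are ungraftable test cases downstream.
#' @export
simulate_taxonomy_and_sampling <- function(tree, f = 0.56,
                                           genus_frac = 1 / 3,
                                           family_frac = 2 / 3,
                                           seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.ages)) stop("tree must carry node ages")
  if (!(f > 0 && f <= 1)) stop("f must be in (0, 1]")
  if (!(genus_frac < family_frac && family_frac < 1))
    stop("need genus_frac < family_frac < 1")
  .set_seed_if(seed)
  ages <- tree$node.ages
  parent <- .parents(tree)
  ntip <- length(tree$tip.label)
  root <- .root_of(tree)
  H <- ages[root]

  group_at <- function(h) {
    # deepest ancestor of each tip whose age is below the cut
    vapply(seq_len(ntip), function(tip) {
      v <- tip
      while (parent[v] != 0L && ages[parent[v]] < h) v <- parent[v]
      v
    }, integer(1))
  }
  g_root <- group_at(genus_frac * H)
  f_root <- group_at(family_frac * H)
  c_root <- vapply(seq_len(ntip), function(tip) {
    v <- tip
    while (parent[v] != root) v <- parent[v]
    v
  }, integer(1))

  genus <- sprintf("G%04d", match(g_root, sort(unique(g_root))))
  family <- sprintf("F%03d", match(f_root, sort(unique(f_root))))
  clade <- sprintf("clade%s", LETTERS[match(c_root, sort(unique(c_root)))])
  sampled <- runif(ntip) < f
  if (!any(sampled)) stop("no species sampled; increase f")

  taxonomy <- validate_taxonomy(data.frame(
    species = tree$tip.label, genus = genus, tribe = NA_character_,
    subfamily = NA_character_, family = family, clade = clade,
    sampled = sampled, stringsAsFactors = FALSE))

  pruned <- ape::keep.tip(tree, tree$tip.label[sampled])
  if (sum(sampled) >= 2L) {
    pruned$node.ages <- .ages_from_lengths(pruned, context = "pruned tree")
  }
  list(taxonomy = taxonomy, sampled_tree = pruned)
}

#' Expand per-group count data into a placeholder taxonomy
#'
#' Builds a species-level taxonomy table realizing given per-group counts
#' of recognized and sampled genera and species, using placeholder names.
#' Useful for coverage accounting on published summary tables where only
#' the counts, not the species lists, are available.
#'
#' @param counts data.frame with columns `group` (used as the family
#'   name), `clade`, `n_genera`, `n_genera_sampled`, `n_species`,
#'   `n_species_sampled`.
#' @return a validated taxonomy table whose [coverage_summary()] restores
#'   the input counts.
#' @export
taxonomy_from_counts <- function(counts) {
  need <- c("group", "clade", "n_genera", "n_genera_sampled",
            "n_species", "n_species_sampled")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "))
  rows <- list()
  for (r in seq_len(nrow(counts))) {
    G <- counts$n_genera[r]; g <- counts$n_genera_sampled[r]
    S <- counts$n_species[r]; s <- counts$n_species_sampled[r]
    grp <- counts$group[r]
    if (g > G || s > S || (g > 0 && s < g) || S - s < G - g)
      stop("infeasible counts for group '", grp,
           "': need g <= G, s <= S, s >= g and S - s >= G - g")
    genus_names <- sprintf("%s_g%03d", grp, seq_len(G))
    # genera 1..g sampled; each needs >= 1 sampled species, the first
    # takes the surplus; unsampled genera get one unsampled species each,
    # remaining unsampled species join the first genus
    n_sp_genus <- integer(G)
    sp_sampled <- vector("list", G)
    if (g > 0) {
      n_samp <- c(s - (g - 1L), rep(1L, g - 1L))
      extra_unsamp <- S - s - (G - g)
      n_sp_genus[seq_len(g)] <- n_samp
      n_sp_genus[1] <- n_sp_genus[1] + extra_unsamp
      for (j in seq_len(g))
        sp_sampled[[j]] <- c(rep(TRUE, n_samp[j]),
                             rep(FALSE, n_sp_genus[j] - n_samp[j]))
    } else {
      extra <- S - G
      n_sp_genus[] <- 1L
      n_sp_genus[1] <- n_sp_genus[1] + extra
      for (j in seq_len(G)) sp_sampled[[j]] <- rep(FALSE, n_sp_genus[j])
    }
    if (g > 0 && g < G) {
      idx <- (g + 1L):G
      n_sp_genus[idx] <- 1L
      for (j in idx) sp_sampled[[j]] <- FALSE
    }
    for (j in seq_len(G)) {
      rows[[length(rows) + 1L]] <- data.frame(
        species = sprintf("%s_sp%03d", genus_names[j],
                          seq_len(n_sp_genus[j])),
        genus = genus_names[j], tribe = NA_character_,
        subfamily = NA_character_, family = grp,
        clade = counts$clade[r], sampled = sp_sampled[[j]],
        stringsAsFactors = FALSE)
    }
  }
  validate_taxonomy(do.call(rbind, rows))
}
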