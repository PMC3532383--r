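#' Graft species without molecular data onto a sampled tree
#'
#' Builds the complete species-level composite topology.  Every species in
#' the taxonomy that is absent from the tree is attached at the most recent
#' common ancestor (MRCA) of the sampled members of its lowest-ranked
#' taxonomic group that has at least one sampled member, searching genus,
#' then tribe, then subfamily, then family.  Attachment to a single sampled
#' relative creates a new cherry node; attachment to a group with several
#' sampled members adds a child to the group MRCA, creating or extending a
#' polytomy.  Several missing members of the same group are attached to the
#' same node, forming one polytomy rather than a nested chain, since their
#' relative order is unknown.
#'
#' Species whose family has no sampled member cannot be placed and are
#' reported in the `ungraftable` attribute.  The composite tree is a
#' topology-only object: branch lengths and ages, if any, are dropped,
#' because grafted tips carry no divergence-time information.
#'
#' @param tree a `phylo` whose tips are sampled species of `taxonomy`.
#' @param taxonomy a validated taxonomy table (see [read_taxonomy()]).
#' @return a `phylo` covering all graftable species, with an `origin`
#'   element (`"molecular"`/`"grafted"` per tip) and attributes
#'   `ungraftable` (character vector) and `n_grafted`.
#' @export
graft_missing_species <- function(tree, taxonomy) {
  stopifnot(inherits(tree, "phylo"))
  validate_taxonomy(taxonomy)
  if (nrow(taxonomy) == 0L) stop("empty taxonomy")
  tips <- tree$tip.label
  absent <- setdiff(tips, taxonomy$species)
  if (length(absent) > 0L)
    stop("tree tip(s) absent from taxonomy: ",
         paste(utils::head(absent, 5), collapse = ", "))
  missing <- setdiff(taxonomy$species, tips)

  tax_by_sp <- taxonomy
  rownames(tax_by_sp) <- tax_by_sp$species
  tip_rows <- tax_by_sp[tips, , drop = FALSE]

  # sampled members per group value, per rank, among actual tips
  ranks <- c("genus", "tribe", "subfamily", "family")
  members <- lapply(ranks, function(r) split(tips, tip_rows[[r]]))
  names(members) <- ranks

  target_key <- character(length(missing))
  ungraftable <- character(0)
  for (k in seq_along(missing)) {
    sp <- missing[k]
    row <- tax_by_sp[sp, ]
    key <- NA_character_
    for (r in ranks) {
      g <- row[[r]]
      if (is.na(g)) next
      mem <- members[[r]][[g]]
      if (!is.null(mem) && length(mem) > 0L) {
        key <- paste(r, g, sep = ":")
        break
      }
    }
    if (is.na(key)) ungraftable <- c(ungraftable, sp)
    target_key[k] <- key
  }
  graftable <- missing[!is.na(target_key)]
  target_key <- target_key[!is.na(target_key)]

  ntip <- length(tips)
  n_orig <- ntip + tree$Nnode
  n_new_tips <- length(graftable)
  # worst case one new internal node per group
  groups <- split(graftable, target_key)
  parent <- integer(n_orig + n_new_tips + length(groups))
  parent[seq_len(n_orig)] <- .parents(tree)
  labels <- character(length(parent))
  labels[seq_len(ntip)] <- tips
  next_id <- n_orig
  new_tip_ids <- integer(0)

  # process higher ranks first so that, when one sampled tip anchors groups
  # at several ranks, family-level additions end up outside genus cherries
  rank_of <- vapply(strsplit(names(groups), ":", fixed = TRUE),
                    function(p) p[1], character(1))
  key_order <- names(groups)[order(match(rank_of, rev(ranks)))]
  for (key in key_order) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    mem <- members[[parts[1]]][[paste(parts[-1], collapse = ":")]]
    if (length(mem) == 1L) {
      tip_id <- match(mem, tips)
      next_id <- next_id + 1L
      node <- next_id
      parent[node] <- parent[tip_id]
      parent[tip_id] <- node
    } else {
      node <- ape::getMRCA(tree, mem)
    }
    for (sp in groups[[key]]) {
      next_id <- next_id + 1L
      parent[next_id] <- node
      labels[next_id] <- sp
      new_tip_ids <- c(new_tip_ids, next_id)
    }
  }
  used <- seq_len(next_id)
  built <- .phylo_from_parents(parent[used], labels[used])
  out <- built$tree
  origin <- rep("molecular", length(out$tip.label))
  origin[match(graftable, out$tip.label)] <- "grafted"
  out$origin <- origin
  attr(out, "ungraftable") <- ungraftable
  attr(out, "n_grafted") <- n_new_tips
  if (length(ungraftable) > 0L)
    message(length(ungraftable),
            " species could not be grafted (no sampled member in their family)")
  out
}

#' Randomly resolve soft polytomies
#'
#' Replaces every multifurcation by a random binary resolution of its
#' children drawn from the equal-rates Markov (ERM) law, i.e. a uniformly
#' random labeled history: the children are joined by the same iterated
#' tip-splitting process that generates ERM trees.  A trichotomy therefore
#' yields each of its 3 binary resolutions with probability 1/3, and a
#' degree-4 polytomy each of its 15 resolutions with the ERM shape law.
#' Relationships among already-resolved nodes are never rearranged.
#'
#' @param tree a `phylo`, possibly with polytomies.
#' @param seed optional integer seed for reproducibility.
#' @return a strictly bifurcating `phylo`.  If the input was already binary
#'   it is returned unchanged.  Otherwise the result is topology-only and
#'   carries a `node_map` attribute mapping original node ids to node ids in
#'   the resolved tree.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (.is_binary(tree)) return(tree)
  .set_seed_if(seed)

  ntip <- length(tree$tip.label)
  n_orig <- ntip + tree$Nnode
  kids <- .children(tree)
  deg <- lengths(kids)
  poly <- which(deg > 2L)
  extra <- sum(deg[poly] - 2L)
  parent <- integer(n_orig + extra)
  parent[seq_len(n_orig)] <- .parents(tree)
  labels <- character(length(parent))
  labels[seq_len(ntip)] <- tree$tip.label
  next_id <- n_orig

  for (p in poly) {
    cs <- sample(kids[[p]])
    k <- length(cs)
    # ERM growth over the k child subtrees: split a uniform current slot
    leaves <- cs[1:2]
    parent[cs[1]] <- p
    parent[cs[2]] <- p
    for (j in 3:k) {
      idx <- sample.int(length(leaves), 1L)
      x <- leaves[idx]
      next_id <- next_id + 1L
      v <- next_id
      parent[v] <- parent[x]
      parent[x] <- v
      parent[cs[j]] <- v
      leaves <- c(leaves, cs[j])
    }
  }
  built <- .phylo_from_parents(parent, labels)
  out <- built$tree
  if (!is.null(tree$origin)) {
    out$origin <- tree$origin[match(out$tip.label, tree$tip.label)]
  }
  attr(out, "node_map") <- built$map[seq_len(n_orig)]
  out
}

#' Taxonomic coverage summary
#'
#' Tabulates, for each value of the requested ranks plus a grand total, the
#' number of recognized and sampled genera and species and the integer
#' coverage percentages (a genus counts as sampled when at least one of its
#' species is sampled).
#'
#' @param taxonomy a validated taxonomy table.
#' @param groups ranks to summarize by, a subset of
#'   `c("clade", "family", "subfamily")`.
#' @return a data.frame with one row per group value plus a `Total` row;
#'   columns `group`, `rank`, `n_genera`, `n_genera_sampled`,
#'   `genus_coverage_pct`, `n_species`, `n_species_sampled`,
#'   `species_coverage_pct`.  Percentages are rounded to the nearest
#'   integer.
#' @export
coverage_summary <- function(taxonomy, groups = c("clade", "family")) {
  validate_taxonomy(taxonomy)
  ok <- c("clade", "family", "subfamily")
  bad <- setdiff(groups, ok)
  if (length(bad) > 0L)
    stop("unknown group rank(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(ok, collapse = ", "), ")")
  one <- function(sub, label, rank) {
    by_genus <- split(sub$sampled, sub$genus)
    ng <- length(by_genus)
    ngs <- sum(vapply(by_genus, any, logical(1)))
    ns <- nrow(sub)
    nss <- sum(sub$sampled)
    data.frame(group = label, rank = rank,
               n_genera = ng, n_genera_sampled = ngs,
               genus_coverage_pct = round(100 * ngs / ng),
               n_species = ns, n_species_sampled = nss,
               species_coverage_pct = round(100 * nss / ns),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (rank in groups) {
    vals <- unique(taxonomy[[rank]])
    vals <- vals[!is.na(vals)]
    for (v in vals)
      out[[length(out) + 1L]] <-
        one(taxonomy[!is.na(taxonomy[[rank]]) & taxonomy[[rank]] == v, ],
            v, rank)
  }
  out[[length(out) + 1L]] <- one(taxonomy, "Total", "total")
  do.call(rbind, out)
}
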