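#' Local diversity triplet for an internal branch
#'
#' A branch whose child node is internal anchors a three-clade comparison:
#' the sibling clade at the parent node is the local outgroup (`n_O`) and
#' the two children of the branch's child are the basal-most ingroup clades
#' (`n_L`, `n_R`).
#'
#' @param tree a strictly bifurcating `phylo`.
#' @param branch the child node id of the branch (ape numbering).
#' @return a list with `branch`, `n_O`, `n_L`, `n_R`, `n_I = n_L + n_R`
#'   and `n = n_O + n_I`.
#' @export
local_triplet <- function(tree, branch) {
  st <- .shape_stats(tree)
  tc <- st$tip_counts
  ntip <- length(tree$tip.label)
  root <- st$root
  if (branch == root) stop("the root has no branch above it")
  if (branch <= ntip) stop("branch subtends a tip: no triplet defined")
  parent <- .parents(tree)
  kids <- .children(tree)
  p <- parent[branch]
  sib <- setdiff(kids[[p]], branch)
  cs <- kids[[branch]]
  list(branch = branch,
       n_O = sum(tc[sib]), n_L = tc[cs[1]], n_R = tc[cs[2]],
       n_I = tc[branch], n = tc[p])
}

#' Nodal shift log-likelihood ratio
#'
#' Evidence that a clade of `n` tips split unevenly relative to the
#' homogeneous ERM expectation.  Under homogeneous equal-rates growth the
#' ingroup split size `i` is uniform on `1..n-1`; under a one-shift
#' two-rate model it follows a truncated geometric law
#' `P(i | n, r) = r^i / sum_j r^j`.  The statistic is
#' `ln[ sup_r P(i|n,r) / (1/(n-1)) ]`, found by solving the score equation
#' for the truncated-geometric mean.  It equals `ln(n-1)` exactly at the
#' boundaries `i = 1` and `i = n-1`, is 0 for `n = 2`, and is symmetric
#' under `i -> n-i`.
#'
#' @param n clade size(s), `>= 2`.
#' @param i split size(s), `1 <= i <= n-1`.  Recycled against `n`.
#' @return numeric vector of non-negative log-likelihood ratios.
#' @export
node_shift_loglr <- function(n, i) {
  k <- max(length(n), length(i))
  shift_loglr_cpp(as.integer(rep_len(n, k)), as.integer(rep_len(i, k)))
}

#' Delta-1 shift statistic on a local triplet
#'
#' The branch-localized diversification-rate-shift statistic: the shift
#' evidence at the inclusive node (clade of size `n = n_O + n_L + n_R`
#' splitting into outgroup and ingroup) minus the part attributable to the
#' nodal split of the ingroup itself,
#' `delta1 = loglr(n, n_I) - loglr(n_I, n_L)`.  It is invariant under
#' swapping `n_L` and `n_R` and may be negative when the nodal split is
#' more extreme than the inclusive one.
#'
#' @param triplet a list or data.frame with `n_O`, `n_L`, `n_R` (as
#'   returned by [local_triplet()]), or a numeric vector
#'   `c(n_O, n_L, n_R)`.
#' @return numeric.
#' @export
delta1 <- function(triplet) {
  if (is.numeric(triplet) && length(triplet) == 3L)
    triplet <- list(n_O = triplet[1], n_L = triplet[2], n_R = triplet[3])
  n_O <- triplet$n_O; n_L <- triplet$n_L; n_R <- triplet$n_R
  stopifnot(all(n_O >= 1), all(n_L >= 1), all(n_R >= 1))
  n_I <- n_L + n_R
  node_shift_loglr(n_O + n_I, n_I) - node_shift_loglr(n_I, n_L)
}

#' Monte-Carlo null distribution for delta-1
#'
#' Simulates ERM trees of a given size and pools the delta-1 values of all
#' eligible internal branches, giving the reference distribution for
#' [scan_shifts()] in pooled mode.  Precompute it once when scanning many
#' trees of the same size.
#'
#' @param n_tips tree size the null is conditioned on.
#' @param n_null number of ERM trees (>= 100).
#' @param seed optional integer seed.
#' @return an object of class `delta1_null` holding the sorted pooled
#'   sample.
#' @export
make_delta1_null <- function(n_tips, n_null = 10000, seed = NULL) {
  if (n_null < 100) stop("n_null < 100 cannot discriminate at alpha = 0.05")
  .set_seed_if(seed)
  vals <- sort(erm_delta1_pool_cpp(as.integer(n_tips), as.integer(n_null)))
  structure(list(n_tips = n_tips, n_null = n_null, values = vals),
            class = "delta1_null")
}

#' @export
print.delta1_null <- function(x, ...) {
  cat(sprintf(
    "Pooled ERM delta-1 null: %d trees of %d tips, %d branch values\n",
    x$n_null, x$n_tips, length(x$values)))
  invisible(x)
}

#' Scan all internal branches for diversification-rate shifts
#'
#' Computes the delta-1 statistic for every eligible internal branch (one
#' whose child node is internal) and an upper-tail Monte-Carlo p-value
#' against an equal-rates Markov null.  Polytomies are treated as soft:
#' statistics are recomputed over `n_resolutions` random ERM resolutions
#' and each branch of the input tree reports the median (and quantiles) of
#' its per-resolution values.
#'
#' Two null modes are available.  `"pooled"` (default) pools the delta-1
#' values of all eligible branches of `n_null` ERM trees with the same tip
#' count as `tree`.  `"size-conditional"` conditions each branch's null on
#' its observed parent clade size: triplets are drawn as an eligible
#' uniform split of that clade followed by a uniform nodal split.
#'
#' @param tree a `phylo`, possibly polytomous.
#' @param n_null number of null replicates (>= 100).
#' @param n_resolutions random resolutions for soft polytomies (ignored
#'   for binary trees).
#' @param null_mode `"pooled"` or `"size-conditional"`.
#' @param seed optional integer seed.
#' @param alpha_inclusive if `TRUE`, p-values equal to 0.05 are classed
#'   significant rather than marginal.
#' @param null optional precomputed [make_delta1_null()] object (pooled
#'   mode only; its `n_tips` must match the tree).
#' @return an object of class `shift_report`: a data.frame with one row
#'   per eligible branch (`branch`, `clade`, `n_O`, `n_L`, `n_R`,
#'   `delta1`, `delta1_low`, `delta1_high`, `p`, `p_low`, `p_high`,
#'   `class`), ordered by decreasing `delta1`.  The tip set of each branch
#'   is kept in the `branch_tips` attribute.
#' @export
scan_shifts <- function(tree, n_null = 10000, n_resolutions = 100,
                        null_mode = c("pooled", "size-conditional"),
                        seed = NULL, alpha_inclusive = FALSE, null = NULL) {
  stopifnot(inherits(tree, "phylo"))
  null_mode <- match.arg(null_mode)
  if (n_null < 100) stop("n_null < 100 cannot discriminate at alpha = 0.05")
  .set_seed_if(seed)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  root <- .root_of(tree)
  eligible <- setdiff((ntip + 1L):n_all, root)
  if (length(eligible) == 0L) stop("tree has no eligible internal branch")

  binary <- .is_binary(tree)
  n_res <- if (binary) 1L else as.integer(n_resolutions)

  d1 <- matrix(NA_real_, n_res, length(eligible))
  tO <- tL <- tR <- tP <- d1
  for (r in seq_len(n_res)) {
    rt <- if (binary) tree else resolve_polytomies(tree)
    map <- if (binary) seq_len(n_all) else attr(rt, "node_map")
    st <- tree_shape_cpp(rt$edge, ntip)
    tc <- st$tip_counts
    parent <- .parents(rt)
    kids <- .children(rt)
    for (k in seq_along(eligible)) {
      v <- map[eligible[k]]
      p <- parent[v]
      sib <- setdiff(kids[[p]], v)
      cs <- kids[[v]]
      tO[r, k] <- sum(tc[sib])
      tL[r, k] <- tc[cs[1]]
      tR[r, k] <- tc[cs[2]]
      tP[r, k] <- tc[p]
    }
    nI <- tL[r, ] + tR[r, ]
    d1[r, ] <- node_shift_loglr(tP[r, ], nI) - node_shift_loglr(nI, tL[r, ])
  }

  # p-values per resolution against the null, then aggregated by median
  pmat <- matrix(NA_real_, n_res, length(eligible))
  if (null_mode == "pooled") {
    if (is.null(null)) null <- make_delta1_null(ntip, n_null)
    if (!inherits(null, "delta1_null"))
      stop("null must be a delta1_null object")
    if (null$n_tips != ntip)
      stop("null was built for ", null$n_tips, " tips, tree has ", ntip)
    nv <- null$values
    for (r in seq_len(n_res)) {
      exc <- length(nv) - findInterval(d1[r, ], nv, left.open = TRUE)
      pmat[r, ] <- (1 + exc) / (1 + length(nv))
    }
  } else {
    cache <- new.env(parent = emptyenv())
    for (r in seq_len(n_res)) {
      for (k in seq_along(eligible)) {
        key <- as.character(tP[r, k])
        if (is.null(cache[[key]]))
          cache[[key]] <- sort(erm_delta1_conditional_cpp(
            as.integer(tP[r, k]), as.integer(n_null)))
        nv <- cache[[key]]
        exc <- length(nv) - findInterval(d1[r, k], nv, left.open = TRUE)
        pmat[r, k] <- (1 + exc) / (1 + length(nv))
      }
    }
  }

  med <- function(m) apply(m, 2, median)
  qlo <- function(m) apply(m, 2, quantile, probs = 0.025, type = 1)
  qhi <- function(m) apply(m, 2, quantile, probs = 0.975, type = 1)
  p_med <- med(pmat)
  cls <- .shift_class(p_med, alpha_inclusive)

  sets <- .clade_tips(tree)
  tips_of <- sets[eligible]
  lab <- vapply(tips_of, function(s)
    sprintf("%s+%d", sort(s)[1], length(s) - 1L), character(1))

  out <- data.frame(
    branch = eligible, clade = lab,
    n_O = med(tO), n_L = med(tL), n_R = med(tR),
    delta1 = med(d1), delta1_low = qlo(d1), delta1_high = qhi(d1),
    p = p_med, p_low = qlo(pmat), p_high = qhi(pmat),
    class = cls, stringsAsFactors = FALSE)
  out <- out[order(-out$delta1), ]
  rownames(out) <- NULL
  attr(out, "branch_tips") <- setNames(tips_of, eligible)
  attr(out, "n_null") <- n_null
  attr(out, "null_mode") <- null_mode
  attr(out, "n_resolutions") <- n_res
  attr(out, "seed") <- seed
  class(out) <- c("shift_report", "data.frame")
  out
}

.shift_class <- function(p, alpha_inclusive = FALSE) {
  sig <- if (alpha_inclusive) p <= 0.05 else p < 0.05
  ifelse(sig, "significant",
         ifelse(p < 0.10, "marginal", "nonsignificant"))
}

#' Count shifts per named clade
#'
#' Assigns each significant or marginal shift to the smallest named clade
#' containing the branch's descendant tip set, and tabulates counts per
#' clade and class.  Clade definitions must be nested or disjoint.
#'
#' @param results a [scan_shifts()] report.
#' @param clades named list of character vectors of tip labels.
#' @return data.frame with columns `clade`, `significant`, `marginal`
#'   (plus an `unassigned` row for shifts inside no named clade).
#' @export
count_sdr <- function(results, clades) {
  stopifnot(inherits(results, "shift_report"), is.list(clades),
            !is.null(names(clades)))
  nm <- names(clades)
  for (a in seq_along(clades)) for (b in seq_along(clades)) {
    if (a >= b) next
    ov <- intersect(clades[[a]], clades[[b]])
    if (length(ov) > 0L &&
        !all(clades[[a]] %in% clades[[b]]) &&
        !all(clades[[b]] %in% clades[[a]]))
      stop("clades '", nm[a], "' and '", nm[b],
           "' overlap without nesting")
  }
  tips <- attr(results, "branch_tips")
  counts <- matrix(0L, length(nm) + 1L, 2,
                   dimnames = list(c(nm, "unassigned"),
                                   c("significant", "marginal")))
  flagged <- results[results$class %in% c("significant", "marginal"), ]
  for (j in seq_len(nrow(flagged))) {
    bt <- tips[[as.character(flagged$branch[j])]]
    containing <- nm[vapply(clades, function(s) all(bt %in% s), logical(1))]
    target <- if (length(containing) == 0L) "unassigned" else {
      containing[which.min(lengths(clades[containing]))]
    }
    counts[target, flagged$class[j]] <- counts[target, flagged$class[j]] + 1L
  }
  data.frame(clade = rownames(counts),
             significant = counts[, 1], marginal = counts[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
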