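#' Colless imbalance index
#'
#' Sum over all internal nodes of the absolute difference between the tip
#' counts of the two child clades.  Ranges from 0 (fully balanced) to
#' `(n-1)(n-2)/2` (caterpillar) for `n` tips.
#'
#' @param tree a strictly bifurcating `phylo`.
#' @return an integer.
#' @export
colless_index <- function(tree) {
  st <- .shape_stats(tree)
  as.integer(st$ic)
}

#' B1 balance index
#'
#' Sum over all non-root internal nodes of the reciprocal of the maximum
#' edge-count path from the node to any of its descendant tips.  Larger
#' values indicate a more balanced tree.
#'
#' @param tree a strictly bifurcating `phylo` with at least 3 tips.
#' @return a positive real.
#' @export
b1_index <- function(tree) {
  if (length(tree$tip.label) < 3L) stop("B1 requires at least 3 tips")
  .shape_stats(tree)$b1
}

#' Nodal ERM log-probability summaries
#'
#' Under the equal-rates Markov (ERM) split law a bifurcating node with
#' `n >= 3` descendant tips splits into unequal parts with probability
#' `2/(n-1)` and into equal halves with probability `1/(n-1)`.  This
#' returns the mean (`MPi`) and the population standard deviation (`Msig`)
#' of the natural-log split probabilities over all internal nodes with at
#' least 3 descendant tips (cherries carry no shape information).  The
#' product of the per-node probabilities is the ERM probability of the
#' whole tree shape.
#'
#' @param tree a strictly bifurcating `phylo` with at least 4 tips.
#' @return named numeric vector `c(MPi = ..., Msig = ...)`; `MPi <= 0`,
#'   `Msig >= 0`.
#' @export
nodal_logprob_stats <- function(tree) {
  if (length(tree$tip.label) < 4L)
    stop("nodal log-probability summaries require at least 4 tips")
  st <- .shape_stats(tree)
  c(MPi = st$mpi, Msig = st$msig)
}

.shape_stats <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  st <- tree_shape_cpp(tree$edge, length(tree$tip.label))
  if (!st$binary)
    stop("tree contains polytomies; resolve them first with resolve_polytomies()")
  st
}

#' Simulate an equal-rates Markov (ERM) tree
#'
#' Grows a labeled topology by iterated uniform random tip splitting: start
#' from a cherry and repeatedly split a uniformly chosen current tip until
#' `n_tips` tips exist.  This is the topology law of the Yule process and
#' the null model for all imbalance and shift tests in this package.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @param labels optional tip labels (default `t1..tn`, assigned in random
#'   order).
#' @return a bifurcating `phylo` with no branch lengths.
#' @export
simulate_erm_tree <- function(n_tips, seed = NULL, labels = NULL) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  .set_seed_if(seed)
  n_all <- 2L * n_tips - 1L
  parent <- integer(n_all)
  parent[2:3] <- 1L
  leaves <- c(2L, 3L)
  next_id <- 3L
  while (length(leaves) < n_tips) {
    idx <- sample.int(length(leaves), 1L)
    x <- leaves[idx]
    y <- next_id + 1L
    z <- next_id + 2L
    next_id <- next_id + 2L
    parent[y] <- x
    parent[z] <- x
    leaves[idx] <- y
    leaves <- c(leaves, z)
  }
  labs <- character(n_all)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_tips))
  labs[leaves] <- sample(labels)
  .phylo_from_parents(parent, labs)$tree
}

#' Exact ERM null distribution of the Colless index
#'
#' Complete enumeration of the equal-rates Markov distribution of IC for
#' small trees, by recursive convolution over the uniform split law.  Used
#' as the independent oracle for the Monte-Carlo null.
#'
#' @param n_tips number of tips (enumeration is exponential-free but meant
#'   for small `n`; guarded at 64).
#' @return data.frame with columns `ic` and `prob` (probabilities sum to 1).
#' @export
erm_ic_distribution <- function(n_tips) {
  stopifnot(n_tips >= 1L, n_tips <= 64L)
  memo <- new.env(parent = emptyenv())
  rec <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n <= 2L) {
      res <- c("0" = 1)
    } else {
      res <- numeric(0)
      for (i in 1:(n - 1L)) {
        dl <- rec(i)
        dr <- rec(n - i)
        w <- 1 / (n - 1)
        for (a in names(dl)) for (b in names(dr)) {
          ic <- as.numeric(a) + as.numeric(b) + abs(n - 2 * i)
          key2 <- as.character(ic)
          res[key2] <- (if (is.na(res[key2])) 0 else res[key2]) +
            w * dl[[a]] * dr[[b]]
        }
      }
    }
    memo[[key]] <- res
    res
  }
  d <- rec(as.integer(n_tips))
  out <- data.frame(ic = as.numeric(names(d)), prob = as.numeric(d))
  out[order(out$ic), ]
}

#' Whole-tree imbalance test against the ERM null
#'
#' Computes the four whole-tree symmetry indices (IC, MPi, Msig, B1) and
#' calibrates each against a Monte-Carlo sample of equal-rates Markov trees
#' of the same size.  Polytomies are treated as soft: the indices are
#' computed on `n_resolutions` random ERM resolutions and reported as
#' low/high quantiles across resolutions, with the matching p-value pair.
#' One shared null sample is used for all resolutions (they all have the
#' same tip count).
#'
#' P-values are one-tailed toward imbalance: the greater tail for IC and
#' Msig, the lesser tail for MPi and B1, with the convention
#' `p = (1 + exceedances) / (1 + n_null)` and ties counted as exceedances.
#'
#' @param tree a `phylo`, possibly polytomous.
#' @param indices subset of `c("IC", "MPi", "Msig", "B1")`.
#' @param n_null number of null trees (>= 100).
#' @param n_resolutions number of random polytomy resolutions (ignored for
#'   binary trees).
#' @param seed optional integer seed.
#' @param probs two quantiles reported across resolutions.
#' @param range if `TRUE`, report min/max across resolutions instead of
#'   quantiles.
#' @return an object of class `imbalance_report`: a list with a `table`
#'   data.frame (`index`, `low`, `high`, `p_low`, `p_high`) and the run
#'   metadata.
#' @export
whole_tree_test <- function(tree, indices = c("IC", "MPi", "Msig", "B1"),
                            n_null = 10000, n_resolutions = 1000,
                            seed = NULL, probs = c(0.025, 0.975),
                            range = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  indices <- match.arg(indices, several.ok = TRUE)
  if (n_null < 100) stop("n_null < 100 gives too coarse a p-value resolution")
  .set_seed_if(seed)
  n <- length(tree$tip.label)

  null <- erm_shape_stats_cpp(n, as.integer(n_null))
  colnames(null) <- c("IC", "MPi", "Msig", "B1")

  binary <- .is_binary(tree)
  n_res <- if (binary) 1L else as.integer(n_resolutions)
  obs <- matrix(NA_real_, n_res, 4,
                dimnames = list(NULL, c("IC", "MPi", "Msig", "B1")))
  for (r in seq_len(n_res)) {
    rt <- if (binary) tree else resolve_polytomies(tree)
    st <- tree_shape_cpp(rt$edge, n)
    obs[r, ] <- c(st$ic, st$mpi, st$msig, st$b1)
  }

  greater <- c(IC = TRUE, MPi = FALSE, Msig = TRUE, B1 = FALSE)
  rows <- lapply(indices, function(ix) {
    nv <- sort(null[, ix])
    ov <- obs[, ix]
    exc <- if (greater[[ix]]) {
      n_null - findInterval(ov, nv, left.open = TRUE)
    } else {
      findInterval(ov, nv)
    }
    pv <- (1 + exc) / (1 + n_null)
    lim <- function(x, lower) {
      if (range) (if (lower) min(x) else max(x))
      else unname(quantile(x, if (lower) probs[1] else probs[2], type = 1))
    }
    data.frame(index = ix,
               low = lim(ov, TRUE), high = lim(ov, FALSE),
               p_low = lim(pv, TRUE), p_high = lim(pv, FALSE),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 n_tips = n, n_null = n_null, n_resolutions = n_res,
                 seed = seed),
            class = "imbalance_report")
}

#' @export
print.imbalance_report <- function(x, ...) {
  cat(sprintf(
    "Whole-tree imbalance test: %d tips, %d ERM null trees, %d resolution(s)\n",
    x$n_tips, x$n_null, x$n_resolutions))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
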