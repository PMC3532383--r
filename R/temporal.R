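#' Assign ages to geological epochs
#'
#' Epochs are half-open on the young side: an age belongs to epoch
#' `[older, younger)`, so a boundary age belongs to the younger epoch; the
#' youngest epoch is closed at 0.
#'
#' @param age numeric vector of ages in Mya.
#' @param epochs an epoch table (see [epoch_table()], [default_epochs()]).
#' @return character vector of epoch names.
#' @export
assign_epoch <- function(age, epochs = default_epochs()) {
  if (any(age < 0)) stop("ages must be >= 0")
  older <- which(age > epochs$start_mya[1])
  if (length(older) > 0L)
    stop("age(s) older than the oldest epoch bound (",
         epochs$start_mya[1], " Mya): ",
         paste(utils::head(age[older], 5), collapse = ", "))
  k <- nrow(epochs)
  out <- character(length(age))
  for (j in seq_len(k)) {
    inside <- age <= epochs$start_mya[j] &
      (if (j == k) age >= epochs$end_mya[j] else age > epochs$end_mya[j])
    out[inside] <- epochs$epoch[j]
  }
  out
}

#' One-way ANOVA with Tukey HSD across groups
#'
#' Standard fixed-effects one-way ANOVA (F with k-1 and N-k degrees of
#' freedom) followed by Tukey honest-significant-difference pairwise
#' comparisons based on the studentized range distribution.  Thin wrapper
#' around [stats::aov()] and [stats::TukeyHSD()] with the degenerate cases
#' handled explicitly.
#'
#' @param groups named list of numeric vectors.
#' @return list with `F`, `df1`, `df2`, `p`, `group_means`, and a `tukey`
#'   data.frame (`pair`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    warning("dropping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  N <- sum(lengths(groups))
  if (N <= k) stop("total sample size must exceed the number of groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  means <- vapply(groups, mean, numeric(1))

  if (stats::var(values) == 0 || isTRUE(all.equal(stats::var(values), 0))) {
    pairs <- utils::combn(names(groups), 2)
    tukey <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                        diff = 0, lwr = 0, upr = 0, p_adj = 1,
                        stringsAsFactors = FALSE)
    return(list(F = 0, df1 = k - 1L, df2 = N - k, p = 1,
                group_means = means, tukey = tukey))
  }

  fit <- aov(values ~ g)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$g
  list(F = sm[["F value"]][1], df1 = sm[["Df"]][1], df2 = sm[["Df"]][2],
       p = sm[["Pr(>F)"]][1], group_means = means,
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Epoch-binned summary of absolute shift statistics
#'
#' Attributes each branch's delta-1 value to a dated node, bins nodes by
#' geological epoch, and compares the per-epoch means of |delta-1| with
#' one-way ANOVA and Tukey HSD.
#'
#' @param tree a dated `phylo` (must carry `node.ages`; see
#'   [parse_newick()] with `ages = "branch-lengths"` or
#'   [simulate_yule_dated()]).
#' @param shifts a [scan_shifts()] report computed on the same tree.
#' @param epochs an epoch table.
#' @param attribute which end of the branch dates the statistic:
#'   `"child"` (the inclusive node, default) or `"parent"`.
#' @param nodes `"eligible"` uses exactly the branches in `shifts`;
#'   `"all-internal"` additionally includes the root, whose statistic is
#'   taken as the nodal shift evidence of its basal split (it has no
#'   outgroup, so no triplet is defined there).
#' @param skip_undated drop nodes without an age (with a message) instead
#'   of failing.
#' @return an object of class `epoch_summary`: list with an `epochs`
#'   data.frame (`epoch`, `n`, `mean_abs_delta1`, `sd`), the `anova`
#'   result, the `tukey` table and `n_total`.
#' @export
epoch_shift_summary <- function(tree, shifts, epochs = default_epochs(),
                                attribute = c("child", "parent"),
                                nodes = c("eligible", "all-internal"),
                                skip_undated = FALSE) {
  stopifnot(inherits(tree, "phylo"), inherits(shifts, "shift_report"))
  attribute <- match.arg(attribute)
  nodes <- match.arg(nodes)
  if (is.null(tree$node.ages))
    stop("tree carries no node ages; parse with ages = 'branch-lengths' ",
         "or simulate a dated tree")
  ages <- tree$node.ages
  parent <- .parents(tree)

  node_id <- if (attribute == "child") shifts$branch else parent[shifts$branch]
  vals <- abs(shifts$delta1)

  if (nodes == "all-internal") {
    root <- .root_of(tree)
    if (!root %in% node_id) {
      st <- .shape_stats(tree)
      tc <- st$tip_counts
      cs <- .children(tree)[[root]]
      root_val <- node_shift_loglr(tc[root], tc[cs[1]])
      node_id <- c(node_id, root)
      vals <- c(vals, abs(root_val))
    }
  }

  undated <- is.na(ages[node_id])
  if (any(undated)) {
    if (!skip_undated)
      stop(sum(undated), " node(s) with a shift statistic have no age; ",
           "set skip_undated = TRUE to drop them")
    message("dropping ", sum(undated), " undated node(s)")
    node_id <- node_id[!undated]
    vals <- vals[!undated]
  }

  ep <- assign_epoch(ages[node_id], epochs)
  ep <- factor(ep, levels = epochs$epoch)
  groups <- split(vals, ep)
  tab <- data.frame(
    epoch = epochs$epoch,
    n = as.integer(lengths(groups)),
    mean_abs_delta1 = vapply(groups, function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1)),
    sd = vapply(groups, function(x)
      if (length(x) > 1) sd(x) else NA_real_, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  nonempty <- groups[lengths(groups) > 0L]
  if (length(nonempty) >= 2L) {
    av <- anova_tukey(nonempty)
    anova <- av[c("F", "df1", "df2", "p")]
    tukey <- av$tukey
  } else {
    message("all dated nodes fall in one epoch; no group comparison run")
    anova <- list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                  p = NA_real_)
    tukey <- NULL
  }
  structure(list(epochs = tab, anova = anova,
                 tukey = tukey, n_total = length(vals)),
            class = "epoch_summary")
}

#' @export
print.epoch_summary <- function(x, ...) {
  print(x$epochs, row.names = FALSE, digits = 4)
  if (!is.na(x$anova$F))
    cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  invisible(x)
}
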