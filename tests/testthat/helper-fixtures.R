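# Shared fixtures, all built in code.

cat4 <- function() parse_newick("(((a,b),c),d);")
bal4 <- function() parse_newick("((a,b),(c,d));")

# caterpillar with n tips
caterpillar <- function(n) {
  nw <- paste0("t", 1L:2L, collapse = ",")
  nw <- paste0("(", nw, ")")
  for (k in seq_len(n - 2L)) nw <- paste0("(", nw, ",t", k + 2L, ")")
  parse_newick(paste0(nw, ";"))
}

# fully balanced tree with 2^k tips
balanced_tree <- function(k) {
  nw <- paste0("t", seq_len(2^k))
  while (length(nw) > 1L)
    nw <- paste0("(", nw[c(TRUE, FALSE)], ",", nw[c(FALSE, TRUE)], ")")
  parse_newick(paste0(nw, ";"))
}

# all unlabeled rooted binary shapes of n tips, as Newick strings with
# distinct tip labels (independent enumeration used as an oracle)
all_shapes_newick <- function(n) {
  memo <- new.env(parent = emptyenv())
  rec <- function(n) {
    if (n == 1L) return("x")
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- character(0)
    for (i in 1:(n %/% 2)) {
      L <- rec(i); R <- rec(n - i)
      for (a in seq_along(L)) for (b in seq_along(R)) {
        if (i == n - i && b < a) next
        out <- c(out, paste0("(", L[a], ",", R[b], ")"))
      }
    }
    memo[[key]] <- out
    out
  }
  vapply(rec(n), function(s) {
    parts <- strsplit(s, "x", fixed = TRUE)[[1]]
    paste0(paste0(parts,
                  c(paste0("t", seq_len(length(parts) - 1L)), ""),
                  collapse = ""), ";")
  }, character(1), USE.NAMES = FALSE)
}

# small taxonomy data.frame builder
toy_taxonomy <- function() {
  data.frame(
    species = c("a1", "a2", "b1", "c1"),
    genus = c("A", "A", "B", "C"),
    tribe = NA_character_, subfamily = NA_character_,
    family = c("F1", "F1", "F1", "F2"),
    clade = c("X", "X", "X", "X"),
    sampled = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}
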