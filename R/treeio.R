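#' Parse a rooted Newick tree
#'
#' Reads a rooted Newick string into an [ape::phylo] object, optionally
#' deriving node ages (in Mya) from branch lengths under the assumption that
#' the tree is ultrametric (all taxa extant, tip ages 0).  Square-bracket
#' comments are accepted and ignored, except for the `[&grafted]` tag that
#' marks tips attached by taxonomic grafting rather than by molecular data;
#' quoted labels are accepted and their internal spaces converted to
#' underscores.
#'
#' @param text a Newick string (must end in `;`).
#' @param ages one of `"none"` (topology only; branch lengths, if any, are
#'   kept but not interpreted) or `"branch-lengths"` (node ages computed as
#'   tree height minus root-to-node path length; ultrametricity is verified
#'   to a relative tolerance of `tol` times the tree height).
#' @param tol relative ultrametricity tolerance.
#'
#' @return A `phylo` object.  When ages are requested it carries a
#'   `node.ages` element (one age per tip and internal node, tips exactly 0).
#'   If any tip carried a `[&grafted]` tag the tree carries an `origin`
#'   element (`"molecular"` or `"grafted"` per tip).
#'
#' @examples
#' tr <- parse_newick("((a:1,b:1):1,c:2);", ages = "branch-lengths")
#' tr$node.ages
#' @export
parse_newick <- function(text, ages = c("none", "branch-lengths"),
                         tol = 1e-6) {
  ages <- match.arg(ages)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)

  # structural pre-check with character offsets
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", k)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of string")
  if (!grepl(";\\s*$", text))
    stop("malformed Newick: missing terminal ';' at character ", nchar(text))

  # grafted tags, then strip all comments
  grafted <- character(0)
  tag_re <- "([^(),:;\\[\\]]+)\\[&grafted\\]"
  tagm <- gregexpr(tag_re, text, perl = TRUE)[[1]]
  if (tagm[1] != -1L) {
    hits <- regmatches(text, gregexpr(tag_re, text, perl = TRUE))[[1]]
    grafted <- sub("\\[&grafted\\]$", "", hits)
  }
  text <- gsub("\\[[^]]*\\]", "", text)

  # quoted labels: unquote, spaces -> underscores
  text <- gsub("'([^']*)'", "\\1", gsub(" ", "_", text))

  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree))
    stop("malformed Newick: ape could not parse the string")
  if (any(tree$tip.label == ""))
    stop("tip labels must be non-empty")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L)
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))

  if (length(grafted) > 0L) {
    origin <- ifelse(tree$tip.label %in% grafted, "grafted", "molecular")
    tree$origin <- origin
  }
  if (ages == "branch-lengths") {
    tree$node.ages <- .ages_from_lengths(tree, tol = tol, context = "input tree")
  }
  tree
}

#' Write a tree as Newick
#'
#' Inverse of [parse_newick()]: emits plain unquoted labels; if node ages are
#' present, branch lengths are written so that re-parsing with
#' `ages = "branch-lengths"` recovers them; grafted tips are tagged with a
#' `[&grafted]` comment.
#'
#' @param tree a `phylo`, optionally with `node.ages` and `origin` elements.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$node.ages)) {
    ages <- tree$node.ages
    tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(tree$origin)) {
    for (lab in tree$tip.label[tree$origin == "grafted"]) {
      pat <- paste0("([(,])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lab),
                    "([,:)])")
      txt <- sub(pat, paste0("\\1", lab, "[&grafted]\\2"), txt)
    }
  }
  txt
}

#' Read a ranked taxonomy table
#'
#' Reads a delimited species list giving, for every recognized species, its
#' genus, optional tribe and subfamily, family and major clade, plus a
#' `sampled` flag saying whether the species has molecular data.  The flag
#' can instead be derived from a set of tree tip labels.
#'
#' @param path path to a TSV/CSV file with a header row (or a data.frame).
#' @param dialect optional named character vector mapping the standard column
#'   names (`species`, `genus`, `tribe`, `subfamily`, `family`, `clade`,
#'   `sampled`) to the names used in the file, absorbing arbitrary source
#'   layouts.
#' @param tip_labels optional character vector of tree tip labels; when
#'   given, `sampled` is defined as membership in this set and any tip label
#'   absent from the species list is reported in a warning and in the
#'   `unknown_tips` attribute (synonym resolution is the caller's problem).
#' @param sep field separator; guessed from the file extension when `NULL`.
#'
#' @return a validated data.frame with columns `species`, `genus`, `tribe`,
#'   `subfamily`, `family`, `clade`, `sampled`.  Rank nesting is enforced:
#'   a genus must map to exactly one family and a family to exactly one
#'   major clade.
#' @export
read_taxonomy <- function(path, dialect = NULL, tip_labels = NULL, sep = NULL) {
  if (is.data.frame(path)) {
    raw <- path
  } else {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  std <- c("species", "genus", "tribe", "subfamily", "family", "clade",
           "sampled")
  cols <- setNames(std, std)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  need <- c("species", "genus", "family", "clade")
  missing_cols <- need[!cols[need] %in% names(raw)]
  if (length(missing_cols) > 0L)
    stop("taxonomy is missing required column(s): ",
         paste(cols[missing_cols], collapse = ", "))
  tab <- data.frame(
    species = gsub(" ", "_", as.character(raw[[cols["species"]]])),
    genus = as.character(raw[[cols["genus"]]]),
    tribe = if (cols["tribe"] %in% names(raw))
      as.character(raw[[cols["tribe"]]]) else NA_character_,
    subfamily = if (cols["subfamily"] %in% names(raw))
      as.character(raw[[cols["subfamily"]]]) else NA_character_,
    family = as.character(raw[[cols["family"]]]),
    clade = as.character(raw[[cols["clade"]]]),
    stringsAsFactors = FALSE
  )
  tab$tribe[!is.na(tab$tribe) & tab$tribe == ""] <- NA_character_
  tab$subfamily[!is.na(tab$subfamily) & tab$subfamily == ""] <- NA_character_

  if (!is.null(tip_labels)) {
    tip_labels <- gsub(" ", "_", tip_labels)
    tab$sampled <- tab$species %in% tip_labels
    unknown <- setdiff(tip_labels, tab$species)
    if (length(unknown) > 0L) {
      warning(length(unknown),
              " tip label(s) not found in the species list: ",
              paste(utils::head(unknown, 5), collapse = ", "),
              if (length(unknown) > 5) ", ..." else "")
      attr(tab, "unknown_tips") <- unknown
    }
  } else if (cols["sampled"] %in% names(raw)) {
    s <- raw[[cols["sampled"]]]
    tab$sampled <- if (is.logical(s)) s else
      tolower(as.character(s)) %in% c("1", "true", "yes", "y")
  } else {
    stop("provide a 'sampled' column or a tip_labels set")
  }
  validate_taxonomy(tab)
}

#' Validate a taxonomy table
#'
#' Checks species uniqueness, required ranks and strict rank nesting.
#' Called by [read_taxonomy()]; exported so programmatically built tables
#' can be validated the same way.
#'
#' @param tab data.frame with the standard taxonomy columns.
#' @return the table, invisibly unchanged, or an error.
#' @export
validate_taxonomy <- function(tab) {
  need <- c("species", "genus", "family", "clade", "sampled")
  if (!all(need %in% names(tab)))
    stop("taxonomy must have columns ", paste(need, collapse = ", "))
  dup <- tab$species[duplicated(tab$species)]
  if (length(dup) > 0L)
    stop("duplicate species: ", paste(unique(dup), collapse = ", "))
  for (col in c("species", "genus", "family", "clade")) {
    if (any(is.na(tab[[col]]) | tab[[col]] == ""))
      stop("missing values in required rank '", col, "'")
  }
  .check_nesting <- function(child, parent, cn, pn) {
    m <- unique(data.frame(c = child, p = parent, stringsAsFactors = FALSE))
    m <- m[!is.na(m$c), ]
    bad <- unique(m$c[duplicated(m$c)])
    if (length(bad) > 0L) {
      pairs <- m[m$c %in% bad, ]
      stop("rank nesting violated: ", cn, " mapping to multiple ", pn, "s: ",
           paste(paste0(pairs$c, "->", pairs$p), collapse = ", "))
    }
  }
  .check_nesting(tab$genus, tab$family, "genus", "family")
  .check_nesting(tab$family, tab$clade, "family", "clade")
  .check_nesting(tab$tribe, tab$family, "tribe", "family")
  .check_nesting(tab$subfamily, tab$family, "subfamily", "family")
  if (!is.logical(tab$sampled)) stop("'sampled' must be logical")
  invisible(tab)
}

#' Geological epoch table
#'
#' Constructs and validates an ordered epoch table: epochs must be
#' contiguous, non-overlapping and run from the oldest bound down to the
#' present (youngest bound 0 Mya).
#'
#' @param epoch character vector of epoch names, oldest first.
#' @param start_mya older bound of each epoch (Mya).
#' @param end_mya younger bound of each epoch (Mya).
#' @return a validated data.frame.
#' @export
epoch_table <- function(epoch, start_mya, end_mya) {
  tab <- data.frame(epoch = as.character(epoch),
                    start_mya = as.numeric(start_mya),
                    end_mya = as.numeric(end_mya),
                    stringsAsFactors = FALSE)
  if (any(tab$start_mya <= tab$end_mya))
    stop("each epoch must have start_mya > end_mya")
  k <- nrow(tab)
  if (k > 1L && any(abs(tab$end_mya[-k] - tab$start_mya[-1]) > 1e-9))
    stop("epochs must be contiguous (end of one = start of the next)")
  if (tab$end_mya[k] != 0)
    stop("the youngest epoch must end at 0 Mya")
  tab
}

#' Read an epoch table from TSV
#'
#' @param path TSV file with columns `epoch`, `start_mya`, `end_mya`.
#' @return a validated epoch table.
#' @export
read_epochs <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  epoch_table(raw$epoch, raw$start_mya, raw$end_mya)
}

#' Cenozoic epochs from the Paleocene to the Quaternary
#'
#' The six-epoch binning used for the temporal analysis: Paleocene
#' (65.5-55.8 Mya), Eocene (55.8-33.9), Oligocene (33.9-23.03), Miocene
#' (23.03-5.3), Pliocene (5.3-1.8) and Quaternary (1.8-0).  The
#' Oligocene/Miocene limit is taken as 23.03 Mya on both sides.
#'
#' @return an epoch table.
#' @export
default_epochs <- function() {
  epoch_table(
    epoch = c("Paleocene", "Eocene", "Oligocene", "Miocene", "Pliocene",
              "Quaternary"),
    start_mya = c(65.5, 55.8, 33.9, 23.03, 5.3, 1.8),
    end_mya = c(55.8, 33.9, 23.03, 5.3, 1.8, 0)
  )
}
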