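# Tree representation and operations. Trees are ape "phylo" objects throughout;
# this module adds validated Newick I/O, random tree generation with
# configurable branch-length distributions, patristic distance matrices
# (optionally including internal nodes), and induced-subtree sampling for
# bagging.

#' Node identifiers of a phylogeny
#'
#' Tips are identified by their labels; internal nodes by `"node<k>"` where
#' `k` is the ape node number (`n_tips + 1` is the root). These ids index all
#' distance and covariance matrices produced by the package.
#'
#' @param tree A `phylo` object.
#' @return Character vector of length `n_tips + n_internal`, tips first.
#' @export
node_ids <- function(tree) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  c(tree$tip.label, paste0("node", (n + 1):(n + tree$Nnode)))
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("expected a 'phylo' tree")
  n <- length(tree$tip.label)
  if (n < 2) stopf("tree must have at least 2 tips, got %d", n)
  if (anyDuplicated(tree$tip.label)) stopf("tip labels must be unique")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stopf("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stopf("branch lengths must be non-negative")
  invisible(tree)
}

#' Read a rooted Newick tree
#'
#' Parses a Newick string (or file) into an `ape::phylo` tree and validates it:
#' unique tip labels, at least two tips, non-negative branch lengths on every
#' edge. Missing branch lengths are an error unless `default_branch_length`
#' is supplied. Structural errors (unbalanced parentheses, missing terminal
#' semicolon) are reported with the offending character position.
#'
#' @param text Newick string. Exactly one of `text`/`file` must be given.
#' @param file Path to a Newick file.
#' @param default_branch_length Optional branch length substituted where the
#'   Newick string omits one.
#' @return A validated `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL, default_branch_length = NULL) {
  if (is.null(text) == is.null(file)) stopf("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("Newick parse error: unmatched ')' at character %d", i)
    }
  }
  if (depth != 0L)
    stopf("Newick parse error: %d unclosed '(' at character %d", depth, length(chars))
  if (!grepl(";\\s*$", text))
    stopf("Newick parse error: missing terminal ';' at character %d", nchar(text))

  tree <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stopf("Newick parse error: string could not be parsed as a tree")

  if (is.null(tree$edge.length)) {
    if (is.null(default_branch_length))
      stopf("Newick string has no branch lengths and no default was configured")
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (is.null(default_branch_length))
      stopf("Newick string has missing branch lengths and no default was configured")
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  validate_tree(tree)
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Branch-length distribution specifications
#'
#' `random_tree()` draws i.i.d. branch lengths from a named distribution:
#' `list(name = "lognormal", meanlog =, sdlog =)`,
#' `list(name = "exponential", rate =)` or `list(name = "fixed", length =)`.
#' The default lognormal (meanlog -2.5, sdlog 0.8; mean about 0.11 with a heavy
#' right tail) is shaped like branch lengths of typical gene-family trees.
#'
#' @return The default branch-length specification list.
#' @export
default_branch_dist <- function() list(name = "lognormal", meanlog = -2.5, sdlog = 0.8)

draw_branch_lengths <- function(spec, n) {
  if (is.null(spec$name)) stopf("branch_dist must have a 'name' field")
  switch(spec$name,
    lognormal   = stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    exponential = stats::rexp(n, rate = spec$rate),
    fixed       = rep(spec$length, n),
    stopf("unsupported branch-length distribution '%s'", spec$name))
}

#' Generate a random phylogeny
#'
#' Topology from a Yule (pure-birth) process; branch lengths replaced by
#' i.i.d. draws from `branch_dist`. Reproducible for a fixed seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param branch_dist Branch-length specification, see [default_branch_dist()].
#' @param seed Optional integer seed.
#' @return A `phylo` tree with tips labelled `t1 ... t<n_tips>`.
#' @export
random_tree <- function(n_tips, branch_dist = default_branch_dist(), seed = NULL) {
  if (!is_scalar_number(n_tips) || n_tips < 2) stopf("n_tips must be >= 2")
  set_seed_if(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- draw_branch_lengths(branch_dist, nrow(tree$edge))
  tree$tip.label <- paste0("t", seq_len(n_tips))
  validate_tree(tree)
}

#' Patristic distance matrix
#'
#' Path lengths in the tree between all pairs of tips, or between all nodes
#' (tips and internal) when `include_internal = TRUE`. Rows/columns are named
#' by [node_ids()].
#'
#' @param tree A `phylo` object.
#' @param include_internal Include internal nodes?
#' @return Symmetric non-negative matrix with zero diagonal.
#' @export
patristic <- function(tree, include_internal = FALSE) {
  validate_tree(tree)
  if (include_internal) {
    D <- ape::dist.nodes(tree)
    ids <- node_ids(tree)
    dimnames(D) <- list(ids, ids)
  } else {
    n <- length(tree$tip.label)
    D <- ape::dist.nodes(tree)[seq_len(n), seq_len(n), drop = FALSE]
    dimnames(D) <- list(tree$tip.label, tree$tip.label)
  }
  D
}

#' Maximum tip-to-tip patristic distance
#'
#' @param tree A `phylo` object.
#' @return The largest patristic distance between two tips.
#' @export
tree_l_max <- function(tree) max(patristic(tree))

#' Rescale a tree to a given maximum tip-to-tip distance
#'
#' Multiplies every branch length by a common factor so that the maximum
#' patristic distance between tips equals `l_max`.
#'
#' @param tree A `phylo` object.
#' @param l_max Target maximum patristic distance (> 0).
#' @return The rescaled tree.
#' @export
rescale_tree <- function(tree, l_max) {
  validate_tree(tree)
  if (!is_scalar_number(l_max) || l_max <= 0) stopf("l_max must be > 0")
  cur <- tree_l_max(tree)
  if (cur <= 0) stopf("tree has zero depth; cannot rescale")
  tree$edge.length <- tree$edge.length * (l_max / cur)
  tree
}

#' Sample an induced subtree
#'
#' Draws `k` tips uniformly without replacement and returns the induced
#' subtree. Degree-2 internal nodes are suppressed with branch lengths summed,
#' so patristic distances among the retained tips are preserved exactly.
#'
#' @param tree A `phylo` object.
#' @param k Number of tips to retain (2 <= k <= n_tips).
#' @param seed Optional integer seed.
#' @return A `phylo` tree on the sampled tips.
#' @export
sample_subtree <- function(tree, k, seed = NULL) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (!is_scalar_number(k) || k < 2 || k > n)
    stopf("k must be between 2 and the number of tips (%d), got %s", n, format(k))
  set_seed_if(seed)
  keep <- sample(tree$tip.label, k)
  ape::keep.tip(tree, keep)
}
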