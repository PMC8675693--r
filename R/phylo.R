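#' Pairwise site-difference matrix
#'
#' Raw count of differing sites for every sequence pair; sites with `N` in
#' either sequence are excluded from that pair's comparison.
#'
#' @param alleles Character matrix (sequences x sites), rows named.
#' @return List of class `diff_matrix`: `differences` (integer matrix),
#'   `compared` (per-pair count of compared sites).
#' @export
pairwise_difference_matrix <- function(alleles) {
  n <- nrow(alleles)
  labs <- rownames(alleles)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  d <- matrix(0L, n, n, dimnames = list(labs, labs))
  cmp <- matrix(ncol(alleles), n, n, dimnames = list(labs, labs))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      a <- alleles[i, ]
      for (j in (i + 1):n) {
        b <- alleles[j, ]
        ok <- a != "N" & b != "N"
        d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
        cmp[i, j] <- cmp[j, i] <- sum(ok)
      }
    }
  }
  structure(list(differences = d, compared = cmp), class = "diff_matrix")
}

#' @export
print.diff_matrix <- function(x, ...) {
  cat(sprintf("<diff_matrix> %d sequences\n", nrow(x$differences)))
  print(x$differences)
  invisible(x)
}

#' Tidy a difference matrix into pair rows
#'
#' @param x A `diff_matrix`.
#' @param ... Unused.
#' @return Tibble: `seq_a`, `seq_b`, `differences`, `compared_sites`
#'   (upper triangle only).
#' @export
tidy.diff_matrix <- function(x, ...) {
  labs <- rownames(x$differences)
  ij <- which(upper.tri(x$differences), arr.ind = TRUE)
  tibble::tibble(seq_a = labs[ij[, 1]], seq_b = labs[ij[, 2]],
                 differences = x$differences[ij],
                 compared_sites = x$compared[ij])
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of differing sites, `0 <= p < 0.75`.
#' @return Corrected distance `-(3/4) * log(1 - 4p/3)` (substitutions per
#'   site).
#' @export
jukes_cantor_distance <- function(p) {
  if (any(p < 0) | any(p >= 0.75)) {
    stop("saturated: require 0 <= p < 0.75", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Neighbor-joining tree from a difference matrix
#'
#' Standard NJ agglomeration on raw site differences or Jukes-Cantor
#' corrected distances. Negative branch lengths (an NJ artifact) are
#' clamped to zero and the clamped total recorded.
#'
#' @param d A `diff_matrix` from [pairwise_difference_matrix()], or a
#'   numeric distance matrix / `dist`.
#' @param correction `"none"` for raw counts, `"JC"` for Jukes-Cantor
#'   (applied to per-site proportions).
#' @return An [ape::phylo] (unrooted). Attribute `"clamped"` gives the
#'   total negative branch length set to zero.
#' @export
nj_tree <- function(d, correction = c("none", "JC")) {
  correction <- match.arg(correction)
  if (inherits(d, "diff_matrix")) {
    m <- if (correction == "JC") {
      jukes_cantor_distance(d$differences / d$compared)
    } else {
      d$differences
    }
  } else {
    m <- as.matrix(d)
    if (correction == "JC") m <- jukes_cantor_distance(m)
  }
  if (nrow(m) < 3L) stop("need >= 3 taxa", call. = FALSE)
  tree <- ape::nj(stats::as.dist(m))
  clamped <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Root a tree on an outgroup's pendant edge
#'
#' @param tree An [ape::phylo].
#' @param outgroup Leaf label of the outgroup sequence (e.g. chimpanzee).
#' @return Rooted [ape::phylo].
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup not among tips", call. = FALSE)
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# Canonical bipartition keys of a tree's internal edges: for each internal
# edge, the tip set on the far side of the first tip, sorted and collapsed.
bipartition_keys <- function(tree) {
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  n <- length(labs)
  keys <- vapply(parts, function(idx) {
    side <- labs[idx]
    if (labs[1] %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  # drop trivial partitions (all tips / single tip)
  sizes <- lengths(parts)
  unique(keys[sizes > 1 & sizes < n - 1])
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Site columns are resampled with replacement `n_reps` times; support for
#' each internal bipartition of the full-data tree is the percentage of
#' replicate trees containing it.
#'
#' @param alleles Character matrix (sequences x sites).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (reproducible supports).
#' @param correction Passed to [nj_tree()].
#' @return The full-data [nj_tree()] with `node.label` holding supports
#'   (internal nodes, percent) and attribute `"support"` as a tibble.
#' @export
bootstrap_support <- function(alleles, n_reps = 1000, seed = 1,
                              correction = c("none", "JC")) {
  correction <- match.arg(correction)
  stopifnot(n_reps >= 1)
  full <- nj_tree(pairwise_difference_matrix(alleles), correction)
  keys <- bipartition_keys(full)
  hits <- stats::setNames(numeric(length(keys)), keys)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(alleles), replace = TRUE)
    rep_tree <- nj_tree(pairwise_difference_matrix(
      alleles[, cols, drop = FALSE]), correction)
    rep_keys <- bipartition_keys(rep_tree)
    hits[keys %in% rep_keys] <- hits[keys %in% rep_keys] + 1
  }
  support <- 100 * hits / n_reps
  full <- label_internal_support(full, support)
  attr(full, "support") <- tibble::tibble(bipartition = keys,
                                          support = unname(support))
  full
}

# Attach supports (named by bipartition key) as internal node labels.
label_internal_support <- function(tree, support) {
  n_tip <- length(tree$tip.label)
  labs <- character(tree$Nnode)
  for (node in seq_len(tree$Nnode) + n_tip) {
    tips <- tree$tip.label[unlist(phangorn_descendants(tree, node))]
    side <- tips
    if (tree$tip.label[1] %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labs[node - n_tip] <- format(round(support[[key]], 1))
    }
  }
  tree$node.label <- labs
  tree
}

# Tip indices descending from a node (small trees; simple recursion).
phangorn_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_descendants, tree = tree))
}

#' Write a tree in newick format
#'
#' Branch lengths are kept; bootstrap supports (if present) are written as
#' internal node labels.
#'
#' @param tree An [ape::phylo].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("empty or invalid tree", call. = FALSE)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
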