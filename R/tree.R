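#' Read and validate a rooted newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: a single rooted tree, unique tip labels,
#' and finite non-negative branch lengths. Branch lengths absent from the
#' newick string are read as 0 with a warning.
#'
#' @param text a newick string (single tree, ';'-terminated). Exactly one of
#'   `text`/`file` must be given.
#' @param file path to a newick file containing one tree.
#' @return an object of class `phylo`.
#' @export
read_tree_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  if (!nzchar(text)) stop("empty newick input", call. = FALSE)
  if (!grepl(";\\s*$", text)) stop("newick string must end with ';'", call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed newick: ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed newick: could not parse a tree", call. = FALSE)
  validate_tree(tree, fix_lengths = TRUE)
}

validate_tree <- function(tree, fix_lengths = FALSE) {
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (!fix_lengths) stop("tree has no branch lengths", call. = FALSE)
    warning("newick has no branch lengths; all set to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length) || any(is.nan(tree$edge.length))) {
    if (!fix_lengths) stop("tree has missing branch lengths", call. = FALSE)
    warning("missing branch lengths read as 0", call. = FALSE)
    tree$edge.length[!is.finite(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tree
}

#' Write a tree as newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; when NULL the newick string is returned.
#' @return the newick string (invisibly when written to file).
#' @export
write_tree_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Patristic distance matrix
#'
#' Pairwise path-length (sum of branch lengths) distances between tips,
#' the d(i,j) underlying MPD and MNTD.
#'
#' @param tree a `phylo` object.
#' @param taxa optional character vector of tip labels; the matrix is
#'   returned in this order. Default: all tips in tree order.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
patristic <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "phylo"))
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(taxa)) {
    missing <- setdiff(taxa, rownames(d))
    if (length(missing))
      stop("unknown taxa: ", paste(missing, collapse = ", "), call. = FALSE)
    d <- d[taxa, taxa, drop = FALSE]
  }
  d
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels (length >= 1). For a single
#'   tip the tip's own node number is returned.
#' @return a node number in `tree`'s numbering.
#' @export
tree_mrca <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip labels: ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# Distance from the root to every node (tips first, then internals).
node_depths <- function(tree) ape::node.depth.edgelength(tree)

# Height of a node above its descendant tips: mean root-to-tip depth of the
# tips under `node`, minus the node's own depth. For an ultrametric tree the
# mean is exact for every descendant tip.
node_height <- function(tree, node) {
  depths <- node_depths(tree)
  if (node <= ape::Ntip(tree)) return(0)
  desc <- tips_below(tree, node)
  mean(depths[desc]) - depths[node]
}

# Tip indices descending from a node (the node itself if it is a tip).
tips_below <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    n <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- children[[as.character(n)]]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' Test whether a tree is ultrametric within an absolute tolerance
#'
#' All root-to-tip path lengths must agree within `tol` (absolute, in
#' branch-length units), unlike [ape::is.ultrametric()]'s relative criterion.
#'
#' @param tree a `phylo` object.
#' @param tol nonnegative absolute tolerance.
#' @return logical flag.
#' @export
is_ultrametric_abs <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"), tol >= 0)
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  (max(d) - min(d)) <= tol
}

genus_of <- function(labels) sub("_.*$", "", labels)

# Largest monophyletic cluster of a genus: among maximal clades whose tips all
# belong to the genus, the one with most tips; ties broken by the shallower
# (closer to the root) crown node. Returns the crown node number (a tip node
# if the largest cluster is a single tip).
largest_genus_cluster <- function(tree, genus_tips) {
  ntip <- ape::Ntip(tree)
  idx <- match(genus_tips, tree$tip.label)
  if (length(idx) == 1L) return(idx)
  in_genus <- logical(ntip); in_genus[idx] <- TRUE
  depths <- node_depths(tree)
  best_node <- idx[1]; best_size <- 1L; best_depth <- depths[idx[1]]
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    tips <- tips_below(tree, node)
    if (!all(in_genus[tips])) next
    size <- length(tips)
    if (size > best_size ||
        (size == best_size && depths[node] < best_depth)) {
      best_node <- node; best_size <- size; best_depth <- depths[node]
    }
  }
  best_node
}

#' Graft a missing species onto a backbone phylogeny
#'
#' Attaches a species absent from the backbone at its genus (or, failing
#' that, a supplied family node), mirroring the mega-tree practice of adding
#' unplaced taxa as genus-level polytomies while preserving ultrametricity:
#'
#' * genus with >= 2 tips: the new tip becomes an additional child of the
#'   crown node of the genus' largest monophyletic cluster, with pendant
#'   length equal to that node's height;
#' * genus with exactly 1 tip: the pendant branch of that tip is bisected at
#'   its midpoint and the new tip attached there with the remaining
#'   half-height;
#' * genus absent: the new tip is attached at `family_node` by the polytomy
#'   rule (an error if no family node is supplied).
#'
#' Distances among pre-existing tips are never altered.
#'
#' @param tree a `phylo` backbone (ultrametric for the height arithmetic to
#'   preserve ultrametricity).
#' @param new_species tip label to add, conventionally "Genus_epithet".
#' @param genus genus name; default: the prefix of `new_species` before the
#'   first underscore.
#' @param genus_map optional named list mapping genus name -> character
#'   vector of backbone tip labels, overriding prefix matching.
#' @param family_node node number used when the genus has no backbone tips.
#' @return the enlarged `phylo` tree.
#' @export
graft_tip <- function(tree, new_species, genus = NULL, genus_map = NULL,
                      family_node = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (new_species %in% tree$tip.label)
    stop("'", new_species, "' is already a tip", call. = FALSE)
  if (is.null(genus)) genus <- genus_of(new_species)
  gtips <- if (!is.null(genus_map)) intersect(genus_map[[genus]], tree$tip.label)
           else tree$tip.label[genus_of(tree$tip.label) == genus]

  if (length(gtips) == 0L) {
    if (is.null(family_node))
      stop("genus '", genus, "' absent from backbone and no family node supplied",
           call. = FALSE)
    msg("graft_tip: genus '", genus, "' absent; attaching '", new_species,
        "' at supplied family node ", family_node)
    h <- node_height(tree, family_node)
    return(phytools::bind.tip(tree, new_species, edge.length = h,
                              where = family_node, position = 0))
  }

  node <- largest_genus_cluster(tree, gtips)
  ntip <- ape::Ntip(tree)
  if (node <= ntip) {
    # single-tip cluster: bisect the pendant branch at its midpoint
    edge_i <- which(tree$edge[, 2] == node)
    b <- tree$edge.length[edge_i]
    return(phytools::bind.tip(tree, new_species, edge.length = b / 2,
                              where = node, position = b / 2))
  }
  h <- node_height(tree, node)
  phytools::bind.tip(tree, new_species, edge.length = h,
                     where = node, position = 0)
}
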