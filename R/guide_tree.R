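# Rooted guide trees: reading, clade checks, and extraction of
# speciation-event nodes for the tree-based congruence metrics.

#' Wrap a rooted tree as a guide tree
#'
#' A guide tree is a rooted tree whose leaves are the specimen universe; a
#' taxonomy whose species are clades of the tree supports one speciation
#' event per internal node above the species level. Node identity is
#' topological (the leaf set below the node), so newick rotations of the
#' same topology yield identical event sets.
#'
#' @param phy an [ape::phylo] object (rooted; leaf labels unique).
#' @return an object of class `guide_tree` wrapping the `phylo`.
#' @seealso [read_newick()], [extract_event_nodes()]
#' @export
guide_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("'phy' must be an ape phylo tree",
                                    call. = FALSE)
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (!ape::is.rooted(phy))
    stop("guide tree must be rooted", call. = FALSE)
  structure(list(phy = phy), class = "guide_tree")
}

#' Read a guide tree from a newick file
#'
#' Reads a single rooted newick tree. Branch lengths, if present, are kept
#' but unused: the event metrics depend on topology only.
#'
#' @param path path to a newick file containing one tree.
#' @return a `guide_tree`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  phy <- tryCatch(suppressWarnings(ape::read.tree(path)),
                  error = function(e) stop("unreadable newick in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (is.null(phy)) stop("unreadable newick in '", path, "'", call. = FALSE)
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("expected a single tree in '", path, "', found ", length(phy),
           call. = FALSE)
    phy <- phy[[1L]]
  }
  guide_tree(phy)
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("Guide tree: ", length(x$phy$tip.label), " leaves, ", x$phy$Nnode,
      " internal nodes", if (ape::is.binary(x$phy)) ", binary" else
        ", with polytomies", "\n", sep = "")
  invisible(x)
}

# named list: for every node (tips included), the sorted leaf labels below
# it; names are node numbers. Computed once per call site.
clade_leafsets <- function(gt) {
  phy <- gt$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- phy$tip.label[i]
  # postorder guarantees children are filled before their parent
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (j in seq_len(nrow(edge))) {
    par <- edge[j, 1L]; chi <- edge[j, 2L]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  lapply(sets, sort)
}

check_same_leafset <- function(p, gt) {
  tips <- gt$phy$tip.label
  if (!setequal(tips, p$universe))
    stop("leaf set of the guide tree differs from the specimen universe; ",
         "only in tree: {", paste(setdiff(tips, p$universe), collapse = ", "),
         "}; only in partition: {",
         paste(setdiff(p$universe, tips), collapse = ", "), "}",
         call. = FALSE)
}

#' Check that every species of a partition is a clade of a guide tree
#'
#' Tree-based event extraction requires each species to be exactly the leaf
#' set of one tree node (monophyly on the guide tree); single-specimen
#' species qualify via their leaf.
#'
#' @param p a `species_partition`.
#' @param tree a `guide_tree` whose leaf set equals the partition's
#'   universe.
#' @return `TRUE`, or `FALSE` with attribute `"witness"` naming the first
#'   non-clade species and its specimens.
#' @export
check_clade_partition <- function(p, tree) {
  stopifnot(inherits(p, "species_partition"), inherits(tree, "guide_tree"))
  check_same_leafset(p, tree)
  keys <- vapply(clade_leafsets(tree), set_key, character(1))
  for (cl in clusters(p)) {
    if (!(set_key(cl) %in% keys)) {
      res <- FALSE
      lab <- p$assignment[cl[1L]]
      attr(res, "witness") <- list(label = unname(lab), cluster = cl)
      return(res)
    }
  }
  TRUE
}

#' Extract the speciation-event nodes supported by a taxonomy
#'
#' On a binary guide tree whose clades include every species of the
#' partition, the speciation events supported by the taxonomy are the
#' internal nodes above the species level: the nodes whose subtended leaf
#' set is a disjoint union of two or more complete species. A partition with
#' k species always yields exactly k - 1 such nodes.
#'
#' Polytomous trees are refused: the k - 1 identity presumes a dichotomous
#' species tree, and no event-sharing semantics is defined for polytomies.
#' Use the tree-free mode for such data.
#'
#' @param p a `species_partition` whose species are clades of `tree`.
#' @param tree a binary `guide_tree`.
#' @return an object of class `event_set`: a character vector of canonical
#'   node identifiers (the sorted leaf labels of each event clade, comma
#'   joined), with attribute `method`.
#' @examples
#' gt <- guide_tree(ape::read.tree(text = "((a,b),(c,d));"))
#' p <- species_partition(c(a = "1", b = "1", c = "2", d = "3"), "m")
#' extract_event_nodes(p, gt)   # the root and the (c,d) ancestor
#' @export
extract_event_nodes <- function(p, tree) {
  stopifnot(inherits(p, "species_partition"), inherits(tree, "guide_tree"))
  check_same_leafset(p, tree)
  if (!ape::is.binary(tree$phy))
    stop("guide tree has polytomies: event extraction requires a strictly ",
         "bifurcating tree; use the tree-free mode instead", call. = FALSE)
  ok <- check_clade_partition(p, tree)
  if (!isTRUE(ok)) {
    w <- attr(ok, "witness")
    stop("species '", w$label, "' {", paste(w$cluster, collapse = ", "),
         "} is not a clade of the guide tree; use the tree-free mode ",
         "for non-clade taxonomies", call. = FALSE)
  }
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  sets <- clade_leafsets(tree)
  cl <- clusters(p)
  sizes <- stats::setNames(lengths(cl), names(cl))
  nodes <- character(0)
  for (v in (ntip + 1L):(ntip + phy$Nnode)) {
    leaves <- sets[[v]]
    sp <- unique(p$assignment[leaves])
    # v is above the species level iff all its species lie entirely below it
    if (length(sp) >= 2L && sum(sizes[sp]) == length(leaves))
      nodes <- c(nodes, set_key(leaves))
  }
  nodes <- sort(nodes)
  if (length(nodes) != n_events(p))
    stop("internal error: extracted ", length(nodes),
         " event nodes but partition supports ", n_events(p))
  structure(nodes, class = "event_set", method = p$method)
}

#' @export
print.event_set <- function(x, ...) {
  cat("Event set for '", attr(x, "method"), "': ", length(x),
      " speciation event(s)\n", sep = "")
  if (length(x)) cat(paste0("  {", unclass(x), "}"), sep = "\n")
  invisible(x)
}
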