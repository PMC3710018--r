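# Seeded generators: random guide trees, nested clade taxonomies,
# specimen inflation, and species-structured haplotype tables. All are
# pure functions of their inputs and the seed (caller RNG state is left
# untouched).

#' Generate a random rooted binary guide tree
#'
#' Iterative random pair-joining: starting from the leaves, two random
#' lineages are joined until one root remains. Branch lengths are not
#' simulated -- the event metrics are topology-only.
#'
#' @param n_specimens number of leaves (>= 2).
#' @param seed integer seed; identical seeds give byte-identical trees.
#' @param labels optional leaf labels (default `t1 ... tn`).
#' @return a `guide_tree`.
#' @export
generate_guide_tree <- function(n_specimens, seed = 1, labels = NULL) {
  stopifnot(n_specimens >= 2)
  labels <- labels %||% paste0("t", seq_len(n_specimens))
  stopifnot(length(labels) == n_specimens)
  with_seed(seed, {
    frags <- as.list(labels)
    while (length(frags) > 1L) {
      i <- sample.int(length(frags), 2L)
      joined <- paste0("(", frags[[i[1L]]], ",", frags[[i[2L]]], ")")
      frags <- c(frags[-i], joined)
    }
    guide_tree(ape::read.tree(text = paste0(frags[[1L]], ";")))
  })
}

#' Generate nested clade taxonomies on a guide tree
#'
#' For each requested species count k, grows a clade partition by random
#' refinement from the root: starting from the one-species partition, a
#' random current species with more than one specimen is split at the root
#' node of its subtree, k - 1 times. All species are therefore clades of
#' the tree, so every pair of generated partitions is laminar. With
#' `chain = TRUE` (default) each partition continues refining the previous
#' one, so the collection is a nested chain.
#'
#' @param tree a binary `guide_tree`.
#' @param species_counts integer vector of target species numbers, each
#'   between 1 and the leaf count.
#' @param seed integer seed.
#' @param chain make each partition a refinement of the previous one.
#' @param methods optional method names (default `m1 ... mn`).
#' @return a `taxonomy_collection`.
#' @export
generate_nested_taxonomies <- function(tree, species_counts, seed = 1,
                                       chain = TRUE, methods = NULL) {
  stopifnot(inherits(tree, "guide_tree"))
  phy <- tree$phy
  if (!ape::is.binary(phy))
    stop("clade-partition generation requires a binary tree", call. = FALSE)
  ntip <- length(phy$tip.label)
  bad <- species_counts[species_counts < 1 | species_counts > ntip]
  if (length(bad))
    stop("impossible species count(s) for a ", ntip, "-leaf tree: ",
         paste(bad, collapse = ", "), call. = FALSE)
  methods <- methods %||% paste0("m", seq_along(species_counts))
  sets <- clade_leafsets(tree)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  root <- ntip + 1L
  with_seed(seed, {
    parts <- vector("list", length(species_counts))
    # current partition as a list of subtree root nodes
    nodes <- root
    refine_to <- function(nodes, k) {
      while (length(nodes) < k) {
        splittable <- nodes[nodes > ntip]
        v <- if (length(splittable) == 1L) splittable else
          sample(splittable, 1L)
        nodes <- c(setdiff(nodes, v), children[[as.character(v)]])
      }
      nodes
    }
    ord <- if (chain) order(species_counts) else seq_along(species_counts)
    for (i in ord) {
      if (!chain) nodes <- root
      nodes <- refine_to(nodes, species_counts[i])
      lab <- character(ntip)
      names(lab) <- phy$tip.label
      for (j in seq_along(nodes))
        lab[sets[[nodes[j]]]] <- paste0("sp", j)
      parts[[i]] <- species_partition(lab[phy$tip.label],
                                      method = methods[i])
    }
    taxonomy_collection(parts)
  })
}

#' Inflate specimen numbers within species
#'
#' Replicates every specimen within its species, consistently across all
#' methods, producing new unique ids with a `#n` suffix so provenance stays
#' auditable. Species counts -- and hence all Ctax and Rtax values -- are
#' unchanged by construction; pair-counting indices like the Rand index are
#' not invariant under such inflation, which is exactly the bias the event
#' metrics avoid.
#'
#' @param x a `taxonomy_collection`.
#' @param factor integer >= 1: each specimen appears `factor` times.
#' @param per_specimen optional named integer vector of per-specimen copy
#'   numbers overriding `factor` (for unbalanced inflation).
#' @return a `taxonomy_collection` over the inflated universe.
#' @export
inflate_specimens <- function(x, factor = 1, per_specimen = NULL) {
  stopifnot(inherits(x, "taxonomy_collection"), factor >= 1)
  copies <- rep(as.integer(factor), length(x$universe))
  names(copies) <- x$universe
  if (!is.null(per_specimen))
    copies[names(per_specimen)] <- as.integer(per_specimen)
  new_ids <- unlist(lapply(x$universe, function(id) {
    k <- copies[[id]]
    if (k == 1L) id else c(id, paste0(id, "#", seq_len(k - 1L) + 1L))
  }))
  src <- rep(x$universe, copies[x$universe])
  parts <- lapply(x$partitions, function(p)
    species_partition(stats::setNames(p$assignment[src], new_ids),
                      method = p$method))
  taxonomy_collection(parts)
}

#' Generate a species-structured haplotype table
#'
#' Emulates multi-locus phased nuclear data over a known ("true") species
#' partition. At a non-admixed locus every species has a private allele
#' pool: each specimen draws one allele uniformly from its species pool and
#' carries the species' anchor allele on its second chromosome, so each
#' species forms exactly one single-locus field for recombination and
#' different species never share alleles. An admixed locus instead draws
#' from one global pool with a global anchor, lumping all specimens into a
#' single FFR -- the signal of a conserved marker. Loci are admixed
#' independently with probability `admixture_rate`, or exactly
#' `n_admixed` loci are (chosen at random) when that is given.
#'
#' @param true_partition a `species_partition`: the generating species.
#' @param n_loci number of loci.
#' @param alleles_per_species size of each private (and of the global)
#'   allele pool.
#' @param admixture_rate probability in `[0, 1]` that a locus is admixed.
#' @param n_admixed exact number of admixed loci (overrides the rate).
#' @param seed integer seed.
#' @return a `haplotype_table`; attribute `"admixed_loci"` lists the
#'   admixed locus ids.
#' @export
generate_haplotype_table <- function(true_partition, n_loci = 4,
                                     alleles_per_species = 3,
                                     admixture_rate = 0, n_admixed = NULL,
                                     seed = 1) {
  stopifnot(inherits(true_partition, "species_partition"),
            n_loci >= 1, alleles_per_species >= 1,
            admixture_rate >= 0, admixture_rate <= 1)
  ids <- true_partition$universe
  sp <- true_partition$assignment
  with_seed(seed, {
    loci <- paste0("L", seq_len(n_loci))
    admixed <- if (is.null(n_admixed)) {
      stats::runif(n_loci) < admixture_rate
    } else {
      seq_len(n_loci) %in% sample.int(n_loci, n_admixed)
    }
    rows <- lapply(seq_len(n_loci), function(l) {
      pool_of <- if (admixed[l]) {
        function(s) paste0(loci[l], "_g_a", seq_len(alleles_per_species))
      } else {
        function(s) paste0(loci[l], "_", s, "_a",
                           seq_len(alleles_per_species))
      }
      a <- vapply(ids, function(id) sample(pool_of(sp[[id]]), 1L),
                  character(1))
      anchor <- vapply(ids, function(id) pool_of(sp[[id]])[1L], character(1))
      data.frame(specimen = ids, locus = loci[l],
                 allele_a = unname(a), allele_b = unname(anchor),
                 stringsAsFactors = FALSE)
    })
    out <- haplotype_table(do.call(rbind, rows))
    attr(out, "admixed_loci") <- loci[admixed]
    out
  })
}
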