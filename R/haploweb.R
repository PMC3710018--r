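# Haploweb-style delimitation: single-locus fields for recombination from
# phased-allele co-occurrence, and the multi-locus majority consensus.

#' Create or read a phased haplotype table
#'
#' One record per (specimen, locus): the two phased alleles carried by a
#' diploid specimen, opaque labels unique within a locus. Homozygotes repeat
#' the same allele; a missing record (or an `NA,NA` row) means no data for
#' that specimen at that locus. Allele order within a record carries no
#' meaning.
#'
#' @param x a data frame with columns `specimen`, `locus`, `allele_a`,
#'   `allele_b`.
#' @return an object of class `haplotype_table` (a validated data frame).
#' @seealso [read_haplotype_table()], [single_locus_ffr()],
#'   [majority_consensus()]
#' @export
haplotype_table <- function(x) {
  need <- c("specimen", "locus", "allele_a", "allele_b")
  if (!all(need %in% colnames(x)))
    stop("haplotype table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x, stringsAsFactors = FALSE)[need]
  for (cc in need) x[[cc]] <- as.character(x[[cc]])
  # NA,NA rows encode missingness; half-missing records are malformed
  half <- xor(is.na(x$allele_a), is.na(x$allele_b))
  if (any(half))
    stop("record(s) with exactly one missing allele: specimen ",
         paste(x$specimen[half], collapse = ", "), call. = FALSE)
  x <- x[!is.na(x$allele_a), , drop = FALSE]
  key <- paste(x$specimen, x$locus, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), , drop = FALSE]
    stop("more than one record for (specimen, locus): ",
         paste(unique(paste0("(", d$specimen, ", ", d$locus, ")")),
               collapse = ", "), call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("haplotype_table", "data.frame")
  x
}

#' @rdname haplotype_table
#' @param path path to a TSV file with the four columns above; literal
#'   `NA` cells mark missing data.
#' @export
read_haplotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = "NA",
                          stringsAsFactors = FALSE)
  haplotype_table(df)
}

#' Read phased alleles for one locus from a FASTA file
#'
#' Convenience reader for phased sequence data: the file must hold exactly
#' two sequences per specimen (sequence names are the specimen ids, each
#' repeated twice, or suffixed `_a`/`_b`). Identical sequences (exact string
#' match after uppercasing; no alignment is attempted) receive identical
#' allele ids.
#'
#' @param path FASTA file with two sequences per specimen.
#' @param locus locus id to record.
#' @return a `haplotype_table` for this locus.
#' @export
read_phased_fasta <- function(path, locus) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- ape::read.FASTA(path)
  nm <- sub("_[ab]$", "", names(seqs))
  tab <- table(nm)
  if (any(tab != 2L))
    stop("expected exactly two sequences per specimen; offending: ",
         paste(names(tab)[tab != 2L], collapse = ", "), call. = FALSE)
  str <- toupper(vapply(as.character(seqs), paste0, character(1),
                        collapse = ""))
  allele <- paste0(locus, "_h", match(str, unique(str)))
  sp <- unique(nm)
  first <- allele[match(sp, nm)]
  second <- allele[length(allele) + 1L - match(sp, rev(nm))]
  haplotype_table(data.frame(specimen = sp, locus = locus,
                             allele_a = first, allele_b = second,
                             stringsAsFactors = FALSE))
}

#' Single-locus field for recombination
#'
#' Builds, for one locus, the graph whose vertices are the locus's alleles
#' with an edge between the two alleles of every specimen's record, and
#' returns its connected components: the fields for recombination (FFRs),
#' pools of alleles linked by co-occurrence in heterozygotes. Each specimen
#' with data at the locus maps to the single component holding its alleles;
#' specimens without data are unassigned. Only sharing/co-occurrence is
#' used -- haplotype-network topology plays no role in delimitation.
#'
#' @param h a `haplotype_table`.
#' @param locus locus id present in `h`.
#' @return an object of class `locus_ffr`: list with `locus`, `membership`
#'   (named integer vector, specimen to FFR component), `n_components`, and
#'   `alleles` (named integer vector, allele to component).
#' @examples
#' h <- haplotype_table(data.frame(
#'   specimen = c("s1", "s2", "s3"), locus = "L1",
#'   allele_a = c("h1", "h2", "h3"), allele_b = c("h2", "h2", "h3")))
#' single_locus_ffr(h, "L1")   # {s1, s2} | {s3}
#' @export
single_locus_ffr <- function(h, locus) {
  stopifnot(inherits(h, "haplotype_table"))
  rows <- h[h$locus == locus, , drop = FALSE]
  if (!nrow(rows))
    stop("unknown locus '", locus, "'", call. = FALSE)
  alleles <- unique(c(rows$allele_a, rows$allele_b))
  g <- igraph::graph_from_data_frame(
    rows[, c("allele_a", "allele_b")], directed = FALSE,
    vertices = data.frame(name = alleles))
  comp <- igraph::components(g)$membership
  membership <- stats::setNames(as.integer(comp[rows$allele_a]),
                                rows$specimen)
  structure(list(locus = locus, membership = membership,
                 n_components = max(comp),
                 alleles = stats::setNames(as.integer(comp), alleles)),
            class = "locus_ffr")
}

#' @export
print.locus_ffr <- function(x, ...) {
  cat("Locus '", x$locus, "': ", x$n_components,
      " field(s) for recombination over ", length(x$membership),
      " specimen(s) with data\n", sep = "")
  invisible(x)
}

#' Multi-locus majority-consensus species delimitation
#'
#' Combines single-locus fields for recombination into a species partition:
#' two specimens are considered separated at a locus when both have data
#' there and fall in different FFRs; a specimen pair is kept conspecific
#' unless at least `min_separating` loci separate it. Species are the
#' connected components (single linkage) of the "separated by fewer than
#' `min_separating` loci" relation -- along chains, lumping wins, matching
#' a conservative reading of the majority rule. The per-pair separation
#' counts are returned so forced merges can be audited.
#'
#' The default threshold is a strict majority of the loci,
#' `floor(L/2) + 1`: with four loci this is the "at least three of four"
#' rule. Loci with missing data for either specimen abstain; the threshold
#' is an absolute count and is not rescaled for missingness unless
#' `proportional = TRUE`, which instead requires
#' `ceiling(min_separating / L * informative loci)` separating loci per
#' pair.
#'
#' @param ffrs list of `locus_ffr` objects (one per locus), or a
#'   `haplotype_table` from which FFRs for all loci are computed.
#' @param min_separating integer threshold T >= 1; default
#'   `floor(L/2) + 1`.
#' @param universe optional specimen ids fixing partition membership and
#'   order; defaults to the specimens seen at any locus.
#' @param proportional rescale the threshold by the per-pair number of
#'   informative loci (off by default; the published rule is an absolute
#'   count).
#' @return an object of class `haploweb_consensus`: list with `partition`
#'   (a `species_partition`, method `"HW-consensus"`), `separating` (a
#'   symmetric integer matrix of per-pair separating-locus counts),
#'   `informative` (per-pair informative-locus counts), `threshold`,
#'   `n_loci`.
#' @examples
#' h <- haplotype_table(data.frame(
#'   specimen = rep(c("s1", "s2"), 2), locus = rep(c("L1", "L2"), each = 2),
#'   allele_a = c("a", "b", "c", "d"), allele_b = c("a", "b", "c", "d")))
#' majority_consensus(h, min_separating = 2)
#' @export
majority_consensus <- function(ffrs, min_separating = NULL, universe = NULL,
                               proportional = FALSE) {
  if (inherits(ffrs, "haplotype_table")) {
    h <- ffrs
    ffrs <- lapply(unique(h$locus), function(l) single_locus_ffr(h, l))
  }
  stopifnot(is.list(ffrs))
  if (!length(ffrs))
    stop("empty locus set: at least one locus is required", call. = FALSE)
  lapply(ffrs, function(f) stopifnot(inherits(f, "locus_ffr")))
  L <- length(ffrs)
  if (is.null(min_separating)) min_separating <- L %/% 2L + 1L
  min_separating <- as.integer(min_separating)
  if (min_separating < 1L) stop("'min_separating' must be >= 1",
                                call. = FALSE)
  if (min_separating > L)
    warning("'min_separating' (", min_separating, ") exceeds the number of ",
            "loci (", L, "); no pair can be separated and every connected ",
            "co-sampling component becomes one species", call. = FALSE)
  if (is.null(universe))
    universe <- unique(unlist(lapply(ffrs, function(f) names(f$membership))))
  n <- length(universe)
  sep <- matrix(0L, n, n, dimnames = list(universe, universe))
  inf <- matrix(0L, n, n, dimnames = list(universe, universe))
  for (f in ffrs) {
    ids <- intersect(universe, names(f$membership))
    if (length(ids) < 2L) next
    m <- f$membership[ids]
    inf[ids, ids] <- inf[ids, ids] + 1L
    differs <- outer(m, m, "!=")
    sep[ids, ids] <- sep[ids, ids] + differs
  }
  diag(inf) <- 0L; diag(sep) <- 0L
  thr <- if (proportional) {
    pmax(1L, ceiling(min_separating / L * inf))
  } else {
    matrix(min_separating, n, n)
  }
  linked <- sep < thr
  diag(linked) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  comp <- igraph::components(g)$membership
  part <- species_partition(
    stats::setNames(paste0("HW", comp[universe]), universe),
    method = "HW-consensus")
  structure(list(partition = part, separating = sep, informative = inf,
                 threshold = min_separating, n_loci = L,
                 proportional = proportional),
            class = "haploweb_consensus")
}

#' @export
print.haploweb_consensus <- function(x, ...) {
  cat("Haploweb majority consensus (", x$n_loci, " loci, pairs split when ",
      ">= ", x$threshold, " loci separate them",
      if (x$proportional) ", rescaled to informative loci", "):\n",
      sep = "")
  print(x$partition)
  invisible(x)
}
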