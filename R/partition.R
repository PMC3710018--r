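# Species partitions over a shared specimen universe: construction, I/O,
# validation, and the lattice operations (meet, laminarity) that the
# tree-free congruence metrics are built on.

#' Create a species partition
#'
#' A species partition records one delimitation method's assignment of every
#' specimen (or terminal lineage unit) to exactly one species. Species labels
#' are opaque and only meaningful within a method: two methods using the same
#' label string do not thereby claim the same species. A partition with k
#' species supports k - 1 cladogenetic speciation-event hypotheses.
#'
#' @param assignment named character vector: names are specimen ids, values
#'   are species labels. All ids must be distinct and all labels non-missing,
#'   non-empty.
#' @param method name of the delimitation method (a single string).
#' @return an object of class `species_partition` with elements `method`,
#'   `assignment` (named character, in input order) and `universe`.
#' @examples
#' p <- species_partition(c(a = "X", b = "X", c = "Y", d = "Y"), "demo")
#' n_species(p)
#' @export
species_partition <- function(assignment, method = "method") {
  if (length(assignment) == 0L)
    stop("a species partition needs at least one specimen", call. = FALSE)
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("'assignment' must be a fully named character vector", call. = FALSE)
  assignment <- vapply(assignment, as.character, character(1))
  dup <- unique(names(assignment)[duplicated(names(assignment))])
  if (length(dup))
    stop("duplicate specimen id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad <- names(assignment)[is.na(assignment) | assignment == ""]
  if (length(bad))
    stop("missing species label for specimen(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(method = as.character(method)[1],
         assignment = assignment,
         universe = names(assignment)),
    class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat("Species partition '", x$method, "': ", n_species(x), " species over ",
      length(x$universe), " specimens\n", sep = "")
  invisible(x)
}

#' Number of species and of speciation events in a partition
#'
#' `n_events()` returns the number of cladogenetic speciation-event
#' hypotheses supported by the partition, i.e. `n_species() - 1` (on a
#' dichotomous species tree, k species imply k - 1 splitting events).
#'
#' @param p a `species_partition`.
#' @return an integer count.
#' @export
n_species <- function(p) {
  stopifnot(inherits(p, "species_partition"))
  length(unique(p$assignment))
}

#' @rdname n_species
#' @export
n_events <- function(p) n_species(p) - 1L

# list of specimen-id character vectors, one per species, in order of first
# appearance of each label
clusters <- function(p) {
  stopifnot(inherits(p, "species_partition"))
  split(names(p$assignment), factor(p$assignment, levels = unique(p$assignment)))
}

stop_universe_mismatch <- function(a, b) {
  ua <- a$universe; ub <- b$universe
  if (setequal(ua, ub)) return(invisible(NULL))
  only_a <- setdiff(ua, ub); only_b <- setdiff(ub, ua)
  stop("partitions are over different specimen universes; only in '",
       a$method, "': {", paste(only_a, collapse = ", "), "}; only in '",
       b$method, "': {", paste(only_b, collapse = ", "), "}", call. = FALSE)
}

#' Common refinement (meet) of two species partitions
#'
#' Two specimens share a species in the meet exactly when they share a
#' species in both input partitions. The meet underlies the tree-free
#' congruence computation: a pair of compatible taxonomies cumulatively
#' supports `n_species(meet) - 1` speciation events. Labels of the meet are
#' the deterministic composites `"aLabel|bLabel"`, so repeated runs are
#' byte-identical.
#'
#' @param a,b `species_partition` objects over the identical universe.
#' @return a `species_partition` named `"meet(a,b)"` after the two methods.
#' @examples
#' a <- species_partition(c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"), "a")
#' b <- species_partition(c(s1 = "A", s2 = "B", s3 = "B", s4 = "B"), "b")
#' meet(a, b)   # three species: s1 | s2 | s3 s4
#' @export
meet <- function(a, b) {
  stopifnot(inherits(a, "species_partition"), inherits(b, "species_partition"))
  stop_universe_mismatch(a, b)
  lab <- paste(a$assignment, b$assignment[names(a$assignment)], sep = "|")
  names(lab) <- names(a$assignment)
  species_partition(lab, method = paste0("meet(", a$method, ",", b$method, ")"))
}

#' Test whether two partitions form a laminar family
#'
#' Tree-free congruence is only defined for compatible taxonomies: every
#' species of one partition must be nested within, contain, or be disjoint
#' from every species of the other (their union is a laminar family). Two
#' clade partitions of a common guide tree always satisfy this; crossing
#' clusters arise when methods disagree irreconcilably on specimen grouping.
#'
#' @param a,b `species_partition` objects over the identical universe.
#' @return `TRUE` or `FALSE`; on `FALSE` the attribute `"witness"` holds a
#'   list of one offending cluster pair (`label_a`, `label_b`, and the
#'   specimen ids of each).
#' @examples
#' a <- species_partition(c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y"), "a")
#' b <- species_partition(c(s1 = "P", s2 = "Q", s3 = "P", s4 = "Q"), "b")
#' is_laminar(a, b)            # FALSE: X and P cross
#' @export
is_laminar <- function(a, b) {
  stopifnot(inherits(a, "species_partition"), inherits(b, "species_partition"))
  stop_universe_mismatch(a, b)
  ca <- clusters(a); cb <- clusters(b)
  for (la in names(ca)) {
    sa <- ca[[la]]
    hit <- unique(b$assignment[sa])
    for (lb in hit) {
      sb <- cb[[lb]]
      inter <- length(intersect(sa, sb))
      if (inter < length(sa) && inter < length(sb)) {
        res <- FALSE
        attr(res, "witness") <- list(label_a = la, label_b = lb,
                                     cluster_a = sa, cluster_b = sb)
        return(res)
      }
    }
  }
  TRUE
}

#' Read a taxonomy table
#'
#' Reads a table of species assignments: one row per specimen, first column
#' the specimen id, each remaining column one delimitation method. Cells are
#' species labels; empty cells and duplicated specimen ids are hard errors
#' (a missing assignment is never silently interpreted as a singleton
#' species, which would inflate event counts).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a `taxonomy_collection`.
#' @seealso [write_taxonomy_table()], [taxonomy_collection()]
#' @export
read_taxonomy_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", na.strings = NULL,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("taxonomy table needs a specimen-id column plus >= 1 method column",
         call. = FALSE)
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate specimen id(s) in taxonomy table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  methods <- colnames(df)[-1L]
  dupm <- unique(methods[duplicated(methods)])
  if (length(dupm))
    stop("duplicate method column name(s): ", paste(dupm, collapse = ", "),
         call. = FALSE)
  parts <- lapply(methods, function(m) {
    lab <- df[[m]]
    bad <- which(is.na(lab) | lab == "")
    if (length(bad))
      stop("empty species label at row ", bad[1], " (specimen '",
           ids[bad[1]], "'), column '", m, "'", call. = FALSE)
    species_partition(stats::setNames(lab, ids), method = m)
  })
  taxonomy_collection(parts)
}

#' Create a taxonomy collection
#'
#' Bundles several species partitions over one identical specimen universe,
#' the comparison unit of all congruence metrics. Partitions over different
#' universes are refused: the metrics compare taxonomies of one sample set.
#' `restrict = TRUE` instead restricts every partition to the intersection
#' of the ids, with a loud warning.
#'
#' @param partitions list of `species_partition` objects with distinct
#'   method names.
#' @param restrict if `TRUE`, restrict all partitions to the common id
#'   intersection instead of erroring on a mismatch (warns).
#' @return an object of class `taxonomy_collection` with elements
#'   `universe` (specimen ids, row order of the first partition) and
#'   `partitions` (named list, method order preserved).
#' @export
taxonomy_collection <- function(partitions, restrict = FALSE) {
  stopifnot(is.list(partitions), length(partitions) >= 1L)
  lapply(partitions, function(p) stopifnot(inherits(p, "species_partition")))
  methods <- vapply(partitions, function(p) p$method, character(1))
  dup <- unique(methods[duplicated(methods)])
  if (length(dup))
    stop("duplicate method name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (restrict && length(partitions) > 1L) {
    common <- Reduce(intersect, lapply(partitions, function(p) p$universe))
    if (!length(common))
      stop("no specimens common to all partitions", call. = FALSE)
    full <- unique(unlist(lapply(partitions, function(p) p$universe)))
    if (length(common) < length(full))
      warning("restricting all partitions to the ", length(common),
              " specimens shared by every method (dropping ",
              length(full) - length(common), "); ",
              "taxonomy comparisons are only meaningful over one sample set",
              call. = FALSE)
    partitions <- lapply(partitions, function(p)
      species_partition(p$assignment[common], p$method))
  }
  u <- partitions[[1L]]$universe
  for (p in partitions[-1L]) stop_universe_mismatch(partitions[[1L]], p)
  names(partitions) <- methods
  structure(list(universe = u, partitions = partitions),
            class = "taxonomy_collection")
}

#' @export
print.taxonomy_collection <- function(x, ...) {
  k <- vapply(x$partitions, n_species, integer(1))
  cat("Taxonomy collection: ", length(x$universe), " specimens, ",
      length(x$partitions), " method(s)\n", sep = "")
  cat(paste0("  ", names(k), ": ", k, " species"), sep = "\n")
  invisible(x)
}

#' Write a taxonomy table
#'
#' Inverse of [read_taxonomy_table()]; writing then re-reading a valid
#' collection round-trips exactly.
#'
#' @param x a `taxonomy_collection`.
#' @param path output file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param id_column header for the specimen-id column.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(x, path, dialect = c("tsv", "csv"),
                                 id_column = "specimen") {
  stopifnot(inherits(x, "taxonomy_collection"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(x$universe, stringsAsFactors = FALSE)
  colnames(df) <- id_column
  for (m in names(x$partitions))
    df[[m]] <- unname(x$partitions[[m]]$assignment[x$universe])
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a taxonomy collection
#'
#' Reporting-only health check: per-method species and singleton counts and,
#' when at least two methods are present, pairwise laminarity (the
#' compatibility precondition of tree-free congruence). Never mutates or
#' rejects its input; the metric functions themselves refuse non-laminar
#' pairs.
#'
#' @param x a `taxonomy_collection`.
#' @return an object of class `taxonomy_validation`: a list with
#'   `n_specimens`, a per-method `summary` data frame, a `laminar` data
#'   frame of method pairs (or `NULL` for a single method) and
#'   `all_laminar`.
#' @export
validate_collection <- function(x) {
  stopifnot(inherits(x, "taxonomy_collection"))
  summ <- data.frame(
    method = names(x$partitions),
    n_species = vapply(x$partitions, n_species, integer(1)),
    n_singletons = vapply(x$partitions, function(p)
      sum(table(p$assignment) == 1L), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  lam <- NULL
  if (length(x$partitions) >= 2L) {
    prs <- utils::combn(names(x$partitions), 2L)
    lam <- data.frame(method_a = prs[1L, ], method_b = prs[2L, ],
                      laminar = NA, stringsAsFactors = FALSE)
    for (i in seq_len(ncol(prs)))
      lam$laminar[i] <- isTRUE(is_laminar(x$partitions[[prs[1L, i]]],
                                          x$partitions[[prs[2L, i]]]))
  }
  structure(list(n_specimens = length(x$universe), summary = summ,
                 laminar = lam,
                 all_laminar = if (is.null(lam)) NA else all(lam$laminar)),
            class = "taxonomy_validation")
}

#' @export
print.taxonomy_validation <- function(x, ...) {
  cat("Validation of taxonomy collection (", x$n_specimens, " specimens)\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  if (is.null(x$laminar)) {
    cat("Single method: pairwise comparisons unavailable.\n")
  } else if (isTRUE(x$all_laminar)) {
    cat("All ", nrow(x$laminar),
        " method pairs are laminar (tree-free metrics defined).\n", sep = "")
  } else {
    bad <- x$laminar[!x$laminar$laminar, , drop = FALSE]
    cat("Non-laminar pair(s): ",
        paste(paste0(bad$method_a, "~", bad$method_b), collapse = ", "),
        " (tree-free metrics undefined for these)\n", sep = "")
  }
  invisible(x)
}
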