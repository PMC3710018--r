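# Congruence metrics: pairwise Ctax, per-method Rtax, mean Ctax, the full
# report, and the pair-counting Rand baselines.

#' Taxonomic index of congruence between two taxonomies
#'
#' Ctax compares two species delimitations of the same specimens as the
#' ratio of the number of speciation-event hypotheses congruently supported
#' by both (n_shared) to the number cumulatively supported by either
#' (n_union) -- a Jaccard index on event sets. In tree mode the event sets
#' are node sets of the guide tree; in tree-free mode event counts follow
#' from species counts (k species support k - 1 events) and the union count
#' is `n_species(meet(a, b)) - 1`, which requires the two partitions to be
#' laminar (compatible). The two modes agree exactly whenever both apply.
#'
#' Full precision is always retained; round only for display (see
#' [round_half_up()]). The degenerate case of two single-species taxonomies
#' has no events on either side and is defined as Ctax = 1 with a warning
#' (both support the same, empty, boundary set).
#'
#' @param a,b `species_partition` objects over one universe.
#' @param mode `"free"` (default) or `"tree"`.
#' @param tree a `guide_tree`, required for `mode = "tree"`.
#' @return an object of class `pairwise_ctax`: list with `method_a`,
#'   `method_b`, `n_a`, `n_b` (event counts), `n_shared`, `n_union`,
#'   `ctax`, `mode`.
#' @examples
#' a <- species_partition(c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y"), "a")
#' b <- species_partition(c(s1 = "1", s2 = "2", s3 = "3", s4 = "3"), "b")
#' ctax_pair(a, b)   # 1 shared of 2 cumulative events: Ctax = 0.5
#' @export
ctax_pair <- function(a, b, mode = c("free", "tree"), tree = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "species_partition"), inherits(b, "species_partition"))
  stop_universe_mismatch(a, b)
  n_a <- n_events(a); n_b <- n_events(b)
  if (mode == "tree") {
    if (is.null(tree))
      stop("mode = \"tree\" requires a guide tree", call. = FALSE)
    ea <- extract_event_nodes(a, tree)
    eb <- extract_event_nodes(b, tree)
    n_shared <- length(intersect(ea, eb))
    n_union <- length(union(ea, eb))
  } else {
    lam <- is_laminar(a, b)
    if (!isTRUE(lam)) {
      w <- attr(lam, "witness")
      stop("Ctax undefined for incompatible taxonomies: species '",
           w$label_a, "' of '", a$method, "' {",
           paste(w$cluster_a, collapse = ", "), "} crosses species '",
           w$label_b, "' of '", b$method, "' {",
           paste(w$cluster_b, collapse = ", "), "}", call. = FALSE)
    }
    n_union <- n_events(meet(a, b))
    n_shared <- n_a + n_b - n_union
  }
  ctax <- if (n_union == 0L) {
    warning("both taxonomies have a single species (no speciation events); ",
            "Ctax defined as 1", call. = FALSE)
    1
  } else n_shared / n_union
  structure(list(method_a = a$method, method_b = b$method,
                 n_a = n_a, n_b = n_b,
                 n_shared = as.integer(n_shared),
                 n_union = as.integer(n_union),
                 ctax = ctax, mode = mode),
            class = "pairwise_ctax")
}

#' @export
print.pairwise_ctax <- function(x, digits = 2, ...) {
  cat("Ctax(", x$method_a, ", ", x$method_b, ") = ", x$n_shared, "/",
      x$n_union, " = ", format(round_half_up(x$ctax, digits), nsmall = digits),
      "  [", x$mode, " mode; events: ", x$n_a, " vs ", x$n_b, "]\n",
      sep = "")
  invisible(x)
}

#' Relative taxonomic resolving power index
#'
#' Rtax of a method is the share of the complete set of speciation-event
#' hypotheses, cumulatively revealed by all compared methods, that this
#' method supports on its own: `(k_m - 1) / n_total`. In tree mode
#' `n_total` is the size of the union of all methods' event-node sets; in
#' tree-free mode it is `n_species(meet of all partitions) - 1`, defined
#' when the collection is globally laminar. A high Rtax means high
#' resolving power (low beta error), not necessarily reliability.
#'
#' @param x a `taxonomy_collection` with at least two methods.
#' @param mode `"free"` (default) or `"tree"`.
#' @param tree a `guide_tree` for `mode = "tree"`.
#' @return named numeric vector of per-method Rtax values, with attribute
#'   `"n_total"` (the union event count).
#' @export
rtax <- function(x, mode = c("free", "tree"), tree = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "taxonomy_collection"))
  if (length(x$partitions) < 2L)
    stop("Rtax needs at least two methods to compare", call. = FALSE)
  n_total <- total_events(x, mode, tree)
  k <- vapply(x$partitions, n_events, integer(1))
  structure(k / n_total, n_total = n_total)
}

# union event count over all methods of a collection
total_events <- function(x, mode, tree) {
  if (mode == "tree") {
    if (is.null(tree))
      stop("mode = \"tree\" requires a guide tree", call. = FALSE)
    length(unique(unlist(lapply(x$partitions, extract_event_nodes,
                                tree = tree))))
  } else {
    prs <- utils::combn(length(x$partitions), 2L)
    for (i in seq_len(ncol(prs))) {
      lam <- is_laminar(x$partitions[[prs[1L, i]]],
                        x$partitions[[prs[2L, i]]])
      if (!isTRUE(lam)) {
        w <- attr(lam, "witness")
        stop("tree-free Rtax undefined: methods '",
             names(x$partitions)[prs[1L, i]], "' and '",
             names(x$partitions)[prs[2L, i]], "' are not laminar (species '",
             w$label_a, "' crosses '", w$label_b, "')", call. = FALSE)
      }
    }
    n_events(Reduce(meet, x$partitions))
  }
}

#' Mean congruence of one method with all others
#'
#' Arithmetic mean of the pairwise Ctax values involving one method,
#' computed either from a `congruence_report` (full-precision values) or
#' from a user-supplied symmetric matrix, e.g. of printed two-decimal
#' values.
#'
#' @param x a `congruence_report` or a square numeric matrix with method
#'   names as dimnames (diagonal ignored).
#' @param method method name.
#' @return the mean of the off-diagonal Ctax values involving `method`.
#' @examples
#' m <- matrix(c(1, .8, .8, 1), 2, dimnames = list(c("A","B"), c("A","B")))
#' mean_ctax(m, "A")
#' @export
mean_ctax <- function(x, method) {
  m <- if (inherits(x, "congruence_report")) x$ctax else as.matrix(x)
  if (is.null(dimnames(m)) || !(method %in% rownames(m)))
    stop("unknown method '", method, "'", call. = FALSE)
  v <- m[method, setdiff(colnames(m), method)]
  if (anyNA(v))
    stop("missing pairwise Ctax value(s) for method '", method, "': ",
         paste(names(v)[is.na(v)], collapse = ", "), call. = FALSE)
  mean(v)
}

#' Compare all taxonomies of a collection
#'
#' The main entry point: computes per-method species counts, the symmetric
#' pairwise Ctax matrix, per-method Rtax, per-method mean Ctax and the
#' total union event count, in the layout of a published comparison table.
#'
#' @param x a `taxonomy_collection` with at least two methods.
#' @param mode `"free"` (default) or `"tree"`.
#' @param tree a `guide_tree` for `mode = "tree"`.
#' @return an object of class `congruence_report`: list with `methods`,
#'   `n_species` (named int), `ctax` (full-precision symmetric matrix, unit
#'   diagonal), `rtax`, `mean_ctax`, `n_total_events`, `mode`. Values are
#'   full precision; `print()` and [write_report()] round for display.
#' @examples
#' a <- species_partition(c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y"), "a")
#' b <- species_partition(c(s1 = "1", s2 = "2", s3 = "3", s4 = "3"), "b")
#' compare_taxonomies(taxonomy_collection(list(a, b)))
#' @export
compare_taxonomies <- function(x, mode = c("free", "tree"), tree = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "taxonomy_collection"))
  if (length(x$partitions) < 2L)
    stop("comparison needs at least two methods", call. = FALSE)
  ms <- names(x$partitions)
  nm <- length(ms)
  cm <- matrix(1, nm, nm, dimnames = list(ms, ms))
  for (i in seq_len(nm - 1L)) for (j in (i + 1L):nm) {
    pc <- ctax_pair(x$partitions[[i]], x$partitions[[j]], mode = mode,
                    tree = tree)
    cm[i, j] <- cm[j, i] <- pc$ctax
  }
  rt <- rtax(x, mode = mode, tree = tree)
  mc <- vapply(ms, function(m) mean_ctax_matrix(cm, m), numeric(1))
  structure(list(methods = ms,
                 n_species = vapply(x$partitions, n_species, integer(1)),
                 ctax = cm, rtax = stats::setNames(as.numeric(rt), ms),
                 mean_ctax = mc,
                 n_total_events = attr(rt, "n_total"), mode = mode),
            class = "congruence_report")
}

mean_ctax_matrix <- function(m, method)
  mean(m[method, setdiff(colnames(m), method)])

#' @export
print.congruence_report <- function(x, digits = 2, ...) {
  cat("Taxonomy congruence report (", x$mode, " mode): ",
      length(x$methods), " methods, ", x$n_total_events,
      " speciation events in total\n\n", sep = "")
  print(as.data.frame(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.matrix.congruence_report <- function(x, ...) x$ctax

#' @export
as.data.frame.congruence_report <- function(x, row.names = NULL,
                                            optional = FALSE, digits = 2,
                                            ...) {
  cm <- round_half_up(x$ctax, digits)
  diag(cm) <- NA
  df <- as.data.frame(cm)
  df <- cbind(method = x$methods, df,
              mean_Ctax = round_half_up(x$mean_ctax, digits),
              Rtax = round_half_up(x$rtax, digits),
              Nb_species = as.integer(x$n_species))
  rownames(df) <- NULL
  df
}

#' @export
summary.congruence_report <- function(object, digits = 2, ...) {
  print(object, digits = digits)
  off <- object$ctax[lower.tri(object$ctax)]
  i <- which(object$ctax == max(off) & lower.tri(object$ctax),
             arr.ind = TRUE)[1, ]
  j <- which(object$ctax == min(off) & lower.tri(object$ctax),
             arr.ind = TRUE)[1, ]
  cat("\nMost congruent pair:  ", object$methods[i[2]], " ~ ",
      object$methods[i[1]], " (Ctax = ",
      format(round_half_up(max(off), digits), nsmall = digits), ")\n",
      "Least congruent pair: ", object$methods[j[2]], " ~ ",
      object$methods[j[1]], " (Ctax = ",
      format(round_half_up(min(off), digits), nsmall = digits), ")\n",
      sep = "")
  invisible(object)
}

#' Write a congruence report to CSV or JSON
#'
#' The CSV mirrors the published table layout (pairwise matrix block plus
#' per-method mean Ctax, Rtax and species-count columns); the JSON twin
#' carries the same fields at full precision.
#'
#' @param x a `congruence_report`.
#' @param path output path.
#' @param format `"csv"` (default) or `"json"`.
#' @param digits display rounding (half-up) for the CSV; JSON is always
#'   full precision.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json"), digits = 2) {
  stopifnot(inherits(x, "congruence_report"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(x, digits = digits), path,
                     row.names = FALSE, quote = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(mode = x$mode, methods = x$methods,
           n_species = as.list(x$n_species),
           ctax = x$ctax, rtax = as.list(x$rtax),
           mean_ctax = as.list(x$mean_ctax),
           n_total_events = x$n_total_events),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Rand and adjusted Rand indices between two partitions
#'
#' Standard pair-counting agreement baselines, provided for contrast with
#' Ctax: the Rand index counts specimen pairs classified alike in both
#' partitions, so it is weighted by how many specimens each species holds.
#' Duplicating the specimens of one species changes the Rand index but
#' leaves Ctax and Rtax untouched.
#'
#' @param a,b `species_partition` objects over one universe with at least
#'   two specimens.
#' @return a single number: the Rand index in `[0, 1]`, or the
#'   chance-adjusted Rand index (<= 1, 0 expected under random labels).
#' @examples
#' a <- species_partition(c(s1 = "X", s2 = "X", s3 = "Y", s4 = "Y"), "a")
#' b <- species_partition(c(s1 = "P", s2 = "Q", s3 = "P", s4 = "Q"), "b")
#' rand_index(a, b)   # 2/6
#' @export
rand_index <- function(a, b) {
  ct <- pair_contingency(a, b)
  n <- ct$n
  total <- choose(n, 2)
  same_both <- sum(choose(ct$nij, 2))
  same_a <- sum(choose(ct$ai, 2))
  same_b <- sum(choose(ct$bj, 2))
  # agreements: pairs together in both, plus pairs apart in both
  (total + 2 * same_both - same_a - same_b) / total
}

#' @rdname rand_index
#' @export
adjusted_rand_index <- function(a, b) {
  ct <- pair_contingency(a, b)
  total <- choose(ct$n, 2)
  same_both <- sum(choose(ct$nij, 2))
  same_a <- sum(choose(ct$ai, 2))
  same_b <- sum(choose(ct$bj, 2))
  expected <- same_a * same_b / total
  maxi <- (same_a + same_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (same_both - expected) / (maxi - expected)
}

pair_contingency <- function(a, b) {
  stopifnot(inherits(a, "species_partition"), inherits(b, "species_partition"))
  stop_universe_mismatch(a, b)
  if (length(a$universe) < 2L)
    stop("Rand index needs at least two specimens", call. = FALSE)
  tab <- table(a$assignment, b$assignment[names(a$assignment)])
  list(n = length(a$universe), nij = as.numeric(tab),
       ai = rowSums(tab), bj = colSums(tab))
}
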