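# shared fixtures and oracles built in code

# quick partition: part("a a b b") -> species_partition over s1..s4
part <- function(labels, method = "m", ids = NULL) {
  lab <- strsplit(labels, " +")[[1]]
  ids <- ids %||% paste0("s", seq_along(lab))
  species_partition(stats::setNames(lab, ids), method = method)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical, label-free form of a partition: sorted cluster strings
canon <- function(p) {
  cl <- split(names(p$assignment), p$assignment)
  unname(sort(vapply(cl, function(s) paste(sort(s), collapse = ","),
                     character(1))))
}
same_partition <- function(a, b) identical(canon(a), canon(b))

# independent meet oracle: enumerate co-membership over all specimen pairs
meet_oracle <- function(a, b) {
  ids <- a$universe
  co <- outer(a$assignment[ids], a$assignment[ids], "==") &
    outer(b$assignment[ids], b$assignment[ids], "==")
  # connected components of the co-membership relation (it is transitive)
  seen <- character(0); out <- list()
  for (i in ids) {
    if (i %in% seen) next
    grp <- ids[co[i, ]]
    seen <- c(seen, grp)
    out[[length(out) + 1L]] <- sort(grp)
  }
  sort(vapply(out, paste, character(1), collapse = ","))
}

# random partition of ids into at most kmax labels
random_partition <- function(ids, kmax, method = "r") {
  lab <- sample(paste0("g", seq_len(kmax)), length(ids), replace = TRUE)
  species_partition(stats::setNames(lab, ids), method = method)
}

write_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
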