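# internal helpers shared across modules

#' Round half away from zero at a fixed number of decimals
#'
#' Decimal rounding with the "half-up" tie rule used for display and for
#' regression against printed two-decimal tables. Base [round()] uses
#' round-half-to-even, which turns 0.915 into 0.92 or 0.91 depending on the
#' binary neighbourhood; printed taxonomic tables conventionally round
#' halves up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.915, 0.5714, 0.625), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  y <- x * p
  f <- floor(y)
  r <- y - f
  # tolerance absorbs binary representation error of exact decimal halves
  out <- ifelse(r >= 0.5 - 1e-9, f + 1, f) / p
  out[is.na(x)] <- NA_real_
  out
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# canonical string key for a set of specimen ids (used for clade identity)
set_key <- function(ids) paste(sort(ids), collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a
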