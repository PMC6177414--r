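`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Seeds the R generator, evaluates `expr`, and restores the previous
#' `.Random.seed`, so library code never perturbs the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed below 2^31 from a master seed and a stream index
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483629L)
}

# normalize chromosome names: strip "chr" prefix, keep as character
norm_chrom <- function(x) {
  sub("^[Cc]hr", "", as.character(x))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) >= 1 && all(!is.na(x)) && all(x >= 0) &&
    all(x == floor(x))
}

# stable order by score descending, ties broken by id (lexicographic)
order_by_score_desc <- function(score, id) {
  order(-score, as.character(id), method = "radix")
}
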