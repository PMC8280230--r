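# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so package functions never clobber user randomness.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# recognised taxonomic ranks, finest first; "root" is the unranked apex
.rank_levels <- c("species", "genus", "family", "order", "class", "phylum",
                  "kingdom", "root")

rank_index <- function(rank) {
  i <- match(rank, .rank_levels)
  if (anyNA(i)) stop("unknown taxonomic rank: ",
                     paste(unique(rank[is.na(i)]), collapse = ", "))
  i
}

# is rank a at least as coarse as rank b?
rank_coarser_or_equal <- function(a, b) rank_index(a) >= rank_index(b)

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number")
  }
}
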