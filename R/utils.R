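# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# parallel map over identically-shaped nested lists of numerics
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    return(out)
  }
  f(a, b)
}

tree_map3 <- function(a, b, c, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map3(a[[i]], b[[i]], c[[i]], f)
    return(out)
  }
  f(a, b, c)
}

tree_map1 <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map1(a[[i]], f)
    return(out)
  }
  f(a)
}

# total number of scalars in a parameter tree
tree_length <- function(a) {
  if (is.list(a)) return(sum(vapply(a, tree_length, numeric(1))))
  length(a)
}
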