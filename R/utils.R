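# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make label mapping depend on parity; delineation labels use the commercial
# rounding convention at train and eval time alike.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a run seed; keeps results below .Machine$integer.max.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483629)
}

stop_ecg <- function(msg, class) {
  rlang::abort(msg, class = paste0("ecgdelin_", class))
}

# ---- tree utilities over nested lists of numeric arrays --------------------
# Parameters, gradients and optimizer state share one nested-list shape; these
# walk that shape without flattening it.

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, tree, ...) {
  extras <- list(...)
  if (is_leaf(tree)) {
    return(do.call(f, c(list(tree), lapply(extras, identity))))
  }
  out <- vector("list", length(tree))
  names(out) <- names(tree)
  for (i in seq_along(tree)) {
    out[[i]] <- do.call(
      tree_map,
      c(list(f, tree[[i]]), lapply(extras, function(e) e[[i]]))
    )
  }
  out
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map(function(x, y) x + y, a, b)

# Sum of |x| over every leaf; used by freezing tests.
tree_abs_sum <- function(tree) {
  if (is_leaf(tree)) return(sum(abs(tree)))
  sum(vapply(tree, tree_abs_sum, numeric(1)))
}

tree_n_params <- function(tree) {
  if (is_leaf(tree)) return(length(tree))
  sum(vapply(tree, tree_n_params, numeric(1)))
}

# Flatten leaves to a single numeric vector (deterministic order).
tree_flatten <- function(tree) {
  if (is_leaf(tree)) return(as.numeric(tree))
  unlist(lapply(tree, tree_flatten), use.names = FALSE)
}

# Inverse of tree_flatten given a template tree.
tree_unflatten <- function(template, values) {
  idx <- 0L
  rebuild <- function(node) {
    if (is_leaf(node)) {
      n <- length(node)
      out <- values[(idx + 1L):(idx + n)]
      if (!is.null(dim(node))) dim(out) <- dim(node)
      idx <<- idx + n
      return(out)
    }
    lapply(node, rebuild)
  }
  out <- rebuild(template)
  stopifnot(idx == length(values))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
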