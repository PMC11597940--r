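# Shared fixtures, built in code.

# Small cached synthetic dataset: 64x64, scenario 1.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(
        synth_config(image_size = 64L, n_normal = 6L, n_glaucoma = 4L,
                     n_validation = 4L, seed = 101L), scenario = 1)
    cache
  }
})

# Random nested OD/OC mask pair on an n x n grid.
random_nested_masks <- function(n = 32L) {
  cr <- runif(2, n * 0.35, n * 0.65)
  rd <- runif(1, n * 0.15, n * 0.3)
  rc <- rd * runif(1, 0.3, 0.9)
  r <- matrix(rep(1:n, times = n), n, n)
  c_ <- matrix(rep(1:n, each = n), n, n)
  od <- ((r - cr[1])^2 + (c_ - cr[2])^2 <= rd^2) * 1L
  oc <- ((r - cr[1])^2 + (c_ - cr[2])^2 <= rc^2) * 1L
  list(od = od, oc = oc)
}

# Independent pixel-counting oracles (set operations only).
oracle_dice <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  if (length(A) == 0 && length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

oracle_iou <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  u <- length(union(A, B))
  if (u == 0) return(1)
  length(intersect(A, B)) / u
}

# Extents of the whole foreground (valid oracle for single-component
# masks).
oracle_extent <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(0, 0))
  c(diff(range(idx[, 1])) + 1, diff(range(idx[, 2])) + 1)
}

# Count of trainable parameters in a parameter tree.
n_params <- function(params) {
  sum(rapply(params, function(v) length(v), how = "unlist",
             classes = c("numeric", "array", "matrix", "integer")))
}

# Largest absolute difference between two parameter trees.
max_param_delta <- function(a, b) {
  va <- rapply(a, identity, how = "unlist")
  vb <- rapply(b, identity, how = "unlist")
  max(abs(va - vb))
}
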