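# Internal helpers: seed handling, apportionment, R^2.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
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

# n child seeds derived from one root seed; independent of the order in
# which children are later consumed.
derive_seeds <- function(root_seed, n) {
  with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Integer apportionment of `total` across cells proportional to `weights`
# (largest-remainder / Hamilton method).  Allocation is capped at `cap`
# per cell when supplied; ties in remainders break toward earlier cells.
largest_remainder <- function(weights, total, cap = NULL) {
  k <- length(weights)
  if (total == 0 || k == 0L || sum(weights) == 0) return(integer(k))
  share <- total * weights / sum(weights)
  alloc <- floor(share)
  rem <- share - alloc
  left <- total - sum(alloc)
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1
  }
  alloc <- as.integer(alloc)
  if (!is.null(cap)) {
    over <- pmax(alloc - cap, 0L)
    if (any(over > 0L)) {
      alloc <- pmin(alloc, cap)
      # redistribute clipped units to cells with headroom, largest first
      spare <- sum(over)
      room <- cap - alloc
      ord <- order(weights, decreasing = TRUE)
      for (i in ord) {
        if (spare == 0L) break
        take <- min(spare, room[i])
        alloc[i] <- alloc[i] + take
        spare <- spare - take
      }
    }
  }
  alloc
}

#' Squared Pearson correlation between two paired vectors
#'
#' Used for the equivalence analyses (overall vs within-age reduction,
#' individual vs aggregate data).  Identical vectors return 1 even when
#' they are constant.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Squared Pearson correlation in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations for R^2")
  if (isTRUE(all.equal(as.numeric(x), as.numeric(y)))) return(1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("R^2 undefined: an input vector is constant")
  stats::cor(x, y)^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
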