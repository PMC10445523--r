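# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so builders/generators never perturb a user's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Wrap an angle (radians) into (-pi, pi].
wrap_to_pi <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi] <- pi
  y
}

# n random unit vectors as an n x 3 matrix (consumes the current RNG stream).
random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  nr <- sqrt(rowSums(v * v))
  nr[nr < 1e-12] <- 1
  v / nr
}

# Rodrigues rotation matrix for a random axis/angle drawn from the RNG stream.
random_rotation <- function() {
  ax <- drop(random_unit_vectors(1L))
  th <- stats::runif(1L, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Minimum-image displacement columns of a matrix under an orthorhombic box.
min_image <- function(dx, box) {
  if (is.null(box)) return(dx)
  for (k in 1:3) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  dx
}

# Neighbour join on a uniform grid: all (query i, target j) pairs with
# |q_i - t_j| < cutoff, minimum-image if `box` is given.  Returns list(i, j, d).
# With few cells per axis and a periodic box, aliased offsets can report a pair
# more than once; callers needing exact pair counts deduplicate.
grid_join <- function(q, t, cutoff, box = NULL) {
  nq <- nrow(q); nt <- nrow(t)
  empty <- list(i = integer(), j = integer(), d = numeric())
  if (nq == 0L || nt == 0L) return(empty)
  periodic <- !is.null(box)
  if (periodic) {
    lo <- c(0, 0, 0); L <- as.numeric(box)
  } else {
    lo <- pmin(apply(q, 2, min), apply(t, 2, min)) - cutoff
    L <- pmax(apply(q, 2, max), apply(t, 2, max)) + cutoff - lo
  }
  nc <- pmax(1L, as.integer(floor(L / cutoff)))
  cw <- L / nc
  cell_idx <- function(p) {
    m <- matrix(0L, nrow(p), 3L)
    for (k in 1:3) {
      v <- floor((p[, k] - lo[k]) / cw[k])
      v <- if (periodic) v %% nc[k] else pmin(pmax(v, 0), nc[k] - 1L)
      m[, k] <- as.integer(v)
    }
    m
  }
  ct <- cell_idx(t)
  cq <- cell_idx(q)
  keyf <- function(m) m[, 1] + nc[1] * (m[, 2] + nc[2] * m[, 3])
  kt <- keyf(ct)
  ord <- order(kt)
  kts <- kt[ord]
  starts <- which(c(TRUE, kts[-1L] != kts[-length(kts)]))
  lens <- diff(c(starts, length(kts) + 1L))
  uk <- kts[starts]
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  acc_i <- vector("list", nrow(offs))
  acc_j <- vector("list", nrow(offs))
  acc_d <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    tc <- sweep(cq, 2L, as.integer(offs[o, ]), "+")
    valid <- rep(TRUE, nq)
    for (k in 1:3) {
      if (periodic) {
        tc[, k] <- tc[, k] %% nc[k]
      } else {
        valid <- valid & tc[, k] >= 0L & tc[, k] < nc[k]
      }
    }
    kq <- tc[, 1] + nc[1] * (tc[, 2] + nc[2] * tc[, 3])
    pos <- findInterval(kq, uk)
    hit <- valid & pos >= 1L & uk[pmax(pos, 1L)] == kq
    sel <- which(hit)
    if (!length(sel)) next
    g <- pos[sel]
    cnt <- lens[g]
    I <- rep.int(sel, cnt)
    J <- ord[sequence(cnt, from = starts[g])]
    dx <- q[I, , drop = FALSE] - t[J, , drop = FALSE]
    if (periodic) dx <- min_image(dx, box)
    d2 <- rowSums(dx * dx)
    keep <- d2 < cutoff^2
    if (any(keep)) {
      acc_i[[o]] <- I[keep]
      acc_j[[o]] <- J[keep]
      acc_d[[o]] <- sqrt(d2[keep])
    }
  }
  list(i = unlist(acc_i), j = unlist(acc_j), d = unlist(acc_d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
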