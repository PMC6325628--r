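# Brute-force reference implementations used as independent oracles, plus
# small fixture builders shared across test files.

# plane-wise 2-D correlation with an explicit square kernel, replicate
# padding, origin at element floor((N+1)/2)
naive_conv_plane <- function(mat, kernel2d) {
  nk <- nrow(kernel2d)
  c0 <- (nk + 1) %/% 2
  ny <- nrow(mat); nx <- ncol(mat)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    s <- 0
    for (ky in seq_len(nk)) for (kx in seq_len(nk)) {
      yy <- min(max(y + ky - c0, 1), ny)
      xx <- min(max(x + kx - c0, 1), nx)
      s <- s + kernel2d[ky, kx] * mat[yy, xx]
    }
    out[y, x] <- s
  }
  out
}

naive_filter_vol <- function(vol, kernel1d) {
  k2 <- outer(kernel1d, kernel1d)
  out <- vol
  for (z in seq_len(dim(vol)[3])) out[, , z] <- naive_conv_plane(vol[, , z], k2)
  out
}

# BFS connected-component labelling
naive_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dz) == 1, ]
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    if (!mask[y, x, z] || lab[y, x, z] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(y, x, z), ncol = 3)
    lab[y, x, z] <- nxt
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        q <- p + c(offs$dy[k], offs$dx[k], offs$dz[k])
        if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- nxt
          queue <- rbind(queue, q)
        }
      }
    }
  }
  lab
}

naive_size_filter <- function(mask, min_px, max_px = Inf, connectivity = 26) {
  lab <- naive_label(mask, connectivity)
  out <- array(FALSE, dim = dim(mask))
  if (max(lab) == 0) return(out)
  for (k in seq_len(max(lab))) {
    n <- sum(lab == k)
    if (n >= min_px && n <= max_px) out[lab == k] <- TRUE
  }
  out
}

naive_erode6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    if (!mask[y, x, z]) next
    ok <- TRUE
    for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      q <- c(y, x, z) + o
      if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3]) { ok <- FALSE; break }
      if (!mask[q[1], q[2], q[3]]) { ok <- FALSE; break }
    }
    out[y, x, z] <- ok
  }
  out
}

naive_reconstruct <- function(seed, limit, connectivity = 26) {
  lab <- naive_label(limit, connectivity)
  keep <- unique(lab[seed & limit]); keep <- keep[keep > 0]
  array(lab %in% keep, dim = dim(limit))
}

naive_max_project <- function(vol) {
  d <- dim(vol)
  out <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1]))
    out[y, x] <- max(out[y, x], vol[y, x, z])
  out
}

random_mask <- function(dims, p = 0.3) {
  array(runif(prod(dims)) < p, dim = dims)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
# (valid without ties)
mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  n2 <- length(y)
  mu <- n1 * n2 / 2
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# a straight voxel line mask
line_mask <- function(n = 20) {
  m <- array(FALSE, dim = c(n + 4, 5, 3))
  m[3:(n + 2), 3, 2] <- TRUE
  m
}

# a component of exactly n voxels (a straight run, wrapped over rows)
exact_component <- function(n, dims = c(50, 50, 3), origin = c(2, 2, 2)) {
  m <- array(FALSE, dim = dims)
  placed <- 0
  x <- origin[2]
  while (placed < n) {
    take <- min(n - placed, dims[1] - origin[1])
    m[origin[1]:(origin[1] + take - 1), x, origin[3]] <- TRUE
    placed <- placed + take
    x <- x + 1
  }
  m
}

# scaled-down chip fixture and matching chip parameters for module tests
small_spec <- function(noise_frac = 0, morpho = NULL, mito = NULL,
                       viability = NULL) {
  sp <- fixture_spec(ny = 400L, nx = 390L, nz = 10L, noise_frac = noise_frac,
                     geom = list(margin = 15L, wall_w = 40L, mc_w = 160L,
                                 pg_w = 30L, pc_w = 90L, pg_zmax = 8L,
                                 obj_margin = 50L, row_margin = 60L),
                     morpho = list(n_nuclei = 6L, n_pyknotic = 2L,
                                   n_neurons = 1L, n_th = 1L),
                     mito = list(n_nuclei = 4L, n_cells = 2L, n_mito = 8L),
                     viability = list(n_live = 3L, n_cc3_live = 1L, n_dead = 2L))
  for (nm in c("morpho", "mito", "viability")) {
    ov <- get(nm)
    if (!is.null(ov)) sp[[nm]][names(ov)] <- ov
  }
  sp
}

small_chip_params <- list(min_wall_px = 15000, min_component_px = 1000)
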