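# Synthetic 3-D fixtures with voxel-level ground truth. The generator renders
# the chip geometry (two full-height wall blocks, a central phase-guide ridge
# confined to the lowest planes, Matrigel and perfusion channels) and places
# assay-specific objects on the raw gray-level scale the pipeline's fixed
# thresholds assume, each safely clear (>= 20% margin) of its segmentation
# threshold so noise-free recovery is exact.

#' Default fixture specification
#'
#' Geometry defaults give wall and phase-guide blocks large enough for the
#' full device-refinement chain (including the 100 000-pixel wall filter)
#' to run at its standard parameters. Object counts are per bioreactor;
#' `viability$n_live` counts all calcein-positive cells including the
#' `n_cc3_live` CC3-positive ones. `noise_frac` is the additive Gaussian
#' noise standard deviation as a fraction of each channel's dynamic range.
#'
#' @param ny,nx,nz Stack shape (rows, columns, planes).
#' @param noise_frac Noise level; 0 renders noise-free stacks.
#' @param ... Named overrides of the per-assay object-count lists `morpho`,
#'   `mito`, `viability` or the geometry list `geom`.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(ny = 1536L, nx = 500L, nz = 10L, noise_frac = 0, ...) {
  spec <- list(
    ny = as.integer(ny), nx = as.integer(nx), nz = as.integer(nz),
    noise_frac = noise_frac,
    geom = list(margin = 15L, wall_w = 60L, mc_w = 160L, pg_w = 50L,
                pc_w = 140L, pg_zmax = 8L, obj_margin = 50L,
                row_margin = 60L),
    morpho = list(n_nuclei = 18L, n_pyknotic = 6L, n_neurons = 8L, n_th = 6L),
    mito = list(n_nuclei = 12L, n_cells = 6L, n_mito = 40L),
    viability = list(n_live = 10L, n_cc3_live = 4L, n_dead = 6L),
    levels = list(
      background = 5,
      wall_morpho = 40, wall_tmrm = 20, wall_calcein = 150,
      nucleus_morpho = 200, pyknotic = 600, soma_tuj1 = 400,
      neurite_tuj1 = 200, th = 300,
      nucleus_mito = 150, cellmask = 600, mito = 200, tmrm_mito = 60,
      calcein = 400, nucleus_viability = 300, eh = 1000, cc3 = 600)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && nm %in% names(spec))
      spec[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else spec[[nm]] <- dots[[nm]]
  }
  need <- spec$geom$margin * 2L + spec$geom$wall_w * 2L + spec$geom$mc_w +
    spec$geom$pg_w + spec$geom$pc_w
  if (spec$nx != need)
    stop(sprintf("nx (%d) must equal the column budget of the geometry (%d)",
                 spec$nx, need))
  structure(spec, class = "fixture_spec")
}

chip_layout <- function(spec) {
  g <- spec$geom
  w1 <- g$margin + 1L
  mc1 <- w1 + g$wall_w
  pg1 <- mc1 + g$mc_w
  pc1 <- pg1 + g$pg_w
  w2 <- pc1 + g$pc_w
  list(wall1 = c(w1, mc1 - 1L), mc = c(mc1, pg1 - 1L),
       pg = c(pg1, pc1 - 1L), pc = c(pc1, w2 - 1L),
       wall2 = c(w2, w2 + g$wall_w - 1L))
}

# ---- voxel renderers --------------------------------------------------------

render_ellipsoid <- function(vol, center, rxy, rz, value) {
  d <- dim(vol)
  ys <- max(1L, floor(center[1] - rxy)):min(d[1], ceiling(center[1] + rxy))
  xs <- max(1L, floor(center[2] - rxy)):min(d[2], ceiling(center[2] + rxy))
  zs <- max(1L, floor(center[3] - rz)):min(d[3], ceiling(center[3] + rz))
  gy <- ((ys - center[1]) / rxy)^2
  gx <- ((xs - center[2]) / rxy)^2
  gz <- ((zs - center[3]) / max(rz, .Machine$double.eps))^2
  inside <- outer(outer(gy, gx, "+"), gz, "+") <= 1
  sub <- vol[ys, xs, zs, drop = FALSE]
  vol[ys, xs, zs] <- pmax(sub, inside * value)
  vol
}

render_line <- function(vol, p0, p1, radius, value) {
  len <- sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
  d <- dim(vol)
  for (t in ts) {
    p <- round(p0 + t * (p1 - p0))
    ys <- max(1L, p[1] - radius):min(d[1], p[1] + radius)
    xs <- max(1L, p[2] - radius):min(d[2], p[2] + radius)
    z <- min(max(1L, p[3]), d[3])
    vol[ys, xs, z] <- pmax(vol[ys, xs, z], value)
  }
  vol
}

# Rejection-sampled centres with a minimum pairwise (y, x) distance.
place_centers <- function(n, rows, cols, zs, dmin, max_tries = 500L,
                          existing = NULL) {
  pts <- existing
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      cand <- c(runif(1, rows[1], rows[2]), runif(1, cols[1], cols[2]),
                runif(1, zs[1], zs[2]))
      if (is.null(pts) ||
          all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >= dmin^2)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place objects without overlap; reduce counts or dmin")
    cand <- round(cand)
    pts <- rbind(pts, cand)
    out[i, ] <- cand
  }
  out
}

# A small neurite tree: trunk, a first branch point with two daughters, and a
# second branch point splitting the first daughter -- 2 nodes, 5 links.
generate_tree <- function(center, trunk_len = 16, branch_len = 11) {
  dirs <- function(angle) c(cos(angle), sin(angle), 0)
  base_angle <- runif(1, 0, 2 * pi)
  p0 <- center
  p1 <- p0 + trunk_len * dirs(base_angle)
  a1 <- base_angle + pi / 5; a2 <- base_angle - pi / 5
  p2 <- p1 + branch_len * dirs(a1)
  p3 <- p1 + branch_len * dirs(a2)
  p4 <- p2 + branch_len * dirs(a1 + pi / 5)
  p5 <- p2 + branch_len * dirs(a1 - pi / 5)
  list(segments = list(rbind(p0, p1), rbind(p1, p2), rbind(p1, p3),
                       rbind(p2, p4), rbind(p2, p5)),
       node_count = 2L, link_count = 5L)
}

blank_volume <- function(spec) {
  array(spec$levels$background, dim = c(spec$ny, spec$nx, spec$nz))
}

render_chip <- function(vol, spec, wall_value, pg_value = wall_value,
                        pg_only_low = TRUE) {
  lay <- chip_layout(spec)
  for (w in list(lay$wall1, lay$wall2))
    vol[, w[1]:w[2], ] <- pmax(vol[, w[1]:w[2], ], wall_value)
  zs <- if (pg_only_low) seq_len(min(spec$geom$pg_zmax, spec$nz)) else seq_len(spec$nz)
  vol[, lay$pg[1]:lay$pg[2], zs] <- pmax(vol[, lay$pg[1]:lay$pg[2], zs], pg_value)
  vol
}

add_noise <- function(vol, frac) {
  if (frac <= 0) return(vol)
  sdv <- frac * (max(vol) - min(vol))
  pmax(vol + array(rnorm(length(vol), 0, sdv), dim = dim(vol)), 0)
}

object_region <- function(spec, margin = spec$geom$obj_margin) {
  lay <- chip_layout(spec)
  g <- spec$geom
  list(rows = c(g$row_margin, spec$ny - g$row_margin),
       cols = c(lay$mc[1] + margin, lay$mc[2] - margin),
       zs = c(4, spec$nz - 3))
}

# Deterministic-capacity placement for elongated objects: one row-slot per
# object with a small jitter, so neighbouring trees can never overlap.
place_slots <- function(n, rows, cols, zs, jitter = 5) {
  edges <- seq(rows[1], rows[2], length.out = n + 1L)
  mid <- (head(edges, -1L) + tail(edges, -1L)) / 2
  cbind(round(mid + runif(n, -jitter, jitter)),
        round(runif(n, cols[1], cols[2])),
        round(runif(n, zs[1], zs[2])))
}

#' Render a synthetic multi-channel chip stack with ground truth
#'
#' Deterministic under `spec` plus `seed`. The returned ground truth records
#' the expected object counts of every downstream mask, the chip column
#' layout, and (for the morphometric assay) the node/link counts of each
#' generated neurite tree.
#'
#' @param spec A [fixture_spec()].
#' @param assay One of `"morpho"`, `"mito"`, `"viability"`.
#' @param seed Integer seed (mandatory).
#' @return List with `stack` (a [channel_stack]) and `truth` (list with
#'   `counts`, `layout`, and per-object bookkeeping).
#' @export
generate_chip_stack <- function(spec = fixture_spec(),
                                assay = c("morpho", "mito", "viability"),
                                seed) {
  assay <- match.arg(assay)
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  lay <- chip_layout(spec)
  reg <- object_region(spec, margin = 30L)    # blob-scale clearance
  reg_wide <- object_region(spec)             # clearance for the dilated
                                              # cell-death device mask
  lv <- spec$levels

  if (assay == "morpho") {
    hoechst <- render_chip(blank_volume(spec), spec, lv$wall_morpho)
    tuj1 <- render_chip(blank_volume(spec), spec, lv$wall_morpho)
    th <- render_chip(blank_volume(spec), spec, lv$wall_morpho)
    m647 <- render_chip(blank_volume(spec), spec, lv$wall_morpho)
    p <- spec$morpho

    nuc <- place_centers(p$n_nuclei, reg$rows, reg$cols, reg$zs, dmin = 26)
    pyk_idx <- seq_len(p$n_pyknotic)
    for (i in seq_len(p$n_nuclei)) {
      val <- if (i %in% pyk_idx) lv$pyknotic else lv$nucleus_morpho
      hoechst <- render_ellipsoid(hoechst, nuc[i, ], rxy = 5, rz = 3, val)
    }

    n_cells <- p$n_neurons + p$n_th
    tree_cols <- c(lay$mc[1] + 58L, lay$mc[2] - 58L)  # full tree span stays
                                                      # clear of the device
    cells <- place_slots(n_cells, reg$rows, tree_cols, reg$zs)
    trees <- list()
    for (i in seq_len(n_cells)) {
      is_th <- i > p$n_neurons
      tuj1 <- render_ellipsoid(tuj1, cells[i, ], rxy = 6, rz = 3, lv$soma_tuj1)
      tree <- generate_tree(cells[i, ])
      # proximal trunk is thick and soma-bright (caught by the global
      # threshold); distal branches are faint and thin (local threshold only)
      trunk <- tree$segments[[1]]
      tuj1 <- render_line(tuj1, trunk[1, ], trunk[2, ], 2L, lv$soma_tuj1)
      for (s in tree$segments[-1])
        tuj1 <- render_line(tuj1, s[1, ], s[2, ], 1L, lv$neurite_tuj1)
      if (is_th) {
        th <- render_ellipsoid(th, cells[i, ], rxy = 6, rz = 3, lv$th)
        for (s in tree$segments)
          th <- render_line(th, s[1, ], s[2, ], 1L, lv$th)
        trees[[length(trees) + 1L]] <-
          data.frame(node_count = tree$node_count, link_count = tree$link_count)
      }
    }
    chans <- list(hoechst = hoechst, tuj1 = tuj1, th = th, marker647 = m647)
    counts <- list(nuclei = p$n_nuclei, pyknotic = p$n_pyknotic,
                   neurons = n_cells, th = p$n_th)
    extra <- list(trees = do.call(rbind, trees))
  } else if (assay == "mito") {
    hoechst <- blank_volume(spec)
    mitotracker <- blank_volume(spec)
    tmrm <- render_chip(blank_volume(spec), spec, lv$wall_tmrm)
    cellmask <- blank_volume(spec)
    p <- spec$mito

    nuc <- place_centers(p$n_nuclei, reg$rows, reg$cols, reg$zs, dmin = 14)
    for (i in seq_len(p$n_nuclei))
      hoechst <- render_ellipsoid(hoechst, nuc[i, ], rxy = 5, rz = 3, lv$nucleus_mito)
    cells <- place_centers(p$n_cells, reg$rows, reg$cols, reg$zs, dmin = 70)
    for (i in seq_len(p$n_cells))
      cellmask <- render_ellipsoid(cellmask, cells[i, ], rxy = 8, rz = 3, lv$cellmask)
    mito <- place_centers(p$n_mito, reg$rows, reg$cols, reg$zs, dmin = 28)
    for (i in seq_len(p$n_mito)) {
      if (i %% 2L == 0L) {       # punctum
        r <- runif(1, 1.7, 2.8)
        mitotracker <- render_ellipsoid(mitotracker, mito[i, ], rxy = r, rz = min(r, 2), lv$mito)
        tmrm <- render_ellipsoid(tmrm, mito[i, ], rxy = r, rz = min(r, 2), lv$tmrm_mito)
      } else {                   # short rod
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, 4, 6)
        p1 <- mito[i, ] + len * c(cos(ang), sin(ang), 0)
        mitotracker <- render_line(mitotracker, mito[i, ], p1, 1L, lv$mito)
        tmrm <- render_line(tmrm, mito[i, ], p1, 1L, lv$tmrm_mito)
      }
    }
    chans <- list(hoechst = hoechst, mitotracker = mitotracker,
                  tmrm = tmrm, cellmask = cellmask)
    counts <- list(nuclei = p$n_nuclei, cells = p$n_cells, mito = p$n_mito)
    extra <- list(mito_centers = mito)
  } else {
    hoechst <- blank_volume(spec)
    calcein <- render_chip(blank_volume(spec), spec, lv$wall_calcein)
    eh <- blank_volume(spec)
    cc3 <- blank_volume(spec)
    p <- spec$viability
    if (p$n_cc3_live > p$n_live) stop("n_cc3_live cannot exceed n_live")

    n_cells <- p$n_live + p$n_dead
    cells <- place_centers(n_cells, reg_wide$rows, reg_wide$cols, reg_wide$zs,
                           dmin = 36)
    for (i in seq_len(n_cells)) {
      hoechst <- render_ellipsoid(hoechst, cells[i, ], rxy = 5, rz = 3,
                                  lv$nucleus_viability)
      if (i <= p$n_live) {       # calcein-positive (live); first n_cc3_live also CC3+
        calcein <- render_ellipsoid(calcein, cells[i, ], rxy = 8, rz = 3, lv$calcein)
        if (i <= p$n_cc3_live)
          cc3 <- render_ellipsoid(cc3, cells[i, ], rxy = 7, rz = 3, lv$cc3)
      } else {                   # dead: EH-positive nucleus, no calcein
        eh <- render_ellipsoid(eh, cells[i, ], rxy = 5, rz = 3, lv$eh)
      }
    }
    chans <- list(hoechst = hoechst, calcein = calcein, eh = eh, cc3 = cc3)
    counts <- list(nuclei = n_cells, live = p$n_live, eh = p$n_dead,
                   cc3 = p$n_cc3_live, cc3_live = p$n_cc3_live)
    extra <- list()
  }

  chans <- lapply(chans, add_noise, frac = spec$noise_frac)
  truth <- c(list(counts = counts, layout = lay, seed = seed, assay = assay),
             extra)
  list(stack = channel_stack(chans, assay = assay), truth = truth)
}

#' Simulate a per-bioreactor feature table with planted effects
#'
#' Features are multivariate Gaussian with unit variance, block correlation
#' structure, a planted mean deficit in mutant (`G2019S`) bioreactors, and a
#' planted fractional restoration in inhibitor-treated mutants. Four groups
#' (genotype x treatment) of `n_per_group` rows each are produced.
#'
#' @param n_per_group Rows per genotype-by-treatment group.
#' @param n_features Number of feature columns (`feat_01`, ...).
#' @param effect_sizes Mutant mean deficit per feature, in SD units; recycled
#'   to `n_features`.
#' @param rescue Fraction (0-1) of the deficit restored in treated mutants.
#' @param rho,block_size Correlation within consecutive feature blocks.
#' @param seed Integer seed.
#' @return List with `table` (`data.frame`) and `truth` (planted parameters).
#' @export
generate_feature_dataset <- function(n_per_group = 30, n_features = 10,
                                     effect_sizes = 0, rescue = 0,
                                     rho = 0, block_size = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  set.seed(seed)
  effect_sizes <- rep_len(effect_sizes, n_features)
  blocks <- rep(seq_len(ceiling(n_features / block_size)),
                each = block_size)[seq_len(n_features)]
  R <- outer(blocks, blocks, function(a, b) ifelse(a == b, 1, 0)) * rho
  diag(R) <- 1
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation structure is not positive definite"))
  grp <- expand.grid(genotype = c("WT", "G2019S"),
                     treatment = c("vehicle", "Inh2"),
                     stringsAsFactors = FALSE)
  rows <- list()
  for (gi in seq_len(nrow(grp))) {
    z <- matrix(rnorm(n_per_group * n_features), n_per_group) %*% ch
    shift <- if (grp$genotype[gi] == "WT") rep(0, n_features)
             else if (grp$treatment[gi] == "vehicle") -effect_sizes
             else -effect_sizes * (1 - rescue)
    z <- sweep(z, 2, shift, "+")
    df <- as.data.frame(z)
    names(df) <- sprintf("feat_%02d", seq_len(n_features))
    df <- cbind(data.frame(genotype = grp$genotype[gi],
                           treatment = grp$treatment[gi],
                           stringsAsFactors = FALSE), df)
    rows[[gi]] <- df
  }
  table <- do.call(rbind, rows)
  table <- cbind(data.frame(bioreactor_id = sprintf("B%03d", seq_len(nrow(table)))),
                 table)
  list(table = table,
       truth = list(effect_sizes = effect_sizes, rescue = rescue,
                    rho = rho, block_size = block_size, seed = seed))
}
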