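#' Build an injective surface-to-grid mapping
#'
#' Geometric reformatting: each hemisphere's spherical vertex coordinates are
#' projected to the plane with a Lambert azimuthal equal-area projection
#' centred on the lateral pole, scaled into the grid, and vertices are assigned
#' to the nearest free grid cell greedily (vertices in index order; for each
#' vertex an expanding ring search finds the free cell minimising the planar
#' distance, ties broken by row-major cell order). The assignment is injective
#' and deterministic, so forward + inverse reformatting is the identity on
#' assigned vertices. Medial-wall vertices are left unassigned.
#'
#' @param mesh a `cortical_mesh`.
#' @param grid_shape integer c(H, W) per hemisphere; `H*W` must be at least the
#'   number of non-medial vertices per hemisphere.
#' @return an object of class `grid_mapping` with per-hemisphere assignment
#'   tables (`vertex`, `row`, `col`), validity masks (H x W logical), `H`, `W`
#'   and `mesh_id`.
#' @export
build_grid_mapping <- function(mesh, grid_shape = c(32L, 32L)) {
  stopifnot(inherits(mesh, "cortical_mesh"), length(grid_shape) == 2)
  H <- as.integer(grid_shape[1]); W <- as.integer(grid_shape[2])
  hemis <- list(L = which(mesh$hemisphere == "L" & !mesh$medial_mask),
                R = which(mesh$hemisphere == "R" & !mesh$medial_mask))
  need <- max(lengths(hemis))
  if (H * W < need)
    stop_dim("grid %dx%d too small: needs at least %d cells per hemisphere",
             H, W, need)
  assign_hemi <- function(idx, side) {
    v <- mesh$vertices[idx, , drop = FALSE]
    ctr <- colMeans(mesh$vertices[mesh$hemisphere == side, , drop = FALSE])
    u <- sweep(v, 2, ctr)
    u <- u / sqrt(rowSums(u^2))
    # lateral pole: -x for left hemisphere, +x for right (medial wall faces in)
    axis <- if (side == "L") c(-1, 0, 0) else c(1, 0, 0)
    ct <- pmin(1, pmax(-1, u %*% axis))           # cos(theta) to lateral pole
    rho <- 2 * sin(acos(ct) / 2)                  # Lambert equal-area radius
    # tangent-plane direction from (y, z)
    yz <- u[, 2:3, drop = FALSE]
    nrm <- sqrt(rowSums(yz^2)); nrm[nrm < 1e-12] <- 1
    xy <- yz / nrm * rho                          # in disk of radius 2
    # scale disk into the grid (cell units), centre of grid at (H+1)/2,(W+1)/2
    half <- (min(H, W) - 1) / 2
    rr <- (H + 1) / 2 + xy[, 2] / 2 * half        # z -> rows
    cc <- (W + 1) / 2 + xy[, 1] / 2 * half        # y -> cols
    greedy_assign(idx, rr, cc, H, W)
  }
  maps <- list(L = assign_hemi(hemis$L, "L"), R = assign_hemi(hemis$R, "R"))
  valid <- lapply(maps, function(m) {
    v <- matrix(FALSE, H, W); v[cbind(m$row, m$col)] <- TRUE; v
  })
  structure(list(assignment = maps, valid = valid, H = H, W = W,
                 mesh_id = mesh$mesh_id),
            class = "grid_mapping")
}

## greedy nearest-free-cell assignment via expanding Chebyshev rings
greedy_assign <- function(idx, rr, cc, H, W) {
  n <- length(idx)
  free <- matrix(TRUE, H, W)
  out_r <- integer(n); out_c <- integer(n)
  max_ring <- max(H, W)
  for (i in seq_len(n)) {
    r0 <- min(H, max(1L, as.integer(round(rr[i]))))
    c0 <- min(W, max(1L, as.integer(round(cc[i]))))
    best <- NULL; best_d <- Inf
    for (ring in 0:max_ring) {
      # once the closest found free cell is nearer than any cell in this ring
      # can be, stop expanding
      if (best_d < (ring - 1)) break
      cells <- ring_cells(r0, c0, ring, H, W)
      if (is.null(cells)) next
      f <- free[cells]
      if (!any(f)) next
      cand <- cells[f, , drop = FALSE]
      d <- sqrt((cand[, 1] - rr[i])^2 + (cand[, 2] - cc[i])^2)
      j <- order(d, (cand[, 1] - 1) * W + cand[, 2])[1]  # row-major tie-break
      if (d[j] < best_d - 1e-12) { best_d <- d[j]; best <- cand[j, ] }
    }
    if (is.null(best)) stop("greedy_assign: no free cell found", call. = FALSE)
    free[best[1], best[2]] <- FALSE
    out_r[i] <- best[1]; out_c[i] <- best[2]
  }
  data.frame(vertex = idx, row = out_r, col = out_c)
}

ring_cells <- function(r0, c0, ring, H, W) {
  if (ring == 0) {
    cells <- cbind(r0, c0)
  } else {
    rs <- (r0 - ring):(r0 + ring)
    top <- cbind(r0 - ring, (c0 - ring):(c0 + ring))
    bot <- cbind(r0 + ring, (c0 - ring):(c0 + ring))
    lef <- cbind((r0 - ring + 1):(r0 + ring - 1), c0 - ring)
    rig <- cbind((r0 - ring + 1):(r0 + ring - 1), c0 + ring)
    cells <- rbind(top, bot, lef, rig)
  }
  keep <- cells[, 1] >= 1 & cells[, 1] <= H & cells[, 2] >= 1 & cells[, 2] <= W
  if (!any(keep)) return(NULL)
  cells[keep, , drop = FALSE]
}

## per-hemisphere linear indices: grid cell (r, c) of hemi h <-> vertex
mapping_linear_index <- function(mapping) {
  lapply(mapping$assignment, function(m)
    list(vertex = m$vertex, cell = (m$col - 1L) * mapping$H + m$row))
}

#' Reformat a cortical timeseries to grid frames
#'
#' Produces a `grid_sequence`: a `T x H x W x 2` array (channel 1 = left
#' hemisphere, channel 2 = right). Cells without an assigned vertex are exactly
#' zero and flagged invalid in the validity mask.
#'
#' @param ts a `cortical_ts` on the mesh the mapping was built for.
#' @param mapping a `grid_mapping`.
#' @return an object of class `grid_sequence` with fields `frames`
#'   (T x H x W x 2), `valid` (H x W x 2), `mapping_id`.
#' @export
to_grid <- function(ts, mapping) {
  stopifnot(inherits(ts, "cortical_ts"), inherits(mapping, "grid_mapping"))
  if (!identical(ts$mesh_id, mapping$mesh_id))
    stop_dim("to_grid: ts mesh '%s' does not match mapping mesh '%s'",
             ts$mesh_id, mapping$mesh_id)
  Tn <- ncol(ts$values); H <- mapping$H; W <- mapping$W
  li <- mapping_linear_index(mapping)
  frames <- array(0, c(Tn, H, W, 2))
  for (h in 1:2) {
    sub <- ts$values[li[[h]]$vertex, , drop = FALSE]  # n_assigned x T
    plane <- matrix(0, H * W, Tn)
    plane[li[[h]]$cell, ] <- sub
    frames[, , , h] <- aperm(array(plane, c(H, W, Tn)), c(3, 1, 2))
  }
  valid <- array(FALSE, c(H, W, 2))
  valid[, , 1] <- mapping$valid$L; valid[, , 2] <- mapping$valid$R
  structure(list(frames = frames, valid = valid, mapping_id = mapping$mesh_id),
            class = "grid_sequence")
}

#' Inverse reformatting: grid frames back to the cortical surface
#'
#' Every assigned vertex takes the value of its grid cell; medial (unassigned)
#' vertices are zero. `from_grid(to_grid(x))` equals `x` exactly on assigned
#' vertices.
#'
#' @param grid a `grid_sequence` (or a plain `T x H x W x 2` array).
#' @param mapping the `grid_mapping` the sequence was built with.
#' @param n_vertices total vertex count of the mesh.
#' @return numeric matrix V x T.
#' @export
from_grid <- function(grid, mapping, n_vertices) {
  frames <- if (inherits(grid, "grid_sequence")) grid$frames else grid
  if (length(dim(frames)) != 4 || dim(frames)[2] != mapping$H ||
      dim(frames)[3] != mapping$W || dim(frames)[4] != 2)
    stop_dim("from_grid: frames must be T x %d x %d x 2", mapping$H, mapping$W)
  Tn <- dim(frames)[1]; H <- mapping$H; W <- mapping$W
  li <- mapping_linear_index(mapping)
  X <- matrix(0, n_vertices, Tn)
  for (h in 1:2) {
    f3 <- frames[, , , h, drop = FALSE]
    dim(f3) <- dim(f3)[1:3]
    plane <- matrix(aperm(f3, c(2, 3, 1)), H * W, Tn)
    X[li[[h]]$vertex, ] <- plane[li[[h]]$cell, , drop = FALSE]
  }
  X
}

#' Flatten grid frames into the VAE batch layout
#'
#' Converts a `grid_sequence` (or `T x H x W x 2` array) into the `T x D`
#' matrix consumed by [train_vae()] and [encode()] (channel-major columns:
#' hemisphere blocks of `H*W`, row-major positions within a block).
#'
#' @param frames a `grid_sequence` or 4-d array.
#' @return numeric matrix, frames x cells.
#' @export
grid_to_batch <- function(frames) {
  if (inherits(frames, "grid_sequence")) frames <- frames$frames
  d <- dim(frames)
  Tn <- d[1]; H <- d[2]; W <- d[3]
  # position index pos = (r-1)*W + c, column = (ch-1)*H*W + pos
  out <- matrix(0, Tn, H * W * 2)
  for (h in 1:2) {
    f3 <- frames[, , , h, drop = FALSE]
    dim(f3) <- d[1:3]
    pl <- matrix(aperm(f3, c(3, 2, 1)), W * H, Tn)  # pos fastest: c within r
    out[, (h - 1) * H * W + seq_len(H * W)] <- t(pl)
  }
  out
}

batch_to_grid <- function(batch, H, W, valid = NULL) {
  Tn <- nrow(batch)
  frames <- array(0, c(Tn, H, W, 2))
  for (h in 1:2) {
    pl <- t(batch[, (h - 1) * H * W + seq_len(H * W), drop = FALSE])  # pos x T
    frames[, , , h] <- aperm(array(pl, c(W, H, Tn)), c(3, 2, 1))
  }
  structure(list(frames = frames, valid = valid, mapping_id = NULL),
            class = "grid_sequence")
}

## validity mask in batch layout (length 2*H*W logical)
valid_to_batch <- function(valid) {
  H <- dim(valid)[1]; W <- dim(valid)[2]
  c(as.vector(t(valid[, , 1])), as.vector(t(valid[, , 2])))
}
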