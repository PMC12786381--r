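## Deterministic six-view orthographic ball-and-stick rasterizer.

.covalentRadius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)

.cpkPalette <- list(
  H = c(1, 1, 1), C = c(0.4, 0.4, 0.4), N = c(0.19, 0.31, 0.97),
  O = c(1, 0.05, 0.05), S = c(1, 1, 0.19), P = c(1, 0.5, 0),
  F = c(0.2, 0.8, 0.2), Cl = c(0.12, 0.94, 0.12), Br = c(0.65, 0.16, 0.16),
  I = c(0.58, 0, 0.58))
.cpkDefault <- c(1, 0.08, 0.58)   # fallback for uncatalogued elements

#' Rendering style for the six-view rasterizer
#'
#' @param atom_radius_scale sphere radius as a fraction of the element's
#'   covalent radius.
#' @param bond_width bond line width in pixels.
#' @param palette named list of element -> RGB (0-1) triples; elements not
#'   covered fall back to a default color.
#' @param background length-4 RGBA background (default transparent black).
#' @return list of class "RenderStyle".
#' @export
renderStyle <- function(atom_radius_scale = 0.8, bond_width = 3,
                        palette = .cpkPalette,
                        background = c(0, 0, 0, 0)) {
  stopifnot(atom_radius_scale > 0, bond_width > 0, length(background) == 4)
  structure(list(atom_radius_scale = atom_radius_scale,
                 bond_width = bond_width, palette = palette,
                 background = background),
            class = "RenderStyle")
}

## View frames: rows are the world-axis expansion of (right, up, near).
## Opposite views are exact horizontal mirrors of each other.
.viewFrames <- list(
  front  = rbind(right = c( 1, 0, 0), up = c(0,  1, 0), near = c(0, 0,  1)),
  right  = rbind(right = c( 0, 0,-1), up = c(0,  1, 0), near = c(1, 0,  0)),
  back   = rbind(right = c(-1, 0, 0), up = c(0,  1, 0), near = c(0, 0, -1)),
  bottom = rbind(right = c(-1, 0, 0), up = c(0,  0,-1), near = c(0, -1, 0)),
  top    = rbind(right = c( 1, 0, 0), up = c(0,  0,-1), near = c(0,  1, 0)),
  left   = rbind(right = c( 0, 0, 1), up = c(0,  1, 0), near = c(-1, 0, 0)))

#' Canonically orient a conformer
#'
#' Centers the atomic point cloud at the origin and aligns its principal
#' axes with x, y, z (largest variance on x). Degenerate principal
#' subspaces (spherical or cylindrical point clouds) are re-fixed
#' deterministically using the atoms furthest from the centroid, and axis
#' signs are chosen so the furthest atom has non-negative x and y; z
#' completes a right-handed frame so that reflections are never
#' introduced and enantiomers stay distinct. The result is identical (to
#' tolerance) for any rotation of the same conformer.
#'
#' @param mol a \linkS4class{MoleculeRecord} with a conformer.
#' @return the record with transformed coordinates.
#' @export
canonicalOrient <- function(mol) {
  stopifnot(is(mol, "MoleculeRecord"))
  x <- mol@coords
  if (nrow(x) == 0)
    stopMv("RenderError", "molecule '%s' has no conformer", mol@id)
  x <- sweep(x, 2, colMeans(x))
  if (nrow(x) == 1) {
    mol@coords <- x
    return(mol)
  }
  cv <- crossprod(x) / nrow(x)
  eg <- eigen(cv, symmetric = TRUE)
  E <- eg$vectors  # columns = axes, eigenvalues descending
  ev <- eg$values
  ## deterministic atom order: decreasing distance, then index
  d <- sqrt(rowSums(x^2))
  ord <- order(-round(d, 8), seq_along(d))
  tol <- 1e-6
  ## re-fix basis inside (near-)degenerate eigenvalue blocks using
  ## projections of the furthest atoms (Gram-Schmidt)
  blocks <- split(seq_len(3), cumsum(c(1, abs(diff(ev)) >
                                            tol * max(abs(ev), 1))))
  for (blk in blocks) {
    if (length(blk) < 2) next
    P <- E[, blk, drop = FALSE]          # basis of the degenerate subspace
    B <- matrix(0, 3, 0)
    for (a in ord) {
      v <- P %*% crossprod(P, x[a, ])    # projection into the subspace
      v <- v - B %*% crossprod(B, v)     # orthogonal to axes fixed so far
      if (sqrt(sum(v^2)) > 1e-4) B <- cbind(B, v / sqrt(sum(v^2)))
      if (ncol(B) == length(blk)) break
    }
    while (ncol(B) < length(blk)) {      # point cloud itself degenerate
      for (k in seq_len(3)) {
        v <- P %*% crossprod(P, diag(3)[, k])
        v <- v - B %*% crossprod(B, v)
        if (sqrt(sum(v^2)) > 1e-8) {
          B <- cbind(B, v / sqrt(sum(v^2)))
          break
        }
      }
    }
    E[, blk] <- B
  }
  y <- x %*% E
  ## axis signs from the furthest atoms; z completes right-handed frame
  for (k in 1:2) {
    s <- 0
    for (a in ord) {
      if (abs(y[a, k]) > 1e-4) { s <- sign(y[a, k]); break }
    }
    if (s < 0) { E[, k] <- -E[, k]; y[, k] <- -y[, k] }
  }
  e3 <- c(E[2, 1] * E[3, 2] - E[3, 1] * E[2, 2],
          E[3, 1] * E[1, 2] - E[1, 1] * E[3, 2],
          E[1, 1] * E[2, 2] - E[2, 1] * E[1, 2])
  if (sum(e3 * E[, 3]) < 0) y[, 3] <- -y[, 3]
  mol@coords <- y
  mol
}

atomColor <- function(elem, palette) {
  col <- palette[[elem]]
  if (is.null(col)) .cpkDefault else col
}

#' Render six orthogonal ball-and-stick views
#'
#' Orthographic projections of a (canonically oriented) conformer along
#' the six axis directions, in the fixed order front, right, back,
#' bottom, top, left. Atoms are filled CPK-colored discs, bonds thick
#' gray lines; elements are painted far-to-near (painter's algorithm).
#' The molecule's bounding sphere is scaled to 90% of the image
#' half-width, identically across views. The output is a
#' \linkS4class{ViewTensor} (4 x 6 x H x W, RGB + alpha/occupancy);
#' rendering is a pure function of its inputs.
#'
#' @param mol oriented \linkS4class{MoleculeRecord} with conformer.
#' @param H,W image height/width in pixels (>= 16).
#' @param style a \code{\link{renderStyle}}.
#' @return a \linkS4class{ViewTensor}.
#' @export
renderViews <- function(mol, H = 64L, W = 64L, style = renderStyle()) {
  stopifnot(is(mol, "MoleculeRecord"), H >= 16, W >= 16)
  x <- mol@coords
  if (nrow(x) == 0)
    stopMv("RenderError", "molecule '%s' has no conformer", mol@id)
  elems <- mol@elements
  rads <- unname(.covalentRadius[elems])
  rads[is.na(rads)] <- 1.0
  rads <- rads * style$atom_radius_scale
  bound <- max(sqrt(rowSums(x^2)) + rads)
  scale <- 0.9 * (min(H, W) / 2) / max(bound, 1e-6)
  data <- array(0, c(4, 6, H, W))
  for (ch in 1:4) data[ch, , , ] <- style$background[ch]
  for (v in seq_along(.viewFrames)) {
    fr <- .viewFrames[[v]]
    p <- x %*% t(fr)                       # columns: right, up, near
    px <- p[, 1] * scale + (W + 1) / 2
    py <- (H + 1) / 2 - p[, 2] * scale
    depth <- p[, 3]
    img <- matrix(rep(style$background, each = H * W), H * W, 4)
    ## draw list: bonds + atoms, far first
    items <- list()
    b <- mol@bonds
    if (nrow(b) > 0) for (r in seq_len(nrow(b)))
      items[[length(items) + 1]] <-
        list(kind = "bond", i = b[r, 1], j = b[r, 2],
             depth = (depth[b[r, 1]] + depth[b[r, 2]]) / 2)
    for (a in seq_len(nrow(x)))
      items[[length(items) + 1]] <- list(kind = "atom", i = a,
                                         depth = depth[a])
    dep <- vapply(items, `[[`, numeric(1), "depth")
    for (it in items[order(dep, seq_along(items))]) {
      if (it$kind == "atom") {
        a <- it$i
        rpx <- rads[a] * scale
        rows <- max(1, floor(py[a] - rpx)):min(H, ceiling(py[a] + rpx))
        cols <- max(1, floor(px[a] - rpx)):min(W, ceiling(px[a] + rpx))
        if (py[a] + rpx < 1 || py[a] - rpx > H ||
            px[a] + rpx < 1 || px[a] - rpx > W) next
        dy <- rows - py[a]; dx <- cols - px[a]
        mask <- outer(dy^2, dx^2, "+") <= rpx^2
        idx <- (rep(cols - 1L, each = length(rows)) * H + rows)[mask]
        if (length(idx) == 0) next
        col3 <- atomColor(elems[a], style$palette)
        img[idx, 1] <- col3[1]; img[idx, 2] <- col3[2]
        img[idx, 3] <- col3[3]; img[idx, 4] <- 1
      } else {
        i <- it$i; j <- it$j
        hw <- style$bond_width / 2
        rows <- max(1, floor(min(py[i], py[j]) - hw)):
                min(H, ceiling(max(py[i], py[j]) + hw))
        cols <- max(1, floor(min(px[i], px[j]) - hw)):
                min(W, ceiling(max(px[i], px[j]) + hw))
        if (length(rows) == 0 || length(cols) == 0) next
        gx <- rep(cols, each = length(rows)); gy <- rep(rows, length(cols))
        ex <- px[j] - px[i]; ey <- py[j] - py[i]
        len2 <- ex^2 + ey^2
        t <- if (len2 < 1e-12) rep(0, length(gx))
             else pmin(1, pmax(0, ((gx - px[i]) * ex + (gy - py[i]) * ey) /
                                 len2))
        dist2 <- (gx - (px[i] + t * ex))^2 + (gy - (py[i] + t * ey))^2
        sel <- dist2 <= hw^2
        idx <- ((gx - 1L) * H + gy)[sel]
        if (length(idx) == 0) next
        img[idx, 1] <- 0.55; img[idx, 2] <- 0.55
        img[idx, 3] <- 0.55; img[idx, 4] <- 1
      }
    }
    for (ch in 1:4) data[ch, v, , ] <- matrix(img[, ch], H, W)
  }
  new("ViewTensor", data = data)
}

#' Export individual views as PNG files
#'
#' @param t a \linkS4class{ViewTensor}.
#' @param prefix output path prefix; files are
#'   \code{<prefix>_<view>.png}.
#' @return invisibly, the written file paths.
#' @export
writeViewPngs <- function(t, prefix) {
  stopifnot(is(t, "ViewTensor"))
  d <- t@data
  paths <- character(0)
  for (v in seq_len(6)) {
    img <- aperm(d[, v, , ], c(2, 3, 1))   # H x W x 4
    path <- paste0(prefix, "_", t@viewOrder[v], ".png")
    png::writePNG(img, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
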