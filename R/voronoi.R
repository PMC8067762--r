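## 3D Voronoi cell volumes for atoms in an orthorhombic box.
##
## Each cell is the intersection of bisector half-spaces between the site and
## its (periodic images of) neighbours. Vertices are enumerated by solving all
## plane triples (vectorized Cramer's rule) over a distance-pruned candidate
## set: once the cell's circumradius R is known, any bisector whose half
## distance exceeds R cannot cut the cell, so planes are added in increasing
## distance order until that criterion stabilizes. Volumes come from fanning
## each face into pyramids over the site, which lies strictly inside its cell.

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## Cached triple-index matrices: choose(K, 3) combinations reused per K.
.triple_cache <- new.env(parent = emptyenv())
plane_triples <- function(K) {
  key <- as.character(K)
  if (is.null(.triple_cache[[key]]))
    .triple_cache[[key]] <- t(utils::combn(K, 3L))
  .triple_cache[[key]]
}

## Vertices of {x : A x <= b}, A unit rows. Returns matrix (possibly 0-row).
halfspace_vertices <- function(A, b, scale) {
  K <- nrow(A)
  if (K < 4L) return(matrix(numeric(0), 0L, 3L))
  idx <- plane_triples(K)
  n1 <- A[idx[, 1], , drop = FALSE]
  n2 <- A[idx[, 2], , drop = FALSE]
  n3 <- A[idx[, 3], , drop = FALSE]
  c23 <- rowcross(n2, n3)
  dets <- rowSums(n1 * c23)
  ok <- abs(dets) > 1e-10
  if (!any(ok)) return(matrix(numeric(0), 0L, 3L))
  idx <- idx[ok, , drop = FALSE]
  n1 <- n1[ok, , drop = FALSE]; n2 <- n2[ok, , drop = FALSE]
  n3 <- n3[ok, , drop = FALSE]; c23 <- c23[ok, , drop = FALSE]
  dets <- dets[ok]
  b1 <- b[idx[, 1]]; b2 <- b[idx[, 2]]; b3 <- b[idx[, 3]]
  V <- (b1 * c23 + b2 * rowcross(n3, n1) + b3 * rowcross(n1, n2)) / dets
  feas <- tcrossprod(V, A)
  keep <- rowSums(feas > matrix(b + 1e-8 * scale, nrow(V), K,
                                byrow = TRUE)) == 0L
  V <- V[keep, , drop = FALSE]
  if (nrow(V) == 0L) return(V)
  V[!duplicated(round(V / (1e-7 * scale))), , drop = FALSE]
}

## Volume of the convex polyhedron with vertex set V (origin strictly inside)
## whose faces lie on the planes (A, b).
polyhedron_volume <- function(V, A, b, scale) {
  vol <- 0
  resid <- abs(V %*% t(A) - rep(b, each = nrow(V)))
  seen <- character(0)   # near-duplicate planes must not claim a face twice
  for (k in seq_len(nrow(A))) {
    on_face <- which(resid[, k] <= 1e-6 * scale)
    if (length(on_face) < 3L) next
    key <- paste(on_face, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    W <- V[on_face, , drop = FALSE]
    nrm <- A[k, ]
    # orthonormal in-plane basis for angular ordering
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * nrm) * nrm; u <- u / sqrt(sum(u^2))
    v <- c(nrm[2] * u[3] - nrm[3] * u[2],
           nrm[3] * u[1] - nrm[1] * u[3],
           nrm[1] * u[2] - nrm[2] * u[1])
    cen <- colMeans(W)
    ang <- atan2((W - rep(cen, each = nrow(W))) %*% v,
                 (W - rep(cen, each = nrow(W))) %*% u)
    W <- W[order(ang), , drop = FALSE]
    m <- nrow(W)
    nxt <- c(2:m, 1L)
    # tetrahedra (origin, cen, W_j, W_j+1); origin inside => constant sign
    for (j in seq_len(m)) {
      M <- rbind(cen, W[j, ], W[nxt[j], ])
      vol <- vol + abs(det(M)) / 6
    }
  }
  vol
}

voronoi_cell_volume <- function(center_offsets, halfdist, scale, extra_A = NULL,
                                extra_b = NULL) {
  ord <- order(halfdist)
  center_offsets <- center_offsets[ord, , drop = FALSE]
  halfdist <- halfdist[ord]
  An <- center_offsets / sqrt(rowSums(center_offsets^2))
  # bounding cube keeps the enumeration finite before pruning converges
  cube_A <- rbind(diag(3), -diag(3))
  cube_b <- rep(scale, 6L)
  K <- min(length(halfdist), 40L)
  repeat {
    A <- rbind(An[seq_len(K), , drop = FALSE], cube_A, extra_A)
    b <- c(halfdist[seq_len(K)], cube_b, extra_b)
    V <- halfspace_vertices(A, b, scale)
    if (nrow(V) < 4L) stop("degenerate Voronoi cell (no volume)")
    R <- sqrt(max(rowSums(V^2)))
    needed <- sum(halfdist <= R + 1e-8 * scale)
    if (needed <= K || K == length(halfdist)) {
      return(polyhedron_volume(V, A, b, scale))
    }
    K <- min(length(halfdist), max(needed, 2L * K))
  }
}

#' Per-atom Voronoi cell volumes
#'
#' Tessellates the frame's box by the Voronoi diagram of the atom positions
#' and returns each atom's cell volume. With `periodic = TRUE` (the default)
#' the tessellation is periodic in all three directions and the volumes sum
#' exactly to the box volume; with `periodic = FALSE` cells are clipped to
#' the box, an approximation appropriate for non-periodic runs (volumes still
#' partition the box).
#'
#' Coincident atom positions make the tessellation degenerate; such atoms are
#' jittered by 1e-6 Angstrom under a fixed seed, with a warning, rather than
#' failing the extraction.
#'
#' @param frame an [atom_frame].
#' @param periodic logical; periodic tessellation (default) or box-clipped.
#' @return numeric vector of volumes (A^3), one per atom in id order.
#' @export
voronoi_volumes <- function(frame, periodic = TRUE) {
  X <- frame$coords
  n <- nrow(X)
  if (n < 1L) stop_param("frame has no atoms")
  lo <- frame$box_bounds[, 1]; hi <- frame$box_bounds[, 2]
  L <- hi - lo
  scale <- max(L)
  # wrap into the box for tessellation purposes
  Xw <- sweep(sweep(X, 2L, lo), 2L, L, "%%")
  Xw <- sweep(Xw, 2L, lo, "+")
  # coincident-site degeneracy: jitter deterministically and warn
  if (n > 1L) {
    dup <- rep(FALSE, n)
    for (i in 2:n) {
      d <- sweep(Xw[seq_len(i - 1L), , drop = FALSE], 2L, Xw[i, ])
      if (periodic) d <- d - sweep(round(sweep(d, 2L, L, "/")), 2L, L, "*")
      if (min(rowSums(d^2)) < 1e-16) dup[i] <- TRUE
    }
    if (any(dup)) {
      warning(sum(dup), " coincident atom position(s) jittered by 1e-6 A",
              call. = FALSE)
      Xw[dup, ] <- Xw[dup, ] + with_seed(20210407,
        matrix(runif(3 * sum(dup), -1e-6, 1e-6), ncol = 3L))
    }
  }
  offs <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))
  vols <- numeric(n)
  for (i in seq_len(n)) {
    if (periodic) {
      gen <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        sweep(Xw, 2L, offs[k, ] * L, "+")))
      gen <- sweep(gen, 2L, Xw[i, ])
      keep <- rowSums(gen^2) > 1e-16   # drop the site itself
      gen <- gen[keep, , drop = FALSE]
      hd <- sqrt(rowSums(gen^2)) / 2
      vols[i] <- voronoi_cell_volume(gen, hd, scale)
    } else {
      extra_A <- rbind(diag(3), -diag(3))
      extra_b <- c(hi - Xw[i, ], Xw[i, ] - lo)
      if (n == 1L) {
        # whole box
        A <- extra_A
        V <- halfspace_vertices(A, extra_b, scale)
        vols[i] <- polyhedron_volume(V, A, extra_b, scale)
      } else {
        gen <- sweep(Xw[-i, , drop = FALSE], 2L, Xw[i, ])
        hd <- sqrt(rowSums(gen^2)) / 2
        vols[i] <- voronoi_cell_volume(gen, hd, scale, extra_A, extra_b)
      }
    }
  }
  vols
}
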