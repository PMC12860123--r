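# Low-level binary-image primitives shared by the measurement modules.
# Masks are plain logical matrices (row = image row, col = image column,
# 0-based physical coordinates are never needed: a pixel is a unit square and
# one pixel edge = pixel_size_nm).

#' @importFrom EBImage Image imageData distmap dilate erode closing opening
#'   ocontour fillHull
NULL

# Chain-length correction for digitized contours: the (1, sqrt 2) Freeman chain
# overestimates isotropically oriented smooth boundaries by (8/pi)(sqrt2 - 1);
# multiplying by the reciprocal removes the bias (Kulpa's estimator).
KULPA_FACTOR <- 1 / ((8 / pi) * (sqrt(2) - 1))

# shift a numeric/integer/logical matrix by (dr, dc), zero-filling
mat_shift <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(vector(typeof(m), 1L), nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# number of foreground 8-neighbours at every pixel (0 outside the mask)
neighbor_count <- function(mask) {
  s <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  tot <- matrix(0L, nrow(s), ncol(s))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr != 0L || dc != 0L) tot <- tot + mat_shift(s, dr, dc)
    }
  }
  tot[!mask] <- 0L
  tot
}

# disk structuring element rasterized as {(r, c): r^2 + c^2 <= R^2}
disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  stopifnot(r >= 1L)
  off <- -r:r
  k <- outer(off^2, off^2, "+") <= radius_px^2
  matrix(as.numeric(k), 2L * r + 1L, 2L * r + 1L)
}

# 3x3 square structuring element (8-connected unit dilation)
box_kernel <- function() matrix(1, 3L, 3L)

dilate_mask <- function(mask, kern, iterations = 1L) {
  m <- Image(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, kern)
  imageData(m) > 0.5
}

close_mask <- function(mask, kern) {
  m <- Image(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  imageData(EBImage::closing(m, kern)) > 0.5
}

open_image <- function(img, kern) {
  imageData(EBImage::opening(Image(img), kern))
}

fill_holes <- function(mask) {
  m <- Image(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  imageData(EBImage::fillHull(m)) > 0.5
}

# exact Euclidean distance transform: distance (px) from each foreground pixel
# to the nearest background pixel; 0 on the background
euclidean_dt <- function(mask) {
  d <- distmap(Image(matrix(as.numeric(mask), nrow(mask), ncol(mask))),
               metric = "euclidean")
  imageData(d)
}

# connected-component labeling (4- or 8-connectivity) via the pixel adjacency
# graph; returns an integer matrix, 0 = background, components numbered from 1
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(out)
  nr <- nrow(mask)
  pos <- match(idx, idx) # 1..n
  lut <- integer(length(mask))
  lut[idx] <- pos
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (o in offs) {
    r2 <- rr + o[1L]
    c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(mask)
    j <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[j] > 0L
    if (any(hit)) {
      edges <- rbind(edges, cbind(pos[ok][hit], lut[j][hit]))
    }
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    out[idx] <- seq_along(idx)
    return(out)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber components in first-pixel order for determinism
  first <- tapply(seq_along(idx), comp, min)
  renum <- integer(length(first))
  renum[order(first)] <- seq_along(first)
  out[idx] <- renum[comp]
  out
}

# Guo-Hall two-subiteration thinning: one-pixel-wide, topology-preserving,
# 8-connected skeleton (clean diagonals, unlike Zhang-Suen)
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (parity in 0:1) {
      N <- mat_shift(m, 1L, 0L); NE <- mat_shift(m, 1L, -1L)
      E <- mat_shift(m, 0L, -1L); SE <- mat_shift(m, -1L, -1L)
      S <- mat_shift(m, -1L, 0L); SW <- mat_shift(m, -1L, 1L)
      W <- mat_shift(m, 0L, 1L); NW <- mat_shift(m, 1L, 1L)
      C <- ((1L - N) * (NE | E)) + ((1L - E) * (SE | S)) +
        ((1L - S) * (SW | W)) + ((1L - W) * (NW | N))
      n1 <- (NW | N) + (NE | E) + (SE | S) + (SW | W)
      n2 <- (N | NE) + (E | SE) + (S | SW) + (W | NW)
      nm <- pmin(n1, n2)
      if (parity == 0L) {
        cond <- ((N | NE | (1L - SE)) & E) == 0L
      } else {
        cond <- ((S | SW | (1L - NW)) & W) == 0L
      }
      del <- m == 1L & C == 1L & nm >= 2L & nm <= 3L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cleanup_skeleton(m == 1L)
}

# ring offsets (clockwise) and pixel adjacency between ring positions
.ring_off <- rbind(
  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)
)
.ring_adj <- {
  a <- matrix(FALSE, 8L, 8L)
  for (i in 1:8) for (j in 1:8) {
    if (i != j) a[i, j] <- max(abs(.ring_off[i, ] - .ring_off[j, ])) == 1L
  }
  a
}

# number of 8-connected components formed by the foreground ring pixels
.ring_components <- function(vals) {
  idx <- which(vals)
  n <- length(idx)
  if (n == 0L) return(0L)
  seen <- logical(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    q <- s
    seen[s] <- TRUE
    while (length(q)) {
      cur <- q[[1L]]
      q <- q[-1L]
      for (t in seq_len(n)) {
        if (!seen[t] && .ring_adj[idx[cur], idx[t]]) {
          seen[t] <- TRUE
          q <- c(q, t)
        }
      }
    }
  }
  ncomp
}

# remove residual 8-simple pixels (staircase redundancy): a pixel with >= 2
# neighbours whose foreground neighbourhood is a single 8-connected blob can
# be deleted without changing topology; processed sequentially until stable
cleanup_skeleton <- function(sk) {
  nr <- nrow(sk)
  nc <- ncol(sk)
  repeat {
    removed <- FALSE
    for (idx in which(sk)) {
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      if (r < 2L || c < 2L || r > nr - 1L || c > nc - 1L) next
      vals <- sk[cbind(r + .ring_off[, 1L], c + .ring_off[, 2L])]
      if (sum(vals) < 2L) next
      if (.ring_components(vals) == 1L) {
        sk[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

# Perimeter of the (single filled) foreground region: oriented contour chain
# with unit axis steps and sqrt(2) diagonal steps, optionally Kulpa-corrected.
# Degenerate regions (< 3 contour points) fall back to crack-edge counting
# (exact unit-square outline: 1 isolated pixel -> 4 edges).
contour_perimeter_px <- function(mask, correction = c("kulpa", "none")) {
  correction <- match.arg(correction)
  if (!any(mask)) stop("empty mask has no perimeter")
  oc <- ocontour(Image(matrix(as.numeric(mask), nrow(mask), ncol(mask))))
  # outer contour of the largest object
  len <- vapply(oc, nrow, integer(1L))
  p <- oc[[which.max(len)]]
  if (nrow(p) < 3L) {
    return(crack_edge_count(mask))
  }
  d <- sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2))
  tot <- sum(d)
  if (correction == "kulpa") tot <- tot * KULPA_FACTOR
  tot
}

# number of foreground/background 4-adjacent pixel edges (image frame counts
# as background)
crack_edge_count <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  tot <- 0L
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    tot <- tot + sum(m == 1L & mat_shift(m, o[1L], o[2L]) == 0L)
  }
  tot
}

# Length of a pixel-subset of a skeleton, decomposed per pixel: every retained
# skeleton pixel receives half the (1 or sqrt 2) length of each incident edge
# to another retained skeleton pixel, so lengths are exactly additive over any
# partition of the skeleton. Returns the per-pixel length matrix (px units).
skeleton_halfedge_lengths <- function(skel, correction = c("kulpa", "none")) {
  correction <- match.arg(correction)
  s <- matrix(as.numeric(skel), nrow(skel), ncol(skel))
  acc <- matrix(0, nrow(s), ncol(s))
  for (o in list(c(1L, 0L), c(0L, 1L))) {
    acc <- acc + 0.5 * (mat_shift(s, o[1L], o[2L]) + mat_shift(s, -o[1L], -o[2L]))
  }
  for (o in list(c(1L, 1L), c(1L, -1L))) {
    acc <- acc + 0.5 * sqrt(2) *
      (mat_shift(s, o[1L], o[2L]) + mat_shift(s, -o[1L], -o[2L]))
  }
  acc[!skel] <- 0
  if (correction == "kulpa") acc <- acc * KULPA_FACTOR
  acc
}

# run code with a temporary RNG state
with_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  f()
}
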