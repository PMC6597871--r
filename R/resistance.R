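#' Build a resistance surface from a raster layer
#'
#' Encodes the standard hypothesis-driven surfaces used in individual-based
#' isolation-by-resistance analysis:
#' \describe{
#'   \item{habitat}{habitat-class cells get resistance 0.1, everything else
#'     0.9 (gene flow enhanced by natural habitat).}
#'   \item{invert}{max(value) - value, e.g. inverted forest cover (gene flow
#'     easier through denser forest).}
#'   \item{raw}{values used unchanged (elevation, roughness, climate layers).}
#'   \item{null}{every cell 0.5 — the uniform isolation-by-distance surface.}
#' }
#' Afterwards the surface is sanitized: optionally cropped to the bounding box
#' of the sample points plus a buffer (default one decimal degree, minimizing
#' border effects), and zero cells are replaced with 0.001 so conductances
#' stay finite.
#'
#' @param raster a `raster_grid`.
#' @param mode one of `"habitat"`, `"invert"`, `"raw"`, `"null"`.
#' @param habitat_values cell values treated as habitat (habitat mode).
#' @param points optional data frame with `lon`/`lat`; when given, the surface
#'   is cropped to their extent plus `buffer`.
#' @param buffer crop buffer in map units (decimal degrees).
#' @param zero_replacement value substituted for zero resistances.
#' @param provenance free-text tag recording what the surface represents.
#' @return A `resistance_surface` (a `raster_grid` subclass with attributes
#'   `mode` and `provenance`).
#' @export
build_resistance_surface <- function(raster, mode = c("habitat", "invert", "raw", "null"),
                                     habitat_values = 1, points = NULL,
                                     buffer = 1, zero_replacement = 0.001,
                                     provenance = mode[1]) {
  mode <- match.arg(mode)
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  out <- switch(mode,
    habitat = ifelse(is.na(v), NA, ifelse(v %in% habitat_values, 0.1, 0.9)),
    invert = max(v, na.rm = TRUE) - v,
    raw = v,
    null = ifelse(is.na(v), NA, 0.5))
  if (any(out < 0, na.rm = TRUE))
    stop("negative resistance values after transform")
  out[!is.na(out) & out == 0] <- zero_replacement
  r <- raster_grid(out, cellsize = raster$cellsize, xll = raster$xll,
                   yll = raster$yll, nodata = raster$nodata, crs = raster$crs)
  # restore NA cells (raster_grid only maps the nodata marker)
  r$values[is.na(out)] <- NA
  if (!is.null(points)) r <- crop_to_points(r, points, buffer)
  structure(r, mode = mode, provenance = provenance,
            class = c("resistance_surface", "raster_grid"))
}

crop_to_points <- function(r, points, buffer) {
  cc <- raster_cell_centers(r)
  xr <- range(points$lon) + c(-buffer, buffer)
  yr <- range(points$lat) + c(-buffer, buffer)
  cols <- which(cc$x >= xr[1] & cc$x <= xr[2])
  rows <- which(cc$y >= yr[1] & cc$y <= yr[2])
  if (length(cols) == 0 || length(rows) == 0)
    stop("crop extent contains no raster cells")
  v <- r$values[rows, cols, drop = FALSE]
  raster_grid(v, cellsize = r$cellsize,
              xll = r$xll + (min(cols) - 1) * r$cellsize,
              yll = r$yll + (nrow(r$values) - max(rows)) * r$cellsize,
              nodata = r$nodata, crs = r$crs)
}

# Sparse graph Laplacian of a resistance grid. Nodes are non-nodata cells;
# edges join 4- or 8-neighbors; edge conductance is the mean of the two cell
# conductances (or the reciprocal mean resistance), with diagonal edges
# scaled by 1/sqrt(2) for the longer step.
grid_laplacian <- function(surface, neighbors = 8, averaging = c("conductance", "resistance")) {
  averaging <- match.arg(averaging)
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  node <- matrix(NA_integer_, nr, nc)
  node[ok] <- seq_len(sum(ok))
  cond <- 1 / v
  offs <- list(c(0, 1, 1), c(1, 0, 1))
  if (neighbors == 8) offs <- c(offs, list(c(1, 1, 1 / sqrt(2)), c(1, -1, 1 / sqrt(2))))
  ii <- jj <- integer(0); ww <- numeric(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]; scale <- o[3]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    a <- node[r1, c1, drop = FALSE]
    b <- node[r1 + dr, c1 + dc, drop = FALSE]
    keep <- !is.na(a) & !is.na(b)
    if (!any(keep)) next
    ca <- cond[r1, c1, drop = FALSE][keep]
    cb <- cond[r1 + dr, c1 + dc, drop = FALSE][keep]
    w <- if (averaging == "conductance") (ca + cb) / 2 else 1 / ((1 / ca + 1 / cb) / 2)
    ii <- c(ii, a[keep]); jj <- c(jj, b[keep]); ww <- c(ww, w * scale)
  }
  n <- sum(ok)
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  list(L = L, node = node, n = n, adjacency = A)
}

# connected-component labels from a sparse adjacency by BFS
graph_components <- function(A) {
  n <- nrow(A)
  Ap <- methods::as(A, "CsparseMatrix")
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- unique(unlist(lapply(frontier, function(k)
        Ap@i[seq.int(Ap@p[k] + 1L, length.out = Ap@p[k + 1L] - Ap@p[k])] + 1L)))
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Circuit-theory pairwise effective resistance between sample points
#'
#' The resistance raster becomes an electrical network: each non-nodata cell
#' is a node, edges join neighboring cells (8-neighborhood by default, with
#' diagonal conductances scaled by 1/sqrt(2)), and each edge's conductance is
#' the mean of the two cells' conductances. The effective resistance between
#' the cells containing two sample points is obtained by grounding one focal
#' node and solving the reduced graph-Laplacian system with a sparse Cholesky
#' factorization (one factorization, one solve per focal node; exact to
#' machine precision). Points sharing a cell have resistance 0; points in
#' disconnected components get `Inf` with a warning.
#'
#' @param surface a `resistance_surface` (or `raster_grid` of resistances).
#' @param points data frame with `lon`, `lat` (and optionally `id`).
#' @param neighbors 8 (default) or 4.
#' @param averaging `"conductance"` (default) or `"resistance"` edge averaging.
#' @return A symmetric matrix of effective resistances with zero diagonal,
#'   with attribute `provenance` copied from the surface.
#' @export
pairwise_circuit_resistance <- function(surface, points, neighbors = 8,
                                        averaging = "conductance") {
  stopifnot(inherits(surface, "raster_grid"))
  gl <- grid_laplacian(surface, neighbors, averaging)
  np <- nrow(points)
  cells <- t(vapply(seq_len(np), function(i)
    raster_cell_at(surface, points$lon[i], points$lat[i]), integer(2)))
  focal <- gl$node[cbind(cells[, 1], cells[, 2])]
  if (any(is.na(focal))) {
    bad <- which(is.na(focal))[1]
    stop(sprintf("sample point (%g, %g) falls on a nodata cell",
                 points$lon[bad], points$lat[bad]))
  }
  comp <- graph_components(gl$adjacency)
  R <- matrix(0, np, np)
  same_comp <- outer(comp[focal], comp[focal], "==")
  if (!all(same_comp)) {
    warning("some sample pairs are in disconnected raster components; Inf returned")
    R[!same_comp] <- Inf
  }
  ufocal <- unique(focal)
  # solve per connected component containing focal nodes
  for (cmp in unique(comp[focal])) {
    nodes <- which(comp == cmp)
    f_here <- ufocal[comp[ufocal] == cmp]
    if (length(f_here) < 2) next
    idx <- match(seq_len(gl$n), nodes)  # global -> local
    Lc <- gl$L[nodes, nodes, drop = FALSE]
    g <- idx[f_here[length(f_here)]]    # ground the last focal node
    keep <- setdiff(seq_along(nodes), g)
    Lr <- Lc[keep, keep, drop = FALSE]
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lr), LDL = FALSE, perm = TRUE)
    others <- f_here[-length(f_here)]
    rhs <- Matrix::sparseMatrix(i = match(idx[others], keep),
                                j = seq_along(others), x = 1,
                                dims = c(length(keep), length(others)))
    V <- as.matrix(Matrix::solve(ch, rhs))  # potentials, ground at 0
    # local potentials indexed by reduced position
    pos <- match(idx[f_here], keep)         # NA for the ground
    for (a in seq_along(f_here)) for (b in seq_along(f_here)) {
      if (a >= b) next
      na_ <- f_here[a]; nb_ <- f_here[b]
      # effective resistance via potentials of unit injections
      r_ab <- if (is.na(pos[b])) {         # b is ground
        V[pos[a], a]
      } else if (is.na(pos[a])) {          # a is ground
        V[pos[b], b]
      } else {
        V[pos[a], a] + V[pos[b], b] - V[pos[b], a] - V[pos[a], b]
      }
      ia <- which(focal == na_); ib <- which(focal == nb_)
      R[ia, ib] <- R[ib, ia] <- r_ab
    }
  }
  diag(R) <- 0
  ids <- if (!is.null(points$id)) points$id else rownames(points)
  if (!is.null(ids)) dimnames(R) <- list(ids, ids)
  attr(R, "provenance") <- attr(surface, "provenance")
  R
}
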