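#' Build the disk lattice of the corneal basal layer
#'
#' Constructs a unit-spaced square lattice restricted to a disk of radius
#' `R_total`. The outermost annulus of width `limbal_width` is the limbus (the
#' stem-cell niche); the inner disk of radius `R = R_total - limbal_width` is
#' the cornea. Adjacency is 8-connected (Moore neighbourhood), which lets
#' displacement chains follow arbitrary replication-to-removal vectors.
#'
#' Region convention: a site is limbal iff `r > R`, corneal iff `r <= R`,
#' where `r` is the Euclidean distance to the tissue centre in cell units.
#'
#' @param R_total tissue radius in cell units (`>= 2`).
#' @param limbal_width width of the limbal annulus in cell units
#'   (`1 <= limbal_width < R_total`).
#' @return An object of class `tissue_grid`: a list with `sites` (data.frame
#'   with columns `id`, `x`, `y`, `r`, `theta`, `region`), `adjacency` (list of
#'   integer vectors of neighbouring site ids), `R` (corneal radius),
#'   `R_total`, `limbal_width`, and cached index vectors `cornea_ids`,
#'   `limbus_ids`.
#' @examples
#' g <- build_tissue(10)
#' table(g$sites$region)
#' @export
build_tissue <- function(R_total, limbal_width = 1) {
  if (!is.numeric(R_total) || length(R_total) != 1L || R_total < 2)
    stop("R_total must be a single number >= 2", call. = FALSE)
  if (!is.numeric(limbal_width) || length(limbal_width) != 1L ||
      limbal_width < 1 || limbal_width >= R_total)
    stop("limbal_width must satisfy 1 <= limbal_width < R_total", call. = FALSE)

  n <- floor(R_total)
  coords <- expand.grid(x = -n:n, y = -n:n)
  keep <- coords$x^2 + coords$y^2 <= R_total^2 + 1e-9
  coords <- coords[keep, , drop = FALSE]
  r <- sqrt(coords$x^2 + coords$y^2)
  theta <- atan2(coords$y, coords$x) %% (2 * pi)
  R <- R_total - limbal_width
  region <- ifelse(r > R + 1e-9, "LIMBUS", "CORNEA")

  sites <- data.frame(
    id = seq_len(nrow(coords)),
    x = coords$x, y = coords$y,
    r = r, theta = theta, region = region,
    stringsAsFactors = FALSE
  )
  rownames(sites) <- NULL

  # dense (x, y) -> id lookup for neighbour queries
  side <- 2L * n + 1L
  lut <- integer(side * side)
  idx <- (sites$x + n) * side + (sites$y + n) + 1L
  lut[idx] <- sites$id

  off <- expand.grid(dx = -1:1, dy = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  adjacency <- vector("list", nrow(sites))
  for (k in seq_len(nrow(off))) {
    nx <- sites$x + off$dx[k]
    ny <- sites$y + off$dy[k]
    ok <- abs(nx) <= n & abs(ny) <= n
    nb <- integer(nrow(sites))
    nb[ok] <- lut[(nx[ok] + n) * side + (ny[ok] + n) + 1L]
    for (i in which(nb > 0L)) adjacency[[i]] <- c(adjacency[[i]], nb[i])
  }

  g <- list(
    sites = sites,
    adjacency = adjacency,
    R = R,
    R_total = R_total,
    limbal_width = limbal_width,
    cornea_ids = sites$id[region == "CORNEA"],
    limbus_ids = sites$id[region == "LIMBUS"]
  )
  class(g) <- "tissue_grid"
  g
}

#' @export
print.tissue_grid <- function(x, ...) {
  cat(sprintf(
    "tissue_grid: R_total = %g (cornea R = %g, limbal width = %g)\n",
    x$R_total, x$R, x$limbal_width))
  cat(sprintf("  %d sites (%d corneal, %d limbal)\n",
              nrow(x$sites), length(x$cornea_ids), length(x$limbus_ids)))
  invisible(x)
}

#' @export
as.data.frame.tissue_grid <- function(x, ...) x$sites

#' Small lattice for exhaustive-enumeration tests
#'
#' Convenience wrapper around [build_tissue()] restricted to tiny radii, used
#' for exact event-distribution oracles.
#'
#' @param R_total tissue radius, at most 8.
#' @param limbal_width limbal annulus width.
#' @return A `tissue_grid`.
#' @export
tiny_grid <- function(R_total = 3, limbal_width = 1) {
  if (R_total > 8) stop("tiny_grid is restricted to R_total <= 8", call. = FALSE)
  build_tissue(R_total, limbal_width)
}

#' Corneal sites in the biased removal sector of a dividing cell
#'
#' Returns the corneal sites within Euclidean distance `m` of `center` whose
#' direction from `center` lies within `alpha/2` of the inward radial
#' direction (towards the tissue centre). With `alpha = 2*pi` the sector is
#' the full local disk and there is no centripetal bias; smaller `alpha`
#' means stronger bias (`bias = 1 - alpha/(2*pi)`). The centre site itself is
#' excluded. For a cell exactly at the tissue centre the inward direction is
#' undefined and the full disk is returned.
#'
#' @param grid a `tissue_grid`.
#' @param center site id of the dividing cell.
#' @param m local interaction radius in cell units (`>= 1`).
#' @param alpha sector angle in radians, `0 < alpha <= 2*pi`.
#' @return Integer vector of site ids (possibly empty near the boundary; the
#'   engine falls back to the unbiased disk in that case).
#' @export
local_sector <- function(grid, center, m, alpha = 2 * pi) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha > 2 * pi + 1e-12)
    stop("alpha must lie in (0, 2*pi]", call. = FALSE)
  s <- grid$sites
  cx <- s$x[center]; cy <- s$y[center]
  dx <- s$x - cx; dy <- s$y - cy
  d2 <- dx^2 + dy^2
  in_disk <- d2 > 0 & d2 <= m^2 + 1e-9 & s$region == "CORNEA"
  rr <- sqrt(cx^2 + cy^2)
  if (rr < 1e-12 || alpha >= 2 * pi - 1e-12) return(s$id[in_disk])
  # inward unit vector at the dividing cell
  ux <- -cx / rr; uy <- -cy / rr
  cosang <- (dx * ux + dy * uy) / sqrt(pmax(d2, 1e-300))
  s$id[in_disk & cosang >= cos(alpha / 2) - 1e-9]
}

#' Corneal sites in the central removal disk
#'
#' Uncoupled-model removal region: all corneal sites within distance `rho` of
#' the tissue centre. `rho = R` means no centripetal bias; smaller `rho`
#' concentrates removal at the centre.
#'
#' @param grid a `tissue_grid`.
#' @param rho central-disk radius in cell units, `1 <= rho <= R`.
#' @return Integer vector of site ids.
#' @export
central_disk <- function(grid, rho) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (rho < 1 || rho > grid$R + 1e-9)
    stop("rho must satisfy 1 <= rho <= R", call. = FALSE)
  s <- grid$sites
  s$id[s$region == "CORNEA" & s$r <= rho + 1e-9]
}

#' Distance from a point to a closed segment
#'
#' Euclidean distance from point `p` to the segment `ab`, the geometric
#' primitive of the displacement kernel (cells are pulled into the vacancy
#' with probability decreasing in their distance from the replication-removal
#' vector). Degenerate segments (`a == b`) reduce to point distance.
#'
#' @param p,a,b numeric length-2 vectors (x, y), or two-column matrices for
#'   `p` to evaluate many points at once.
#' @return Numeric distance(s), `>= 0`.
#' @export
distance_to_segment <- function(p, a, b) {
  if (is.matrix(p)) {
    px <- p[, 1]; py <- p[, 2]
  } else {
    px <- p[1]; py <- p[2]
  }
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 < 1e-300) {
    return(sqrt((px - a[1])^2 + (py - a[2])^2))
  }
  t <- ((px - a[1]) * abx + (py - a[2]) * aby) / len2
  t <- pmin(pmax(t, 0), 1)
  qx <- a[1] + t * abx; qy <- a[2] + t * aby
  sqrt((px - qx)^2 + (py - qy)^2)
}

#' Export a grid as a plain-text table
#'
#' Writes the site table (id, x, y, r, theta, region) as CSV for debugging
#' and plotting.
#'
#' @param grid a `tissue_grid`.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "tissue_grid"))
  utils::write.csv(grid$sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: pass-through representation of the grid for the C++ engine
grid_for_cpp <- function(grid) {
  list(
    x = as.integer(grid$sites$x),
    y = as.integer(grid$sites$y),
    is_limbus = grid$sites$region == "LIMBUS",
    R = as.numeric(grid$R),
    R_total = as.numeric(grid$R_total)
  )
}
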