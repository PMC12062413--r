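# Tissue geometry (lattice, scar mask, diffusion field, sampling line) and
# the random non-local M-F link-set generator.

#' Tissue geometry
#'
#' Square lattice of myocyte grid points with an optional scar region in
#' which diffusion is zero. The diffusion field is \code{d_reg} (cm^2/ms)
#' outside the scar and exactly 0 inside; no-flux conditions hold at the
#' domain edges and across every scar face. A sampling line is attached:
#' the horizontal radial line from the scar centre toward the pacing edge
#' (x = 1) for circular scars, the full mid-row otherwise.
#'
#' @param nx,ny lattice size (grid points).
#' @param dx lattice spacing (mm; default 0.25).
#' @param scar_shape \code{"none"}, \code{"circle"} or \code{"line"}.
#' @param scar_radius_cm circle radius (cm; default 2, i.e. 80 points at
#'   dx = 0.25 mm).
#' @param scar_cols columns of the straight line-scar band (default: 5
#'   central columns).
#' @param d_reg diffusion coefficient outside the scar (cm^2/ms).
#' @return object of class \code{"tissue_geometry"}: lattice dims, scar
#'   mask (nx x ny logical), diffusion field \code{d} (cm^2/ms), scar shape
#'   spec and the sampling line (matrix of i, j, ordered from the scar
#'   centre outward).
#' @export
tissue_geometry <- function(nx, ny = nx, dx = 0.25,
                            scar_shape = c("none", "circle", "line"),
                            scar_radius_cm = 2, scar_cols = NULL,
                            d_reg = 0.001) {
  scar_shape <- match.arg(scar_shape)
  if (nx < 3 || ny < 3) stop("lattice must be at least 3 x 3")
  if (d_reg < 0) stop("d_reg must be non-negative")
  scar <- matrix(FALSE, nx, ny)
  ci <- (nx + 1) / 2; cj <- (ny + 1) / 2
  if (scar_shape == "circle") {
    rad_pts <- scar_radius_cm * 10 / dx
    if (rad_pts >= min(nx, ny) / 2)
      stop("scar radius does not fit in the domain")
    ii <- matrix(seq_len(nx), nx, ny)
    jj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
    scar <- (ii - ci)^2 + (jj - cj)^2 <= rad_pts^2
  } else if (scar_shape == "line") {
    if (is.null(scar_cols)) {
      mid <- round(nx / 2)
      scar_cols <- (mid - 2):(mid + 2)
    }
    if (any(scar_cols < 2) || any(scar_cols > nx - 1))
      stop("line scar must leave tissue on both sides")
    scar[scar_cols, ] <- TRUE
  }
  d <- matrix(d_reg, nx, ny)
  d[scar] <- 0
  j0 <- round(cj)
  line <- if (scar_shape == "circle") {
    cbind(i = seq(round(ci), 1), j = j0)
  } else {
    cbind(i = seq_len(nx), j = j0)
  }
  structure(list(nx = nx, ny = ny, dx = dx, scar = scar, d = d,
                 d_reg = d_reg, scar_shape = scar_shape,
                 scar_radius_cm = if (scar_shape == "circle")
                   scar_radius_cm else NA_real_,
                 scar_cols = if (scar_shape == "line") scar_cols else NULL,
                 sampling_line = line),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("tissue_geometry: %d x %d, dx = %g mm, scar = %s (%d points)\n",
              x$nx, x$ny, x$dx, x$scar_shape, sum(x$scar)))
  invisible(x)
}

# linear point index <-> (i, j); column-major like an R matrix [nx, ny]
.pt_index <- function(i, j, nx) (j - 1L) * nx + i
.pt_ij <- function(p, nx) cbind(i = ((p - 1L) %% nx) + 1L,
                                j = ((p - 1L) %/% nx) + 1L)

# Euclidean distance (mm) between linear point indices
.pt_dist <- function(p, q, geom) {
  a <- .pt_ij(p, geom$nx); b <- .pt_ij(q, geom$nx)
  geom$dx * sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Fixed seeds for the five spatial link realisations
#'
#' The study protocol repeats each parameter combination for 5 spatial
#' realisations of the random M-F links; these map to fixed documented
#' RNG seeds so that "case 1..5" runs are reproducible.
#' @param realisation realisation id, 1-5 (other positive ids allowed and
#'   mapped deterministically).
#' @return integer seed.
#' @export
realisation_seed <- function(realisation) {
  if (any(realisation < 1)) stop("realisation ids are positive")
  as.integer(202500 + realisation)
}

#' Generate a random non-local M-F link set
#'
#' Places \code{n_units} fibroblast units on the scar: each unit gets one
#' uniformly random proximal scar grid point, then \code{k ~ Poisson(lambda)}
#' candidate distal attachments drawn uniformly from the candidate pool and
#' accepted only if within Euclidean distance \code{l_max} mm of the
#' proximal point; rejected candidates are discarded (not redrawn) and
#' duplicate attachments of a unit to the same grid point are dropped. The
#' default pool is the whole lattice, so units whose proximal point lies
#' near the scar rim can attach into the surrounding tissue -- the
#' border-zone mechanism. All links carry the same conductance Gs.
#'
#' @param geom \code{\link{tissue_geometry}} with a non-empty scar.
#' @param n_units number of fibroblast units (np).
#' @param lambda Poisson mean of the candidate-attachment count.
#' @param l_max maximum attachment distance (mm); 0 forces exactly one
#'   attachment (the proximal point) per unit.
#' @param seed RNG seed; identical inputs give bit-identical link sets.
#' @param gs junctional conductance per fibroblast per link (nS).
#' @param pool candidate pool: \code{"lattice"} (default) or \code{"scar"}.
#' @return object of class \code{"link_set"}: \code{proximal} (int vector of
#'   point indices), \code{distal} (list of int vectors), generation
#'   metadata.
#' @export
generate_links <- function(geom, n_units, lambda, l_max = 2.5, seed = 1,
                           gs = 1, pool = c("lattice", "scar")) {
  pool <- match.arg(pool)
  stopifnot(inherits(geom, "tissue_geometry"))
  scar_idx <- which(geom$scar)
  if (length(scar_idx) == 0) stop("geometry has no scar points")
  if (lambda < 0) stop("lambda must be non-negative")
  if (l_max < 0) stop("l_max must be non-negative")
  if (n_units < 1) stop("n_units must be positive")
  pool_idx <- if (pool == "lattice") seq_len(geom$nx * geom$ny) else scar_idx

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  proximal <- sample(scar_idx, n_units, replace = TRUE)
  k <- rpois(n_units, lambda)
  distal <- vector("list", n_units)
  tot <- sum(k)
  if (l_max > 0 && tot > 0) {
    cand <- sample(pool_idx, tot, replace = TRUE)
    unit_of <- rep.int(seq_len(n_units), k)
    ok <- .pt_dist(cand, proximal[unit_of], geom) <= l_max
    cand <- cand[ok]; unit_of <- unit_of[ok]
    if (length(cand)) {
      sp <- split(cand, unit_of)
      idx <- as.integer(names(sp))
      for (w in seq_along(sp)) {
        u <- idx[w]
        d <- unique(sp[[w]])
        distal[[u]] <- d[d != proximal[u]]
      }
    }
  }
  distal[vapply(distal, is.null, TRUE)] <- list(integer())
  structure(list(proximal = proximal, distal = distal, n_units = n_units,
                 lambda = lambda, l_max = l_max, seed = seed, gs = gs,
                 pool = pool, realisation = NA_integer_,
                 nx = geom$nx, ny = geom$ny, dx = geom$dx),
            class = "link_set")
}

#' @export
print.link_set <- function(x, ...) {
  deg <- link_degrees(x)
  cat(sprintf(paste0("link_set: %d units (lambda = %g, l_max = %g mm, ",
                     "seed = %s), degrees 1-%d, mean %.2f\n"),
              x$n_units, x$lambda, x$l_max, format(x$seed), max(deg),
              mean(deg)))
  invisible(x)
}

#' Attachment count per fibroblast unit
#' @param links a \code{\link{link_set}}.
#' @return integer vector: 1 (proximal) + number of distal attachments.
#' @export
link_degrees <- function(links) {
  1L + lengths(links$distal)
}

#' Degree histogram of a link set
#'
#' Fraction of fibroblast units attached to a given number of grid points.
#' @param links a \code{\link{link_set}}.
#' @return data.frame with \code{degree} (1..max observed), \code{count}
#'   and \code{fraction} (summing to 1).
#' @export
degree_histogram <- function(links) {
  deg <- link_degrees(links)
  if (length(deg) == 0) stop("empty link set")
  tb <- tabulate(deg, nbins = max(deg))
  data.frame(degree = seq_along(tb), count = tb,
             fraction = tb / sum(tb))
}

#' Invert a link set to the per-grid-point attachment map
#'
#' @param links a \code{\link{link_set}}.
#' @param geom the matching \code{\link{tissue_geometry}}.
#' @return list of length nx*ny; element p holds the ids of the units
#'   attached to grid point p (possibly repeated is impossible: duplicates
#'   are dropped at generation).
#' @export
invert_links <- function(links, geom) {
  npts <- geom$nx * geom$ny
  pts <- c(links$proximal, unlist(links$distal, use.names = FALSE))
  units <- c(seq_len(links$n_units),
             rep.int(seq_len(links$n_units), lengths(links$distal)))
  out <- vector("list", npts)
  if (length(pts)) {
    sp <- split(units, pts)
    out[as.integer(names(sp))] <- sp
  }
  out[vapply(out, is.null, TRUE)] <- list(integer())
  out
}

# CSR form consumed by the C++ solver: 0-based, proximal first per unit
.links_csr <- function(links) {
  if (is.null(links))
    return(list(unit_ptr = 0L, unit_pts = integer(), n_units = 0L))
  deg <- link_degrees(links)
  pts <- integer(sum(deg))
  ptr <- c(0L, cumsum(deg))
  pos <- 1L
  for (u in seq_len(links$n_units)) {
    pts[pos] <- links$proximal[u]
    d <- links$distal[[u]]
    if (length(d)) pts[(pos + 1L):(pos + length(d))] <- d
    pos <- pos + deg[u]
  }
  list(unit_ptr = ptr, unit_pts = pts - 1L, n_units = links$n_units)
}

#' Validate link-set constraints
#'
#' Asserts the generation invariants: every proximal point on the scar,
#' every distal attachment within \code{l_max} of its proximal point, no
#' duplicate attachments within a unit.
#' @param links a \code{\link{link_set}}.
#' @param geom the matching \code{\link{tissue_geometry}}.
#' @return invisibly TRUE; errors otherwise.
#' @export
validate_links <- function(links, geom) {
  if (!all(geom$scar[links$proximal]))
    stop("proximal point off the scar")
  for (u in seq_len(links$n_units)) {
    d <- links$distal[[u]]
    if (length(d) == 0) next
    if (anyDuplicated(c(links$proximal[u], d)))
      stop("duplicate attachment in unit ", u)
    if (any(.pt_dist(d, rep(links$proximal[u], length(d)), geom) >
            links$l_max + 1e-9))
      stop("attachment beyond l_max in unit ", u)
  }
  invisible(TRUE)
}

#' Distance of every grid point to the scar rim
#'
#' Minimum Euclidean distance (mm) from each non-scar point to the nearest
#' scar point that touches non-scar tissue (the rim). Scar points get 0.
#' Distances above \code{cap} are reported as \code{Inf} (only the
#' near-rim band is ever needed).
#' @param geom \code{\link{tissue_geometry}}.
#' @param cap maximum distance of interest (mm).
#' @return numeric nx x ny matrix.
#' @export
scar_rim_distance <- function(geom, cap = 10) {
  nx <- geom$nx; ny <- geom$ny
  out <- matrix(Inf, nx, ny)
  out[geom$scar] <- 0
  if (!any(geom$scar)) return(out)
  s <- geom$scar
  ns <- !s
  touches <- matrix(FALSE, nx, ny)
  touches[-nx, ] <- touches[-nx, ] | ns[-1, ]   # east neighbour non-scar
  touches[-1, ] <- touches[-1, ] | ns[-nx, ]    # west
  touches[, -ny] <- touches[, -ny] | ns[, -1]   # north
  touches[, -1] <- touches[, -1] | ns[, -ny]    # south
  rim <- which(s & touches)
  if (length(rim) == 0) return(out)
  rim_ij <- .pt_ij(rim, nx)
  cap_pts <- ceiling(cap / geom$dx)
  cand <- which(!s)
  cand_ij <- .pt_ij(cand, nx)
  # restrict to points within the bounding box of interest
  keep <- cand_ij[, 1] >= min(rim_ij[, 1]) - cap_pts &
          cand_ij[, 1] <= max(rim_ij[, 1]) + cap_pts &
          cand_ij[, 2] >= min(rim_ij[, 2]) - cap_pts &
          cand_ij[, 2] <= max(rim_ij[, 2]) + cap_pts
  cand <- cand[keep]; cand_ij <- cand_ij[keep, , drop = FALSE]
  if (length(cand)) {
    chunk <- 4000L
    for (a in seq(1L, length(cand), by = chunk)) {
      b <- min(a + chunk - 1L, length(cand))
      dx2 <- outer(cand_ij[a:b, 1], rim_ij[, 1], "-")^2
      dy2 <- outer(cand_ij[a:b, 2], rim_ij[, 2], "-")^2
      out[cand[a:b]] <- geom$dx * sqrt(apply(dx2 + dy2, 1, min))
    }
  }
  out[out > cap] <- Inf
  out
}

#' Border-zone annulus
#'
#' The non-scar points within \code{l_max + margin} of the scar rim: the
#' region whose dynamics the M-F links can alter directly.
#' @param geom \code{\link{tissue_geometry}}.
#' @param l_max link distance cutoff (mm).
#' @param margin extra margin (mm; default 2 grid spacings).
#' @return logical nx x ny matrix.
#' @export
border_zone <- function(geom, l_max, margin = 2 * geom$dx) {
  d <- scar_rim_distance(geom, cap = l_max + margin + geom$dx)
  !geom$scar & d <= l_max + margin
}
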