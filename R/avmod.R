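#' Dye parameters for AV1 accessible-volume calculations
#'
#' @param linker_length linker length L (Angstrom).
#' @param linker_width linker width w (Angstrom).
#' @param dye_radius dye radius (Angstrom).
#' @return A `dye_parameters` list. Defaults are the common AV1 values
#'   for maleimide-linked organic dyes (20 / 4.5 / 3.5 Angstrom).
#' @export
dye_parameters <- function(linker_length = 20, linker_width = 4.5,
                           dye_radius = 3.5) {
  stopifnot(linker_length > 0, linker_width > 0, dye_radius > 0,
            linker_length > linker_width)
  list(linker_length = linker_length, linker_width = linker_width,
       dye_radius = dye_radius)
}

## van der Waals radii (Angstrom) by element; unknown elements fall back
## to carbon.
.vdw_radius <- function(elements) {
  tab <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
           F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.9)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 1.7
  unname(r)
}

## 26-connectivity offsets and their Euclidean step costs.
.grid_offsets <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  list(off = off, cost = sqrt(rowSums(off^2)))
}

## Chamfer-style geodesic distance on a free-voxel mask (3D array) from a
## source voxel, 26-connectivity, by label-correcting sweeps until no
## update changes any distance.
.grid_geodesic <- function(free, src_idx, spacing) {
  dims <- dim(free)
  dist <- array(Inf, dims)
  dist[src_idx[1], src_idx[2], src_idx[3]] <- 0
  go <- .grid_offsets()
  shift_arr <- function(a, d, fill = Inf) {
    out <- array(fill, dims)
    sx <- seq_len(dims[1]); sy <- seq_len(dims[2]); sz <- seq_len(dims[3])
    fx <- sx - d[1]; fy <- sy - d[2]; fz <- sz - d[3]
    okx <- fx >= 1 & fx <= dims[1]
    oky <- fy >= 1 & fy <= dims[2]
    okz <- fz >= 1 & fz <= dims[3]
    out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
    out
  }
  for (pass in 1:200) {
    changed <- FALSE
    for (k in seq_len(nrow(go$off))) {
      cand <- shift_arr(dist, go$off[k, ]) + go$cost[k] * spacing
      upd <- free & cand < dist
      if (any(upd)) {
        dist[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  dist
}

#' AV1 accessible-volume cloud of a dye at a labeling site
#'
#' Geometric AV1 model: the dye is a sphere on a flexible linker attached
#' at a given atom. A cubic grid around the attachment point is
#' classified; a grid point belongs to the accessible volume iff (i) the
#' dye sphere clears every protein atom (center-to-atom distance at least
#' vdW radius + dye radius), and (ii) a linker path of length at most L
#' exists from the attachment point through sterically free grid points
#' (clearance at least vdW + half the linker width), measured as the
#' graph geodesic with 26-connectivity.
#'
#' @param coords protein heavy-atom coordinates: matrix/data.frame with
#'   columns `x`, `y`, `z` and optionally `element` (single-letter
#'   element codes; defaults to carbon radii). The attachment atom should
#'   not be included as an obstacle.
#' @param attachment length-3 numeric: attachment atom coordinates.
#' @param params a [dye_parameters()] list.
#' @param spacing grid spacing (Angstrom).
#' @return An `av_cloud`: list with `points` (allowed grid coordinates,
#'   n x 3), `mean_position`, `spacing`, `attachment`, `n_points`.
#'   Errors with "buried site" if the cloud is empty.
#' @export
av1_cloud <- function(coords, attachment, params = dye_parameters(),
                      spacing = 1.0) {
  cm <- as.matrix(as.data.frame(coords)[, c("x", "y", "z")])
  elem <- if ("element" %in% colnames(as.data.frame(coords)))
    as.data.frame(coords)$element else rep("C", nrow(cm))
  vdw <- .vdw_radius(elem)
  L <- params$linker_length
  reach <- L + params$dye_radius
  half <- ceiling(reach / spacing)
  ax <- attachment[1] + seq(-half, half) * spacing
  ay <- attachment[2] + seq(-half, half) * spacing
  az <- attachment[3] + seq(-half, half) * spacing
  dims <- c(length(ax), length(ay), length(az))
  ## clearance to the nearest atom surface per voxel
  clear <- array(Inf, dims)
  if (nrow(cm)) {
    near <- which(sqrt(colSums((t(cm) - attachment)^2)) <= reach + max(vdw) + 2)
    gx <- rep(ax, times = dims[2] * dims[3])
    gy <- rep(rep(ay, each = dims[1]), times = dims[3])
    gz <- rep(az, each = dims[1] * dims[2])
    cl <- rep(Inf, prod(dims))
    for (i in near) {
      d <- sqrt((gx - cm[i, 1])^2 + (gy - cm[i, 2])^2 + (gz - cm[i, 3])^2) -
        vdw[i]
      cl <- pmin(cl, d)
    }
    clear <- array(cl, dims)
  }
  free_link <- clear >= params$linker_width / 2
  free_dye <- clear >= params$dye_radius
  src <- pmin(pmax(round((attachment - c(ax[1], ay[1], az[1])) / spacing) + 1,
                   1), dims)
  free_link[src[1], src[2], src[3]] <- TRUE # linker starts at the attachment
  gd <- .grid_geodesic(free_link, src, spacing)
  allowed <- free_dye & gd <= L
  idx <- which(allowed, arr.ind = TRUE)
  if (!nrow(idx)) stop("buried site")
  pts <- cbind(x = ax[idx[, 1]], y = ay[idx[, 2]], z = az[idx[, 3]])
  structure(list(points = pts,
                 mean_position = colMeans(pts),
                 spacing = spacing, attachment = attachment,
                 n_points = nrow(pts)),
            class = "av_cloud")
}

#' AV1 cloud from a PDB file
#'
#' Reads a structure with \pkg{bio3d} (first model, altloc "A" or blank),
#' locates the attachment atom by a site spec like `"A:52:CB"`
#' (chain:residue:atom), and runs [av1_cloud()] against all other heavy
#' atoms.
#'
#' @param pdb_file path to a PDB file.
#' @param site site spec `"chain:resno:atom"`.
#' @param params a [dye_parameters()] list.
#' @param spacing grid spacing (Angstrom).
#' @return An `av_cloud`.
#' @export
av1_cloud_pdb <- function(pdb_file, site, params = dye_parameters(),
                          spacing = 1.0) {
  pdb <- bio3d::read.pdb(pdb_file, multi = FALSE)
  at <- pdb$atom
  at <- at[at$alt %in% c("", "A", NA), ]
  at <- at[at$elesy != "H" & !grepl("^H", at$elety), ]
  sp <- strsplit(site, ":")[[1]]
  if (length(sp) != 3) stop("site spec must be chain:resno:atom")
  hit <- which(at$chain == sp[1] & at$resno == as.integer(sp[2]) &
                 at$elety == sp[3])
  if (length(hit) != 1) stop("attachment atom not found: ", site)
  attach <- as.numeric(at[hit, c("x", "y", "z")])
  rest <- at[-hit, ]
  coords <- data.frame(x = rest$x, y = rest$y, z = rest$z,
                       element = rest$elesy)
  av1_cloud(coords, attach, params, spacing)
}

#' FRET observables predicted from two accessible-volume clouds
#'
#' Monte-Carlo average over uniformly weighted dye-position pairs:
#' the mean inter-dye distance `<R>`, the distance between mean positions
#' `R_mp`, the FRET-averaged efficiency `<E>` (mean of the Forster
#' relation over pairs) and its apparent distance
#' `R_<E> = R0 (1/<E> - 1)^(1/6)`.
#'
#' @param cloud_a,cloud_b `av_cloud` objects.
#' @param R0 Forster distance (Angstrom).
#' @param n_pairs number of Monte-Carlo pairs.
#' @param seed RNG seed for the subsample.
#' @return list with `R_mean`, `R_mp`, `E_mean`, `R_E`.
#' @export
av_fret_distance <- function(cloud_a, cloud_b, R0 = 62, n_pairs = 1e5,
                             seed = 42L) {
  set.seed(seed)
  ia <- sample.int(nrow(cloud_a$points), n_pairs, replace = TRUE)
  ib <- sample.int(nrow(cloud_b$points), n_pairs, replace = TRUE)
  dv <- cloud_a$points[ia, , drop = FALSE] -
    cloud_b$points[ib, , drop = FALSE]
  R <- sqrt(rowSums(dv^2))
  R <- pmax(R, 1e-9)
  E <- e_from_r(R, R0)
  Em <- mean(E)
  list(R_mean = mean(R),
       R_mp = sqrt(sum((cloud_a$mean_position - cloud_b$mean_position)^2)),
       E_mean = Em,
       R_E = r_from_e(min(max(Em, 1e-12), 1 - 1e-12), R0))
}
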