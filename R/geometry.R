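#' Phantom brain geometry
#'
#' Defines the voxel grid of a synthetic brain together with a set of
#' named, axis-aligned box regions standing in for an atlas parcellation.
#' Boxes are given in 1-based inclusive voxel coordinates and must be
#' pairwise disjoint and lie inside the grid.
#'
#' @param grid_dims Three positive integers, grid size in voxels.
#' @param voxel_size Three positive lengths in mm.
#' @param regions A data frame with columns `region` (character),
#'   `x0,x1,y0,y1,z0,z1` (integer box bounds, inclusive) and
#'   `hemisphere` (one of `"left"`, `"right"`, `"bilateral"`,
#'   `"midline"`). May have zero rows.
#' @return An object of class `phantom_geometry`.
#' @seealso [default_phantom_geometry()], [build_phantom_atlas()]
#' @export
phantom_geometry <- function(grid_dims, voxel_size, regions) {
  grid_dims <- as.integer(grid_dims)
  voxel_size <- as.numeric(voxel_size)
  if (length(grid_dims) != 3L || any(is.na(grid_dims)) || any(grid_dims < 1L))
    stop("'grid_dims' must be three positive integers")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths (mm)")
  req <- c("region", "x0", "x1", "y0", "y1", "z0", "z1", "hemisphere")
  if (!is.data.frame(regions) || !all(req %in% names(regions)))
    stop("'regions' must be a data frame with columns ",
         paste(req, collapse = ", "))
  regions <- regions[, req]
  regions$region <- as.character(regions$region)
  if (anyDuplicated(regions$region))
    stop("duplicated region names: ",
         paste(unique(regions$region[duplicated(regions$region)]), collapse = ", "))
  if (!all(regions$hemisphere %in% c("left", "right", "bilateral", "midline")))
    stop("'hemisphere' must be one of left, right, bilateral, midline")
  for (i in seq_len(nrow(regions))) {
    b <- regions[i, ]
    lo <- c(b$x0, b$y0, b$z0); hi <- c(b$x1, b$y1, b$z1)
    if (any(lo < 1L) || any(hi > grid_dims) || any(lo > hi))
      stop("region '", b$region, "' box does not lie inside the grid")
  }
  # pairwise disjointness of boxes (overlap on all three axes => collision)
  if (nrow(regions) > 1L) {
    for (i in seq_len(nrow(regions) - 1L)) {
      for (j in seq.int(i + 1L, nrow(regions))) {
        a <- regions[i, ]; b <- regions[j, ]
        if (a$x0 <= b$x1 && b$x0 <= a$x1 &&
            a$y0 <= b$y1 && b$y0 <= a$y1 &&
            a$z0 <= b$z1 && b$z0 <= a$z1)
          stop("region boxes overlap: '", a$region, "' and '", b$region, "'")
      }
    }
  }
  structure(list(grid_dims = grid_dims, voxel_size = voxel_size,
                 regions = regions),
            class = "phantom_geometry")
}

#' Default two-genotype phantom geometry
#'
#' A 32 x 32 x 16 grid at 0.354 x 0.354 x 0.8 mm (the in-plane resolution
#' and slice thickness of the emulated acquisition) holding ten disjoint
#' box regions named after the rat brain areas reported to respond to
#' chemogenetic VTA stimulation: four midline/bilateral regions shared by
#' both stimulation experiments (VTA, mPFC, Cg, Septum) and six more
#' engaged only by the CamKII-driven experiment (Insula, MC_R, Hipp,
#' TH_R, PtA_R, ViC_R). Right-hemisphere (`_R`) boxes sit in the low-x
#' half of the grid; the convention is recorded in the region table.
#'
#' @return A `phantom_geometry` with 10 regions.
#' @export
default_phantom_geometry <- function() {
  regions <- data.frame(
    region = c("VTA", "mPFC", "Cg", "Septum", "Insula",
               "MC_R", "Hipp", "TH_R", "PtA_R", "ViC_R"),
    x0 = c(15, 14, 14, 14,  5,  6,  9,  7,  6,  6),
    x1 = c(18, 19, 19, 19,  8, 10, 24, 11, 10, 10),
    y0 = c( 8, 24, 19, 14, 18, 22, 10, 12, 17,  6),
    y1 = c(11, 27, 22, 17, 21, 25, 13, 15, 20,  9),
    z0 = c( 4,  8, 12,  7,  7, 12, 11,  7, 12, 12),
    z1 = c( 6, 11, 14,  9,  9, 14, 13,  9, 14, 14),
    hemisphere = c("midline", "midline", "midline", "midline", "right",
                   "right", "bilateral", "right", "right", "right"),
    stringsAsFactors = FALSE
  )
  phantom_geometry(grid_dims = c(32L, 32L, 16L),
                   voxel_size = c(0.354, 0.354, 0.8),
                   regions = regions)
}

#' Build an atlas label volume from a phantom geometry
#'
#' Rasterizes the geometry's region boxes into an integer label volume
#' (0 = background, labels 1..K in region-table order), builds a brain
#' mask as the union of a central ellipsoid of unlabeled tissue and all
#' region voxels, and returns the label/region lookup table.
#'
#' @param geometry A `phantom_geometry`.
#' @return An object of class `phantom_atlas`: a list with `labels`
#'   (3D integer array), `mask` (3D logical array), `table` (data frame
#'   with columns `label`, `region_name`, `hemisphere`), `grid_dims`,
#'   and `voxel_size`.
#' @export
build_phantom_atlas <- function(geometry) {
  stopifnot(inherits(geometry, "phantom_geometry"))
  d <- geometry$grid_dims
  labels <- array(0L, dim = d)
  regions <- geometry$regions
  for (i in seq_len(nrow(regions))) {
    b <- regions[i, ]
    block <- labels[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1, drop = FALSE]
    if (any(block != 0L)) {
      hit <- regions$region[unique(block[block != 0L])]
      stop("region boxes overlap: '", b$region, "' collides with '",
           paste(hit, collapse = "', '"), "'")
    }
    labels[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] <- i
  }
  ctr <- (d + 1) / 2
  ax <- pmax(d * 0.45, 1)
  xs <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
  ys <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
  zs <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
  mask <- outer(outer(xs, ys, `+`), zs, `+`) <= 1
  mask <- mask | (labels > 0L)
  tab <- data.frame(label = seq_len(nrow(regions)),
                    region_name = regions$region,
                    hemisphere = regions$hemisphere,
                    stringsAsFactors = FALSE)
  structure(list(labels = labels, mask = mask, table = tab,
                 grid_dims = d, voxel_size = geometry$voxel_size),
            class = "phantom_atlas")
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("<phantom_atlas> %s grid, %d regions, %d brain voxels\n",
              paste(x$grid_dims, collapse = "x"), nrow(x$table),
              sum(x$mask)))
  invisible(x)
}

# voxel linear indices of one labeled region
region_voxels <- function(atlas, region) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  hit <- atlas$table$label[atlas$table$region_name == region]
  if (length(hit) != 1L)
    stop("unknown region '", region, "'")
  which(atlas$labels == hit)
}
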