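#' Region labels used throughout the package
#'
#' Integer labels of the synthetic labelled mask volume: background (0),
#' the three functional striatal subdivisions - limbic (1), associative (2),
#' sensorimotor (3) - the cerebellar reference region (4) and extra-striatal
#' brain (5).  The whole striatum is the union of labels 1-3.
#'
#' @return Named integer vector mapping region names to labels.
#' @export
region_labels <- function() {
  c(background = 0L, limbic = 1L, associative = 2L, sensorimotor = 3L,
    cerebellum = 4L, extrastriatal = 5L)
}

#' @rdname region_labels
#' @export
striatal_region_names <- function() c("limbic", "associative", "sensorimotor")

# resolve a region name or label to the set of integer labels it covers
resolve_region <- function(region) {
  labs <- region_labels()
  if (is.numeric(region)) return(as.integer(region))
  if (identical(region, "striatum") || identical(region, "whole_striatum"))
    return(unname(labs[striatal_region_names()]))
  if (!region %in% names(labs)) stop("unknown region: ", region)
  unname(labs[[region]])
}

#' Synthetic labelled mask volume
#'
#' Builds a 3D integer-labelled volume with box-shaped regions: a striatum of
#' exactly `n_striatal` voxels split into limbic / associative / sensorimotor
#' subdivisions, a cerebellar reference block, and an extra-striatal brain
#' block.  Geometry is deliberately schematic (no anatomical realism); what
#' matters downstream is the label bookkeeping and the feature
#' dimensionality, which defaults to the 2847 striatal voxels used by the
#' voxel-wise classifiers.
#'
#' @param n_striatal Total striatal voxel count (default 2847).
#' @param subdivision_frac Fractions of the striatum assigned to limbic,
#'   associative and sensorimotor subdivisions (named, sums to 1).  Counts
#'   are rounded so they total `n_striatal` exactly.
#' @param voxel_size_mm Isotropic voxel size, mm (metadata only).
#' @return A `mask_volume`: list with `data` (3D integer array), `labels`
#'   ([region_labels()]), `voxel_size_mm`.
#' @examples
#' m <- make_striatal_mask()
#' sum(m$data %in% 1:3)  # 2847
#' @export
make_striatal_mask <- function(n_striatal = 2847L,
                               subdivision_frac = c(limbic = 0.15,
                                                    associative = 0.55,
                                                    sensorimotor = 0.30),
                               voxel_size_mm = 2) {
  stopifnot(n_striatal >= 3L,
            setequal(names(subdivision_frac), striatal_region_names()),
            abs(sum(subdivision_frac) - 1) < 1e-8)
  dims <- c(30L, 30L, 16L)
  vol <- array(0L, dims)
  labs <- region_labels()

  # striatal slab: fill the first n_striatal voxels (column-major order) of a
  # box large enough to hold them, splitting contiguously into subdivisions
  box <- expand.grid(x = 3:18, y = 3:18, z = 2:14)   # 16*16*13 = 3328 voxels
  if (nrow(box) < n_striatal) stop("striatal box too small for n_striatal")
  counts <- round(n_striatal * subdivision_frac[striatal_region_names()])
  counts[3L] <- n_striatal - sum(counts[1:2])
  lab_seq <- rep(labs[striatal_region_names()], counts)
  idx <- box[seq_len(n_striatal), ]
  vol[cbind(idx$x, idx$y, idx$z)] <- as.integer(lab_seq)

  cer <- expand.grid(x = 21:28, y = 3:10, z = 2:7)    # 384 voxels
  vol[cbind(cer$x, cer$y, cer$z)] <- labs[["cerebellum"]]
  exs <- expand.grid(x = 21:28, y = 13:22, z = 6:15)  # 800 voxels
  vol[cbind(exs$x, exs$y, exs$z)] <- labs[["extrastriatal"]]

  structure(list(data = vol, labels = labs, voxel_size_mm = voxel_size_mm),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  tab <- table(factor(x$data, levels = x$labels,
                      labels = names(x$labels)))
  cat("<mask_volume>", paste(dim(x$data), collapse = "x"), "voxels,",
      x$voxel_size_mm, "mm\n")
  print(tab)
  invisible(x)
}

# linear indices (into the flattened volume) of voxels carrying any of the
# labels of `region`; fixed, reproducible voxel ordering
mask_region_idx <- function(mask, region) {
  which(mask$data %in% resolve_region(region))
}
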