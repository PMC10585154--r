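#' Brain volumes and parenchymal fraction from a segmentation label map
#'
#' Counts voxels per tissue label (1 gray matter, 2 white matter, 3 CSF, 0
#' background) and converts counts to ml. The intracranial volume is the
#' total non-background volume; the brain parenchymal fraction is total
#' brain volume (gray plus white) over intracranial volume.
#'
#' @param labels Integer array with values in 0:3 (e.g. from
#'   \code{\link{generate_label_map}}).
#' @param voxel_volume_mm3 Voxel volume; defaults to the cube of the map's
#'   \code{voxel_mm} attribute when present.
#' @return List of class \code{brain_volumes} with \code{gm}, \code{wm},
#'   \code{csf}, \code{tbv}, \code{icv} (ml) and \code{bpf}.
#' @export
volumes_from_labels <- function(labels, voxel_volume_mm3 = NULL) {
  if (is.null(voxel_volume_mm3)) {
    vm <- attr(labels, "voxel_mm")
    if (is.null(vm)) stop_bad("voxel_volume_mm3 missing and no voxel_mm attribute")
    voxel_volume_mm3 <- vm^3
  }
  if (voxel_volume_mm3 <= 0) stop_bad("voxel volume must be positive")
  vals <- unique(as.integer(labels))
  if (!all(vals %in% 0:3)) {
    stop_bad("unknown label values: %s",
             paste(setdiff(vals, 0:3), collapse = ", "))
  }
  counts <- tabulate(as.integer(labels) + 1L, nbins = 4L)  # bg, gm, wm, csf
  if (sum(counts[2:4]) == 0) stop_bad("empty label map: no tissue voxels")
  ml <- counts * voxel_volume_mm3 / 1000
  gm <- ml[2]; wm <- ml[3]; csf <- ml[4]
  tbv <- gm + wm
  icv <- gm + wm + csf
  structure(list(gm = gm, wm = wm, csf = csf, tbv = tbv, icv = icv,
                 bpf = tbv / icv),
            class = "brain_volumes")
}
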