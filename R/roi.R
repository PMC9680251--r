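## ROI summarization: parameter means over the tumor mask and tumor volume.

#' Mean of a parameter map over an ROI
#'
#' Arithmetic mean over the masked voxels carrying defined (non-NA, finite)
#' values; undefined voxels — e.g. Ve where kep is below its floor, or
#' velocities at frozen voxels — are excluded and counted.
#'
#' @param map scalar 3D array.
#' @param mask an [roi_mask()] of the same spatial shape.
#' @return list with `mean`, `n`, `n_excluded`.
#' @export
roi_mean <- function(map, mask) {
  map <- as.array(map)
  check_mask_matches(mask, dim(map))
  vals <- map[mask$values]
  ok <- is.finite(vals)
  if (!any(ok))
    stop("all masked voxels are undefined; ROI mean is not computable")
  list(mean = mean(vals[ok]), n = sum(ok), n_excluded = sum(!ok))
}

#' Tumor volume from a mask
#'
#' @param mask an [roi_mask()].
#' @param grid the [volume_grid()] supplying voxel spacing (mm).
#' @return volume in cm^3 (voxel count times voxel volume).
#' @export
tumor_volume <- function(mask, grid) {
  stopifnot_grid(grid)
  check_mask_matches(mask, grid$dims)
  sum(mask$values) * voxel_volume_mm3(grid) / 1000
}

#' Summarize perfusion maps over a tumor ROI
#'
#' Produces the per-patient row consumed by the cohort statistics stage:
#' ROI means of QTM speed and the Kety parameters, plus tumor volume.
#'
#' @param speed 3D speed map, mm/s (e.g. `solve_qtm(...)$speed`); voxels
#'   reported as NA (frozen/excluded) are skipped.
#' @param kety_maps the `maps` element of a [fit_kety()] result.
#' @param mask tumor [roi_mask()].
#' @param grid the [volume_grid()].
#' @return list of class `roi_summary`: `roi_speed`, `roi_ktrans`,
#'   `roi_ve`, `roi_tau`, `tumor_volume_cm3`, `n_voxels`, `n_excluded`.
#' @export
roi_summary <- function(speed, kety_maps, mask, grid) {
  ms <- roi_mean(speed, mask)
  mk <- roi_mean(kety_maps$ktrans, mask)
  mv <- roi_mean(kety_maps$ve, mask)
  mt <- roi_mean(kety_maps$tau, mask)
  structure(list(
    roi_speed = ms$mean, roi_ktrans = mk$mean, roi_ve = mv$mean,
    roi_tau = mt$mean, tumor_volume_cm3 = tumor_volume(mask, grid),
    n_voxels = sum(mask$values),
    n_excluded = ms$n_excluded + mk$n_excluded + mv$n_excluded +
      mt$n_excluded),
    class = "roi_summary")
}
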