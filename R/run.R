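#' A single 4D BOLD run
#'
#' Container for one subject-by-condition image series: a 4D array
#' indexed (x, y, z, t) plus voxel geometry and acquisition metadata.
#'
#' @param data 4D numeric array (x, y, z, t) of signal intensities.
#' @param voxel_size Three positive lengths in mm.
#' @param subject Subject identifier.
#' @param condition `"CNO"` or `"saline"`.
#' @param genotype Genotype / cohort label.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, voxel_size, subject = NA, condition = NA_character_,
                     genotype = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t); got dims ",
         paste(dim(data), collapse = "x"))
  if (!all(is.finite(data)))
    stop("'data' must be finite everywhere")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths (mm)")
  if (!is.na(condition) && !condition %in% c("CNO", "saline"))
    stop("'condition' must be \"CNO\" or \"saline\"")
  structure(list(data = data, voxel_size = voxel_size,
                 n_volumes = dim(data)[4], subject = subject,
                 condition = condition, genotype = genotype),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %s; subject %s, condition %s, genotype %s\n",
              paste(dim(x$data), collapse = "x"), x$subject, x$condition,
              x$genotype))
  invisible(x)
}
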