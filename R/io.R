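#' Read and write BOLD runs as NIfTI-1
#'
#' `write_run()` stores the 4D array and voxel geometry of a
#' [bold_run()] as a NIfTI-1 file (plain `.nii` or gzipped `.nii.gz`).
#' `read_run()` reads it back; the round-trip preserves the data
#' bitwise (images are written as 64-bit floats).
#'
#' @param run A `bold_run`.
#' @param file Path ending in `.nii` or `.nii.gz`.
#' @return `write_run()` returns `file` invisibly; `read_run()` a
#'   `bold_run`.
#' @export
write_run <- function(run, file) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$voxel_size, 1)
  RNifti::writeNifti(img, file, datatype = "double")
  invisible(file)
}

#' @param subject,condition,genotype Metadata to attach to the run read
#'   from `file` (NIfTI stores none of these).
#' @rdname write_run
#' @export
read_run <- function(file, subject = NA, condition = NA_character_,
                     genotype = NA_character_) {
  img <- RNifti::readNifti(file)
  arr <- plain_array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D image; '", file, "' has dims ",
         paste(dim(arr), collapse = "x"))
  vox <- RNifti::pixdim(img)[1:3]
  bold_run(arr, vox, subject = subject, condition = condition,
           genotype = genotype)
}

#' Read and write phantom atlases
#'
#' An atlas is stored as three files in `dir`: `atlas_labels.nii.gz`
#' (integer label volume), `atlas_mask.nii.gz` (brain mask, 0/1) and
#' `atlas_regions.tsv` (columns label, region_name, hemisphere).
#'
#' @param atlas A `phantom_atlas`.
#' @param dir Directory to write to / read from.
#' @return `write_atlas()` returns `dir` invisibly; `read_atlas()` a
#'   `phantom_atlas`.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(lab) <- atlas$voxel_size
  RNifti::writeNifti(lab, file.path(dir, "atlas_labels.nii.gz"),
                     datatype = "int32")
  msk <- RNifti::asNifti(array(as.integer(atlas$mask), dim = dim(atlas$mask)))
  RNifti::pixdim(msk) <- atlas$voxel_size
  RNifti::writeNifti(msk, file.path(dir, "atlas_mask.nii.gz"),
                     datatype = "int32")
  write_tsv(atlas$table, file.path(dir, "atlas_regions.tsv"))
  invisible(dir)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(dir) {
  lab <- RNifti::readNifti(file.path(dir, "atlas_labels.nii.gz"))
  labels <- plain_array(lab)
  if (length(dim(labels)) != 3L)
    stop("atlas label volume must be 3D; got dims ",
         paste(dim(labels), collapse = "x"))
  mask <- plain_array(RNifti::readNifti(file.path(dir, "atlas_mask.nii.gz")))
  if (!identical(dim(mask), dim(labels)))
    stop("atlas mask dims ", paste(dim(mask), collapse = "x"),
         " do not match label dims ", paste(dim(labels), collapse = "x"))
  tab <- read_tsv(file.path(dir, "atlas_regions.tsv"))
  structure(list(labels = array(as.integer(round(labels)), dim(labels)),
                 mask = array(mask != 0, dim(mask)),
                 table = tab, grid_dims = dim(labels),
                 voxel_size = RNifti::pixdim(lab)[1:3]),
            class = "phantom_atlas")
}

#' Write a 3D statistic map as NIfTI-1
#'
#' Undefined voxels (out-of-mask, zero-variance) are stored as NaN.
#'
#' @param data 3D numeric or logical array.
#' @param voxel_size Three lengths in mm.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_map <- function(data, voxel_size, file) {
  if (is.logical(data) || is.integer(data))
    data <- array(as.numeric(data), dim(data))
  data[is.na(data)] <- NaN
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, file, datatype = "double")
  invisible(file)
}

#' Full-precision TSV round-trip
#'
#' `write_tsv()` writes a data frame as tab-separated text with numeric
#' columns rendered at 17 significant digits, so `read_tsv()` restores
#' doubles exactly.
#'
#' @param df A data frame.
#' @param file Path to the TSV file.
#' @return `write_tsv()` returns `file` invisibly; `read_tsv()` a data
#'   frame.
#' @export
write_tsv <- function(df, file) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

# strip NIfTI attributes down to a plain R array
plain_array <- function(img) {
  arr <- as.array(img)
  array(as.vector(arr), dim(arr))
}
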