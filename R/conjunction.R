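#' Conjunction of two thresholded activation maps
#'
#' Classifies every voxel of the grid by membership in two binary
#' masks from different stimulation experiments: 0 = neither,
#' 1 = A only, 2 = B only, 3 = both. Category 3 is exactly the
#' voxel-wise intersection of the two masks.
#'
#' @param mask_a,mask_b `threshold_mask` objects (or 3D logical
#'   arrays) on the same grid.
#' @param label_a,label_b Experiment labels (e.g. `"DAT"`,
#'   `"CamKII"`).
#' @return An object of class `conjunction_map`: `data` (3D integer
#'   array of categories), `labels`, `counts` (named voxel counts per
#'   category), and the thresholds used (when available).
#' @export
conjunction <- function(mask_a, mask_b, label_a = "A", label_b = "B") {
  get_mask <- function(m) {
    if (inherits(m, "threshold_mask")) m$data
    else if (is.array(m) && length(dim(m)) == 3L) m != 0 & !is.na(m)
    else stop("masks must be threshold_mask objects or 3D logical arrays")
  }
  a <- get_mask(mask_a); b <- get_mask(mask_b)
  if (!identical(dim(a), dim(b)))
    stop("mask grids differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  cat_arr <- array(as.integer(a) + 2L * as.integer(b), dim(a))
  counts <- c(none = sum(cat_arr == 0L), a_only = sum(cat_arr == 1L),
              b_only = sum(cat_arr == 2L), both = sum(cat_arr == 3L))
  thr <- function(m) if (inherits(m, "threshold_mask"))
    list(rule = m$rule, level = m$level) else NULL
  structure(list(data = cat_arr, labels = c(a = label_a, b = label_b),
                 counts = counts,
                 thresholds = list(a = thr(mask_a), b = thr(mask_b))),
            class = "conjunction_map")
}

#' @export
print.conjunction_map <- function(x, ...) {
  cat(sprintf(
    "<conjunction_map> %s vs %s: %d %s-only, %d %s-only, %d both\n",
    x$labels["a"], x$labels["b"], x$counts["a_only"], x$labels["a"],
    x$counts["b_only"], x$labels["b"], x$counts["both"]))
  invisible(x)
}

#' Per-region overlap report of a conjunction map
#'
#' Counts, for every atlas region, the voxels significant only in
#' experiment A, only in B, and in both. `any_both` flags voxel-level
#' overlap inside the region; `coactive` flags region-level
#' co-activation (both experiments touch the region somewhere, even
#' without sharing a voxel) - the two notions can disagree.
#'
#' @param conj A [conjunction()] map.
#' @param atlas A `phantom_atlas` aligned with the conjunction grid.
#' @return A data frame with columns `region`, `n_A_only`, `n_B_only`,
#'   `n_both`, `any_both`, `coactive`.
#' @export
region_overlap_report <- function(conj, atlas) {
  stopifnot(inherits(conj, "conjunction_map"),
            inherits(atlas, "phantom_atlas"))
  if (!identical(dim(conj$data), dim(atlas$labels)))
    stop("conjunction dims (", paste(dim(conj$data), collapse = "x"),
         ") do not match atlas dims (",
         paste(dim(atlas$labels), collapse = "x"), ")")
  tab <- atlas$table
  out <- data.frame(region = tab$region_name, n_A_only = NA_integer_,
                    n_B_only = NA_integer_, n_both = NA_integer_,
                    any_both = NA, coactive = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    v <- conj$data[atlas$labels == tab$label[i]]
    out$n_A_only[i] <- sum(v == 1L)
    out$n_B_only[i] <- sum(v == 2L)
    out$n_both[i] <- sum(v == 3L)
    out$any_both[i] <- out$n_both[i] > 0L
    out$coactive[i] <- (out$n_A_only[i] + out$n_both[i] > 0L) &&
      (out$n_B_only[i] + out$n_both[i] > 0L)
  }
  out
}
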