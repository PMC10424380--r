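#' Scan timeline of a pharmacological fMRI run
#'
#' Describes the temporal protocol of a single run in 1-based, inclusive
#' scan indices: how many volumes were acquired, which window is the
#' pre-injection baseline, after which volume the ligand (CNO or saline)
#' was injected, and which late post-injection window is treated as the
#' activation phase. The default corresponds to a 65-volume run with
#' baseline scans 5-25, injection after scan 25 (40 post-injection
#' volumes), and activation phase volumes 45-65.
#'
#' @param n_volumes Total number of volumes in the run.
#' @param baseline Length-2 integer vector, first and last scan (1-based,
#'   inclusive) of the baseline window used for normalization.
#' @param activation Length-2 integer vector, first and last scan of the
#'   activation-phase window used for the AUC statistic.
#' @param injection_after Volume index after which the injection occurs;
#'   the baseline window must end at or before it and the activation
#'   window must start after it.
#' @return An object of class `bold_timeline`.
#' @examples
#' tl <- bold_timeline()
#' tl$n_volumes                       # 65
#' diff(tl$baseline) + 1L             # 21 baseline volumes
#' @export
bold_timeline <- function(n_volumes = 65L, baseline = c(5L, 25L),
                          activation = c(45L, 65L), injection_after = 25L) {
  n_volumes <- as.integer(n_volumes)
  baseline <- as.integer(baseline)
  activation <- as.integer(activation)
  injection_after <- as.integer(injection_after)
  if (length(n_volumes) != 1L || is.na(n_volumes) || n_volumes < 2L)
    stop("'n_volumes' must be a single integer >= 2")
  for (w in list(baseline = baseline, activation = activation)) {
    if (length(w) != 2L || anyNA(w) || w[1] > w[2])
      stop("windows must be length-2 non-decreasing integer vectors")
  }
  if (baseline[1] < 1L || activation[2] > n_volumes)
    stop("windows must lie within [1, n_volumes]")
  if (length(injection_after) != 1L || is.na(injection_after) ||
      injection_after < 1L || injection_after >= n_volumes)
    stop("'injection_after' must lie within [1, n_volumes)")
  if (baseline[2] > injection_after)
    stop("baseline window must end at or before the injection volume")
  if (activation[1] <= injection_after)
    stop("activation window must start after the injection volume")
  structure(
    list(n_volumes = n_volumes, baseline = baseline,
         activation = activation, injection_after = injection_after),
    class = "bold_timeline"
  )
}

#' Default scan timeline
#'
#' The emulated acquisition protocol: 65 repetitions, 25 pre-injection
#' volumes (baseline averaged over scans 5-25), 40 post-injection
#' volumes, activation phase over volumes 45-65.
#'
#' @return A `bold_timeline`.
#' @export
default_timeline <- function() bold_timeline()

#' Scan indices of a timeline window
#'
#' @param timeline A `bold_timeline`.
#' @param window Either `"baseline"` or `"activation"`.
#' @return Integer vector of 1-based scan indices (inclusive window).
#' @export
window_indices <- function(timeline, window = c("baseline", "activation")) {
  stopifnot(inherits(timeline, "bold_timeline"))
  window <- match.arg(window)
  w <- timeline[[window]]
  seq.int(w[1], w[2])
}

#' @export
print.bold_timeline <- function(x, ...) {
  cat(sprintf(
    "<bold_timeline> %d volumes; baseline %d-%d; injection after %d; activation %d-%d\n",
    x$n_volumes, x$baseline[1], x$baseline[2], x$injection_after,
    x$activation[1], x$activation[2]))
  invisible(x)
}
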