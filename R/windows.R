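## Sliding-window dynamic functional connectivity.
##
## Each window yields one node x node Fisher-z correlation matrix; the
## ordered stack of windows is the layer sequence of the temporal
## multilayer network.

#' Sliding-window specification
#'
#' @param length window length in volumes (TR units); >= 3.
#' @param step window step in volumes; >= 1.
#' @param tr repetition time in seconds (used only to report window
#'   durations; the analysis is in TR units).
#' @return a \code{window_spec}.
#' @export
#' @examples
#' sp <- window_spec(45, 1, tr = 2.5)
#' window_seconds(sp)     # 112.5
window_spec <- function(length, step = 1L, tr = 2.5) {
  length <- as.integer(length); step <- as.integer(step)
  if (length < 3L) stop("window length must be >= 3 volumes")
  if (step < 1L) stop("window step must be >= 1 volume")
  if (tr <= 0) stop("tr must be positive seconds")
  structure(list(length = length, step = step, tr = tr),
            class = "window_spec")
}

#' Window duration and step in seconds
#' @param spec a \code{window_spec}.
#' @return named numeric: \code{length_s}, \code{step_s}.
#' @export
window_seconds <- function(spec) {
  c(length_s = spec$length * spec$tr, step_s = spec$step * spec$tr)
}

#' Enumerate sliding windows
#'
#' Returns 1-based inclusive \code{(start, end)} volume indices. Trailing
#' volumes that do not fill a complete window are dropped, so the window
#' count is \code{floor((n_volumes - length) / step) + 1}.
#'
#' @param n_volumes total volumes in the series.
#' @param spec a \code{window_spec}.
#' @return data frame with columns \code{start}, \code{end}.
#' @export
#' @examples
#' w <- window_indices(190, window_spec(45, 1))
#' nrow(w)   # 146 windows: (1,45), (2,46), ..., (146,190)
window_indices <- function(n_volumes, spec) {
  n_volumes <- as.integer(n_volumes)
  if (spec$length > n_volumes)
    stop(sprintf("window length %d exceeds series length %d volumes",
                 spec$length, n_volumes))
  starts <- seq.int(1L, n_volumes - spec$length + 1L, by = spec$step)
  data.frame(start = starts, end = starts + spec$length - 1L)
}

#' Build the dynamic connectivity graph of one subject
#'
#' For each sliding window, computes pairwise Pearson correlations over
#' the window's volumes and applies the Fisher z-transform
#' \code{atanh(r)}, clipping \code{|r|} at \code{1 - 1e-7} first so that
#' perfectly correlated pairs stay finite. Diagonals are set to 0.
#'
#' @param x a \code{subject_record} or a node x volume numeric matrix.
#' @param spec a \code{window_spec}.
#' @return a \code{dynamic_graph}: list with \code{layers} (list of
#'   symmetric node x node Fisher-z matrices), \code{windows} (the
#'   \code{\link{window_indices}} table) and \code{spec}.
#' @export
dynamic_graph <- function(x, spec) {
  ts <- if (inherits(x, "subject_record")) x$timeseries else as.matrix(x)
  win <- window_indices(ncol(ts), spec)
  clip <- 1 - 1e-7
  layers <- vector("list", nrow(win))
  for (w in seq_len(nrow(win))) {
    seg <- ts[, win$start[w]:win$end[w], drop = FALSE]
    sds <- apply(seg, 1L, sd)
    if (any(sds == 0))
      stop(sprintf(
        "node %d is constant within window %d (%d-%d); correlation undefined",
        which(sds == 0)[1L], w, win$start[w], win$end[w]))
    r <- cor(t(seg))
    r <- pmin(pmax(r, -clip), clip)
    z <- atanh(r)
    diag(z) <- 0
    layers[[w]] <- (z + t(z)) / 2   # enforce exact symmetry
  }
  structure(list(layers = layers, windows = win, spec = spec),
            class = "dynamic_graph")
}

#' @export
print.dynamic_graph <- function(x, ...) {
  cat(sprintf("<dynamic_graph> %d layers of %d x %d (window %d TR, step %d TR)\n",
              length(x$layers), nrow(x$layers[[1L]]), ncol(x$layers[[1L]]),
              x$spec$length, x$spec$step))
  invisible(x)
}
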