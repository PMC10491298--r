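# Oligomer analysis: peptides belong to the same oligomer when any two of
# their heavy atoms are within a distance cutoff (5 A), under the
# minimum-image convention; oligomers are the connected components of the
# resulting contact graph.

#' Partition peptides into oligomers for one frame
#'
#' @param coords n x 3 coordinate matrix.
#' @param system `fp_system`.
#' @param cutoff Heavy-atom contact distance, A (default 5).
#' @param box Cubic box side (defaults to the system's).
#' @return `fp_oligomer_partition`: list with `membership` (cluster id per
#'   peptide), `sizes` (cluster sizes) and `clusters` (list of peptide id
#'   vectors).
#' @export
oligomer_partition <- function(coords, system, cutoff = 5,
                               box = system$box) {
  heavy <- .heavy_by_peptide(system)
  np <- length(heavy)
  peps <- as.integer(names(heavy))
  bx <- if (is.null(box) || is.na(box)) NA else box
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  edges <- integer(0)
  if (np >= 2) {
    for (a in seq_len(np - 1)) {
      pa <- coords[heavy[[a]], , drop = FALSE]
      for (b in (a + 1):np) {
        d <- .dist_pbc(pa, coords[heavy[[b]], , drop = FALSE], bx)
        if (min(d) <= cutoff) edges <- c(edges, a, b)
      }
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  membership <- stats::setNames(as.integer(comp$membership), peps)
  clusters <- split(peps, membership)
  structure(list(membership = membership,
                 sizes = as.integer(comp$csize),
                 clusters = clusters, cutoff = cutoff),
            class = "fp_oligomer_partition")
}

#' Oligomer partitions along a trajectory
#'
#' @param traj `fp_trajectory`.
#' @param system `fp_system`.
#' @param stride Analyse every `stride`-th frame.
#' @param cutoff Heavy-atom contact distance, A.
#' @return List with `partitions` (one `fp_oligomer_partition` per
#'   analysed frame) and `times` (ps).
#' @export
oligomer_series <- function(traj, system, stride = 1, cutoff = 5) {
  idx <- seq(1, n_frames(traj), by = stride)
  list(partitions = lapply(idx, function(i)
         oligomer_partition(frame_coords(traj, i), system, cutoff,
                            box = traj$box)),
       times = traj$times[idx])
}

#' Window-averaged oligomer size histogram
#'
#' Average count of oligomers of each size over a set of frames (e.g. the
#' frames belonging to a window of pulse indices).  Mass conservation
#' holds per frame and is preserved by the average:
#' sum(size x count) = n_peptides.
#'
#' @param partitions List of `fp_oligomer_partition` (or the result of
#'   [oligomer_series()]).
#' @param frames Indices of the frames to average (default all).
#' @param window Optional recorded window label (e.g. pulse bounds).
#' @return `fp_oligomer_histogram`: data.frame `size`, `count` (mean
#'   per-frame count), with attributes `n_frames` and `window`.
#' @export
window_histogram <- function(partitions, frames = NULL, window = NULL) {
  if (!is.null(partitions$partitions)) partitions <- partitions$partitions
  if (is.null(frames)) frames <- seq_along(partitions)
  if (!length(frames)) stop("empty frame window")
  np <- length(partitions[[frames[1]]]$membership)
  counts <- matrix(0, length(frames), np)
  for (q in seq_along(frames)) {
    sz <- partitions[[frames[q]]]$sizes
    tb <- table(factor(sz, levels = seq_len(np)))
    counts[q, ] <- as.numeric(tb)
  }
  out <- data.frame(size = seq_len(np), count = colMeans(counts))
  attr(out, "n_frames") <- length(frames)
  attr(out, "window") <- window
  class(out) <- c("fp_oligomer_histogram", class(out))
  out
}

#' Frames belonging to a window of pulse indices
#'
#' Maps trajectory time stamps to pulse indices via the pulse-train
#' schedule (pulse k spans the interval centred on its Gaussian centre)
#' and returns the frame indices whose pulse index lies in the closed
#' window.
#'
#' @param times Frame times, ps.
#' @param field `fp_pulse_train`.
#' @param window Closed interval of 1-based pulse indices, e.g.
#'   c(991, 1000).
#' @return Integer frame indices.
#' @export
pulse_window_frames <- function(times, field, window) {
  k <- floor((times - field$t0_offset) / field$interval + 0.5) + 1L
  k[k < 1L] <- 1L
  which(k >= window[1] & k <= window[2])
}
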