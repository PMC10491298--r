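# Hydrogen-bond kinetics: geometric criterion presence series for the
# designed fibril C=O...H-N pairs and their water partners, irreversible
# break detection, event-aligned averaging and pulse-periodicity analysis.
# The geometric criterion here is deliberately independent of the DSSP
# energy criterion used by the secondary-structure analysis.

#' Geometric hydrogen-bond criterion
#'
#' A bond is formed when the hydrogen-acceptor distance is at most
#' `distance` and the donor-hydrogen-acceptor angle is at least `angle`.
#'
#' @param distance Acceptor...H maximum distance, A.
#' @param angle Minimum donor-H...acceptor angle, degrees.
#' @return `fp_hbond_criterion`.
#' @export
hbond_criterion <- function(distance = 2.5, angle = 135) {
  stopifnot(distance > 0, angle > 0, angle <= 180)
  structure(list(distance = distance, angle = angle),
            class = "fp_hbond_criterion")
}

# angle at H between H->D and H->A directions (degrees), vectorised
.hb_angle <- function(D, H, A, box) {
  u <- .min_image(D - H, box); v <- .min_image(A - H, box)
  cs <- rowSums(u * v) / (sqrt(rowSums(u * u)) * sqrt(rowSums(v * v)))
  acos(pmax(-1, pmin(1, cs))) * 180 / pi
}

#' Hydrogen-bond presence series along a trajectory
#'
#' For every designed C=O...H-N pair (the fibril registry by default),
#' three boolean series per frame: the peptide-peptide bond itself
#' (class "pep"), the acceptor C=O bonded to ANY water (donor water O-H;
#' class "co_wat"), and the donor N-H bonded to ANY water oxygen (class
#' "nh_wat").
#'
#' @param traj `fp_trajectory`.
#' @param system `fp_system` (needs `registry` unless `pairs` given).
#' @param pairs data.frame with columns N, H, C, O (atom ids); default is
#'   the system's designed registry.
#' @param criterion `fp_hbond_criterion`.
#' @param stride Analyse every `stride`-th frame.
#' @return `fp_hbond_series`: list of three logical matrices
#'   (frames x pairs) `pep`, `co_wat`, `nh_wat`, plus `times` and `pairs`.
#' @export
hbond_series <- function(traj, system, pairs = system$registry,
                         criterion = hbond_criterion(), stride = 1) {
  if (is.null(pairs) || !nrow(pairs))
    stop("no hydrogen-bond pairs: system has no registry and none given")
  need <- c("N", "H", "C", "O")
  if (!all(need %in% names(pairs))) stop("pairs must have columns N,H,C,O")
  nmax <- n_atoms(system)
  if (any(unlist(pairs[need]) > nmax))
    stop("pair references unknown atoms")
  at <- system$atoms
  wO <- at$id[at$site == "OW"]
  wH <- at$id[at$site %in% c("HW1", "HW2")]
  wH_parent <- rep(wO, each = 2)
  bx <- if (is.null(traj$box) || is.na(traj$box)) NA else traj$box
  idx <- seq(1, n_frames(traj), by = stride)
  np <- nrow(pairs)
  pep <- co_wat <- nh_wat <- matrix(FALSE, length(idx), np)
  for (q in seq_along(idx)) {
    co <- frame_coords(traj, idx[q])
    # peptide class: H...O distance + N-H...O angle
    dHO <- sqrt(rowSums(.min_image(co[pairs$H, , drop = FALSE] -
                                   co[pairs$O, , drop = FALSE], bx)^2))
    ang <- .hb_angle(co[pairs$N, , drop = FALSE], co[pairs$H, , drop = FALSE],
                     co[pairs$O, , drop = FALSE], bx)
    pep[q, ] <- dHO <= criterion$distance & ang >= criterion$angle
    if (length(wO)) {
      # acceptor C=O ... any water H (donor water)
      dm <- .dist_pbc(co[pairs$O, , drop = FALSE],
                      co[wH, , drop = FALSE], bx)
      hits <- which(dm <= criterion$distance, arr.ind = TRUE)
      if (nrow(hits)) {
        a <- .hb_angle(co[wH_parent[hits[, 2]], , drop = FALSE],
                       co[wH[hits[, 2]], , drop = FALSE],
                       co[pairs$O[hits[, 1]], , drop = FALSE], bx)
        co_wat[q, unique(hits[a >= criterion$angle, 1])] <- TRUE
      }
      # donor N-H ... any water O (acceptor water)
      dm <- .dist_pbc(co[pairs$H, , drop = FALSE],
                      co[wO, , drop = FALSE], bx)
      hits <- which(dm <= criterion$distance, arr.ind = TRUE)
      if (nrow(hits)) {
        a <- .hb_angle(co[pairs$N[hits[, 1]], , drop = FALSE],
                       co[pairs$H[hits[, 1]], , drop = FALSE],
                       co[wO[hits[, 2]], , drop = FALSE], bx)
        nh_wat[q, unique(hits[a >= criterion$angle, 1])] <- TRUE
      }
    }
  }
  structure(list(pep = pep, co_wat = co_wat, nh_wat = nh_wat,
                 times = traj$times[idx], pairs = pairs,
                 criterion = criterion),
            class = "fp_hbond_series")
}

#' Irreversible break time of one presence series
#'
#' The break is the LAST formed -> unformed transition after which the
#' bond never re-forms within the trajectory.  An event is reported only
#' when at least `margin` of trajectory remains after it (censoring
#' guard); a bond that persists at the end, or never formed, yields no
#' event.
#'
#' @param formed Logical vector (one pair's series).
#' @param times Frame times, ps.
#' @param margin Required remaining span after the break, ps.
#' @return List with `time` (ps) and `frame` (index of the first unformed
#'   frame), or NULL when there is no uncensored irreversible break.
#' @export
irreversible_break_time <- function(formed, times, margin = 0) {
  stopifnot(length(formed) == length(times), length(formed) > 0)
  if (!any(formed)) return(NULL)
  last_on <- max(which(formed))
  if (last_on == length(formed)) return(NULL)   # persists at the end
  t_break <- times[last_on + 1L]
  if (times[length(times)] - t_break < margin) return(NULL)
  list(time = t_break, frame = last_on + 1L)
}

#' All irreversible break events of a series set
#'
#' @param hb `fp_hbond_series`.
#' @param margin Censoring margin, ps.
#' @return data.frame with `pair`, `time`, `frame` (possibly 0 rows).
#' @export
break_events <- function(hb, margin = 0) {
  ev <- lapply(seq_len(ncol(hb$pep)), function(p) {
    b <- irreversible_break_time(hb$pep[, p], hb$times, margin)
    if (is.null(b)) NULL else data.frame(pair = p, time = b$time,
                                         frame = b$frame)
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) data.frame(pair = integer(), time = numeric(),
                              frame = integer()) else ev
}

#' Event-aligned average hydrogen-bond probabilities
#'
#' For each irreversible break event, the three class series of that pair
#' are re-indexed to tau = t - t_break and averaged across events on a
#' symmetric tau grid with the trajectory's frame stride.
#'
#' @param hb `fp_hbond_series`.
#' @param events data.frame from [break_events()] (>= 1 row).
#' @param window Half-width of the tau window, ps.
#' @return data.frame with `tau`, mean probabilities `pep`, `co_wat`,
#'   `nh_wat`, and `n` (contributing pairs per tau).
#' @export
aligned_average <- function(hb, events, window = 200) {
  if (is.null(events) || nrow(events) == 0)
    stop("no break events: either nothing dissociated or the margin ",
         "censored every event")
  dt <- hb$times[2] - hb$times[1]
  tau <- seq(-window, window, by = dt)
  acc <- matrix(0, length(tau), 3); cnt <- integer(length(tau))
  for (e in seq_len(nrow(events))) {
    p <- events$pair[e]
    tt <- hb$times - events$time[e]
    for (q in seq_along(tau)) {
      k <- which.min(abs(tt - tau[q]))
      if (abs(tt[k] - tau[q]) > dt / 2 + 1e-9) next
      acc[q, ] <- acc[q, ] + c(hb$pep[k, p], hb$co_wat[k, p], hb$nh_wat[k, p])
      cnt[q] <- cnt[q] + 1L
    }
  }
  ok <- cnt > 0
  data.frame(tau = tau[ok],
             pep = acc[ok, 1] / cnt[ok],
             co_wat = acc[ok, 2] / cnt[ok],
             nh_wat = acc[ok, 3] / cnt[ok],
             n = cnt[ok])
}

#' Dominant period of a presence series
#'
#' Periodogram of the (mean-removed) series; the dominant period is the
#' inverse of the highest-power nonzero frequency.  A constant series has
#' no significant period and returns NA.
#'
#' @param x Numeric (or logical) series, regular sampling.
#' @param dt Sampling interval, ps.
#' @param min_intervals The series must span at least this many candidate
#'   periods (default 5).
#' @param expected Optional expected period used for the span check, ps.
#' @return Dominant period in ps, or NA for a flat series.
#' @export
pulse_periodicity <- function(x, dt, min_intervals = 5, expected = NULL) {
  x <- as.numeric(x)
  span <- (length(x) - 1) * dt
  if (!is.null(expected) && span < min_intervals * expected)
    stop("series spans ", span, " ps < ", min_intervals,
         " x the expected period")
  if (length(x) < 2 * min_intervals)
    stop("series too short for periodicity analysis")
  x <- x - mean(x)
  if (stats::sd(x) == 0) return(NA_real_)
  n <- length(x)
  P <- Mod(stats::fft(x)[2:(n %/% 2)])^2
  f <- (seq_len(n %/% 2 - 1)) / (n * dt)
  1 / f[which.max(P)]
}

#' Write aligned profiles and event table
#'
#' @param profile data.frame from [aligned_average()].
#' @param events data.frame from [break_events()].
#' @param path CSV path for the profile; events go to `path`.json.
#' @return `path`, invisibly.
#' @export
write_hbond_outputs <- function(profile, events, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  jsonlite::write_json(events, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
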