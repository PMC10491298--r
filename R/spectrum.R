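#' Spectrum estimator configuration
#'
#' Welch-averaged windowed periodogram of the C=O bond-stretch velocity,
#' averaged over all backbone C=O bonds.  The wavenumber resolution (bin
#' width) is 1/(c T_segment); the segment length must keep it at or below
#' `max_bin` and cover at least 10 periods of the lowest analysed
#' wavenumber.
#'
#' @param segment_ps Welch segment length, ps.
#' @param window "hann" or "rectangular".
#' @param overlap Segment overlap fraction (default 0.5).
#' @param search_range Wavenumber window for peak location, cm^-1.
#' @param max_bin Maximum admissible bin width, cm^-1.
#' @return `fp_spectrum_config`.
#' @export
spectrum_config <- function(segment_ps = 5, window = c("hann", "rectangular"),
                            overlap = 0.5, search_range = c(1300, 2100),
                            max_bin = 10) {
  window <- match.arg(window)
  bin <- 1 / (fp_constants$c_cm_fs * segment_ps * 1000)
  if (bin > max_bin)
    stop("segment of ", segment_ps, " ps gives bin width ", signif(bin, 3),
         " cm^-1 > ", max_bin, " cm^-1")
  n_periods <- segment_ps * 1000 * fp_constants$c_cm_fs * min(search_range)
  if (n_periods < 10)
    stop("segment covers only ", signif(n_periods, 3),
         " periods at ", min(search_range), " cm^-1 (need >= 10)")
  structure(list(segment_ps = segment_ps, window = window, overlap = overlap,
                 search_range = search_range, bin = bin),
            class = "fp_spectrum_config")
}

#' C=O stretch velocity time series
#'
#' One series per backbone C=O bond: the rate of change of the bond length
#' by central differences of the recorded frames.  The frame stride must
#' resolve the stretch: the Nyquist wavenumber 1/(2 c dt) must exceed the
#' top of the analysis range.
#'
#' @param traj `fp_trajectory`.
#' @param system `fp_system` the trajectory was run from.
#' @param nu_max Highest wavenumber to resolve, cm^-1.
#' @return Matrix (time points x bonds) of d(bond length)/dt in A/fs, with
#'   attribute `dt_fs` (sampling interval).
#' @export
co_stretch_series <- function(traj, system, nu_max = 2000) {
  co <- system$bonds[system$bonds$type == "C-O", , drop = FALSE]
  if (!nrow(co)) stop("system has no C=O bonds")
  nf <- n_frames(traj)
  if (nf < 3) stop("need at least 3 frames for a velocity series")
  dt <- (traj$times[2] - traj$times[1]) * 1000  # fs
  nyq <- 1 / (2 * fp_constants$c_cm_fs * dt)
  if (nyq < nu_max)
    stop("frame stride ", dt, " fs gives Nyquist limit ", round(nyq),
         " cm^-1 < ", nu_max, " cm^-1; store frames more often")
  L <- if (is.null(traj$box) || is.na(traj$box)) NA else traj$box
  d <- matrix(0, nf, nrow(co))
  for (b in seq_len(nrow(co))) {
    dx <- traj$coords[co$i[b], , ] - traj$coords[co$j[b], , ]
    if (!is.na(L)) dx <- .min_image(dx, L)
    d[, b] <- sqrt(colSums(dx^2))
  }
  v <- (d[-(1:2), , drop = FALSE] - d[seq_len(nf - 2), , drop = FALSE]) / (2 * dt)
  attr(v, "dt_fs") <- dt
  v
}

#' Welch power spectrum of bond-velocity series
#'
#' @param series Matrix (time x bonds) as from [co_stretch_series()], or a
#'   numeric vector for a single series.
#' @param config `fp_spectrum_config`.
#' @param dt_fs Sampling interval; taken from the series attribute when
#'   absent.
#' @return `fp_spectrum`: list with `wavenumber` (cm^-1), `intensity`,
#'   `peak` (cm^-1, NA when the spectrum is flat zero), `bin` and
#'   `n_segments`.
#' @export
power_spectrum <- function(series, config = spectrum_config(),
                           dt_fs = attr(series, "dt_fs")) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  if (is.null(dt_fs)) stop("sampling interval dt_fs not supplied")
  M <- round(config$segment_ps * 1000 / dt_fs)
  nt <- nrow(series)
  if (nt < M) stop("series (", nt, " points) shorter than one segment (",
                   M, " points)")
  step <- max(1, round(M * (1 - config$overlap)))
  starts <- seq(1, nt - M + 1, by = step)
  w <- if (config$window == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(M) / (M + 1))) else rep(1, M)
  wnorm <- sum(w^2)
  nk <- M %/% 2
  acc <- numeric(nk)
  nseg <- 0L
  for (b in seq_len(ncol(series))) for (s0 in starts) {
    x <- series[s0:(s0 + M - 1), b]
    x <- (x - mean(x)) * w
    X <- stats::fft(x)
    p <- Mod(X[2:(nk + 1)])^2 / (M * wnorm) * 2  # one-sided, Parseval-normalised
    acc <- acc + p
    nseg <- nseg + 1L
  }
  acc <- acc / nseg
  freq <- seq_len(nk) / (M * dt_fs)              # 1/fs
  wavenumber <- freq / fp_constants$c_cm_fs      # cm^-1
  sel <- wavenumber >= config$search_range[1] & wavenumber <= config$search_range[2]
  peak <- NA_real_
  if (any(sel) && max(acc) > 0 && stats::sd(acc) > 0) {
    iset <- which(sel)
    peak <- wavenumber[iset[which.max(acc[iset])]]
  }
  structure(list(wavenumber = wavenumber, intensity = acc, peak = peak,
                 bin = config$bin, n_segments = nseg),
            class = "fp_spectrum")
}

#' @export
print.fp_spectrum <- function(x, ...) {
  cat("fp_spectrum:", length(x$wavenumber), "bins |",
      if (is.na(x$peak)) "no peak (flat spectrum)" else
        paste0("peak ", round(x$peak, 1), " +/- ", round(x$bin, 1), " cm^-1"),
      "\n")
  invisible(x)
}

#' Determine the amide-I resonance wavenumber of a system
#'
#' Runs a short equilibrium trajectory with high-frequency output (frames
#' every `sample_fs`), computes the C=O stretch velocity power spectrum
#' and returns the peak wavenumber.  This value is what feeds the pulse
#' train's `nu` in the irradiation protocol.
#'
#' @param system `fp_system` with calibrated force field.
#' @param ff `fp_forcefield`.
#' @param config `fp_run_config` (output stride is overridden by
#'   `sample_fs`).
#' @param spec_config `fp_spectrum_config`.
#' @param duration Production length, ps.
#' @param equilibration Discarded initial span, ps.
#' @param sample_fs Frame sampling interval, fs.
#' @return Peak wavenumber (cm^-1) with attributes `bin` (uncertainty) and
#'   `spectrum` (the full `fp_spectrum`).
#' @export
determine_resonance <- function(system, ff = default_forcefield(),
                                config = run_config(),
                                spec_config = spectrum_config(),
                                duration = 20, equilibration = 2,
                                sample_fs = 2) {
  config$out_stride <- sample_fs
  traj <- run_md(system, ff, config, duration = equilibration + duration)
  keep <- traj$times >= equilibration
  traj$coords <- traj$coords[, , keep, drop = FALSE]
  traj$times <- traj$times[keep]
  v <- co_stretch_series(traj, system, nu_max = max(spec_config$search_range))
  sp <- power_spectrum(v, spec_config)
  if (is.na(sp$peak)) stop("flat spectrum: no resonance peak found")
  structure(sp$peak, bin = sp$bin, spectrum = sp)
}

#' Write a spectrum as CSV plus JSON summary
#'
#' @param sp `fp_spectrum`.
#' @param path CSV output path; the JSON summary goes to `path`.json.
#' @param provenance Optional named list stored in the summary.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path, provenance = list()) {
  utils::write.csv(data.frame(wavenumber = sp$wavenumber,
                              intensity = sp$intensity),
                   path, row.names = FALSE)
  jsonlite::write_json(c(list(peak = sp$peak, bin = sp$bin,
                              n_segments = sp$n_segments), provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
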