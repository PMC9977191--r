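#' Analysis frequency grid for segmented spectra
#'
#' The natural frequency resolution of an unpadded discrete Fourier
#' transform of a segment is \code{1/segment_duration}; the analysis grid
#' runs from the lower to the upper band edge inclusively at that step.
#' Both band endpoints must sit on the natural grid. 4-s segments with a
#' 2--30 Hz band give 113 bins at 0.25 Hz.
#'
#' @param segment_duration segment length in seconds.
#' @param band length-2 numeric, band edges in Hz (low < high).
#' @return Numeric vector of bin frequencies in Hz.
#' @export
frequency_grid <- function(segment_duration, band) {
  if (!is.numeric(segment_duration) || segment_duration <= 0)
    stop("`segment_duration` must be positive", call. = FALSE)
  if (length(band) != 2L || band[1] >= band[2])
    stop("`band` must be (low, high) with low < high", call. = FALSE)
  step <- 1 / segment_duration
  k <- band / step
  if (any(abs(k - round(k)) > 1e-9))
    stop("band endpoints must be multiples of 1/segment_duration = ",
         signif(step, 6), " Hz; use e.g. (",
         round(k[1]) * step, ", ", round(k[2]) * step, ")", call. = FALSE)
  seq(from = round(k[1]) * step, by = step,
      length.out = round(k[2]) - round(k[1]) + 1L)
}

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first \code{k} dpss tapers of length \code{n} with
#' time-bandwidth product \code{nw}, as eigenvectors of the classical
#' symmetric tridiagonal matrix that commutes with the spectral
#' concentration operator. The largest \code{k} eigenvalues are located by
#' Sturm-sequence bisection and the eigenvectors obtained by inverse
#' iteration with a pivoted tridiagonal solver, so the cost is O(n k) and
#' long tapers (n in the thousands) are cheap.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (typically 2 to 8).
#' @param k number of tapers (at most \code{2 nw - 1} for well-concentrated
#'   tapers).
#' @return n x k matrix; columns are unit-norm tapers, order 0 first.
#' @export
dpss_tapers <- function(n, nw, k) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  w <- nw / n
  if (w >= 0.5) stop("nw/n must be < 0.5", call. = FALSE)
  t0 <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  ev <- tridiag_top_eigenvalues(diag_main, off, k)
  tapers <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- tridiag_inverse_iteration(diag_main, off, ev[j])
    # polarity convention: symmetric tapers positive on average,
    # antisymmetric tapers start positive
    s <- sum(v)
    if (abs(s) > 1e-7 * sqrt(n)) {
      if (s < 0) v <- -v
    } else if (v[2] - v[1] < 0) v <- -v
    tapers[, j] <- v
  }
  attr(tapers, "eigenvalues") <- ev
  tapers
}

# Number of eigenvalues of the symmetric tridiagonal matrix strictly below
# each shift in `x` (Sturm / LDL^T sign count), vectorised over shifts.
tridiag_count_below <- function(diag_main, off, x) {
  m <- length(x)
  cnt <- integer(m)
  q <- diag_main[1] - x
  cnt <- cnt + (q < 0)
  off2 <- off^2
  tiny <- .Machine$double.xmin
  for (i in 2:length(diag_main)) {
    q[q == 0] <- tiny
    q <- (diag_main[i] - x) - off2[i - 1] / q
    cnt <- cnt + (q < 0)
  }
  cnt
}

# k largest eigenvalues, descending, by simultaneous bisection.
tridiag_top_eigenvalues <- function(diag_main, off, k) {
  n <- length(diag_main)
  r <- c(abs(off), 0) + c(0, abs(off))   # Gershgorin radii
  lo0 <- min(diag_main - r); hi0 <- max(diag_main + r)
  # j-th target (descending): eigenvalue with exactly n - j eigenvalues below
  lo <- rep(lo0, k); hi <- rep(hi0, k)
  target <- n - seq_len(k)    # want count_below(lambda_j^-) == target[j]
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    cb <- tridiag_count_below(diag_main, off, mid)
    up <- cb > target            # mid above the target eigenvalue
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
    if (max(hi - lo) < 1e-12 * max(abs(hi0), abs(lo0))) break
  }
  (lo + hi) / 2
}

# Solve (T - shift I) x = b for tridiagonal T via LU with partial
# pivoting (second superdiagonal fill-in).
tridiag_shifted_solve <- function(diag_main, off, shift, b) {
  n <- length(diag_main)
  a <- c(off, 0)                # subdiagonal (a[i] couples i+1 to i)
  d <- diag_main - shift        # main diagonal
  c1 <- c(off, 0)               # first superdiagonal
  c2 <- numeric(n)              # fill-in second superdiagonal
  x <- b
  for (i in 1:(n - 1)) {
    if (abs(a[i]) > abs(d[i])) {  # pivot rows i, i+1
      tmp <- d[i]; d[i] <- a[i]; a[i] <- tmp
      tmp <- c1[i]; c1[i] <- d[i + 1]; d[i + 1] <- tmp
      tmp <- c2[i]; c2[i] <- c1[i + 1]; c1[i + 1] <- tmp
      tmp <- x[i]; x[i] <- x[i + 1]; x[i + 1] <- tmp
    }
    if (d[i] == 0) d[i] <- .Machine$double.eps
    m <- a[i] / d[i]
    d[i + 1] <- d[i + 1] - m * c1[i]
    c1[i + 1] <- c1[i + 1] - m * c2[i]
    x[i + 1] <- x[i + 1] - m * x[i]
  }
  if (d[n] == 0) d[n] <- .Machine$double.eps
  x[n] <- x[n] / d[n]
  x[n - 1] <- (x[n - 1] - c1[n - 1] * x[n]) / d[n - 1]
  if (n > 2) for (i in (n - 2):1)
    x[i] <- (x[i] - c1[i] * x[i + 1] - c2[i] * x[i + 2]) / d[i]
  x
}

tridiag_inverse_iteration <- function(diag_main, off, lambda, iters = 4L) {
  n <- length(diag_main)
  set_local <- sin(seq_len(n))  # deterministic, non-degenerate start
  v <- set_local / sqrt(sum(set_local^2))
  for (it in seq_len(iters)) {
    v <- tridiag_shifted_solve(diag_main, off, lambda, v)
    v <- v / sqrt(sum(v^2))
  }
  v
}

#' Multitaper power spectral density of segmented data
#'
#' mtmfft-style estimator: each segment is demeaned, multiplied by each of
#' \code{K = 2 * duration * smoothing - 1} dpss tapers with time-bandwidth
#' product \code{NW = duration * smoothing} (so \code{smoothing} is the
#' half-bandwidth of spectral concentration in Hz), Fourier transformed,
#' and the squared magnitudes are averaged over tapers and then over
#' segments. The output lives on the natural one-sided grid
#' \code{0, 1/duration, ..., fs/2}; absolute units are arbitrary up to a
#' fixed constant, which cancels in \code{\link{relative_power}}.
#'
#' @param segments numeric matrix, segments in rows and samples in columns
#'   (all segments the same length).
#' @param fs sampling rate in Hz.
#' @param smoothing spectral smoothing half-bandwidth in Hz (default 1).
#' @return A \code{power_spectrum} object: list with \code{freqs} (Hz),
#'   \code{power} (nonnegative vector), \code{kind = "absolute"},
#'   \code{segment_duration}, \code{n_tapers}.
#' @export
multitaper_psd <- function(segments, fs, smoothing = 1) {
  if (is.vector(segments)) segments <- matrix(segments, nrow = 1L)
  stopifnot(is.matrix(segments), fs > 0, smoothing > 0)
  nsamp <- ncol(segments)
  if (nsamp < 2L) stop("segments too short", call. = FALSE)
  duration <- nsamp / fs
  nw <- duration * smoothing
  if (nw < 1) stop("smoothing * duration must be >= 1 (at least one taper)",
                   call. = FALSE)
  K <- max(1L, as.integer(floor(2 * nw - 1 + 1e-9)))
  tapers <- dpss_tapers(nsamp, nw, K)
  xt <- t(segments - rowMeans(segments))      # time x segment, demeaned
  nkeep <- floor(nsamp / 2) + 1L
  acc <- matrix(0, nkeep, ncol(xt))
  for (k in seq_len(K)) {
    ft <- stats::mvfft(xt * tapers[, k])
    acc <- acc + (Mod(ft[seq_len(nkeep), , drop = FALSE]))^2
  }
  pwr <- rowMeans(acc) / K
  structure(list(freqs = (seq_len(nkeep) - 1L) / duration,
                 power = pwr, kind = "absolute",
                 segment_duration = duration, n_tapers = K),
            class = "power_spectrum")
}

#' Convert a power spectrum to relative power over a band
#'
#' Each bin inside the band (endpoints inclusive) is divided by the total
#' power over the band; bins outside the band are dropped. Relative power
#' makes spectra comparable across subjects and nodes. The operation is
#' idempotent: relative power of a relative spectrum over the same band is
#' unchanged.
#'
#' @param psd a \code{power_spectrum}, or a numeric matrix of spectra
#'   (rows = nodes, columns = frequency bins) with frequencies supplied in
#'   \code{freqs}.
#' @param band length-2 numeric band in Hz, default \code{c(2, 30)}.
#' @param freqs frequencies for matrix input, ignored for
#'   \code{power_spectrum} input.
#' @return A \code{power_spectrum} with \code{kind = "relative"} (vector
#'   input), or a list with \code{freqs} and row-normalised \code{power}
#'   matrix (matrix input). Band sums equal 1.
#' @export
relative_power <- function(psd, band = c(2, 30), freqs = NULL) {
  if (inherits(psd, "power_spectrum")) {
    f <- psd$freqs; p <- psd$power
    sel <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
    if (!any(sel)) stop("band outside spectrum range", call. = FALSE)
    tot <- sum(p[sel])
    if (tot <= 0)
      stop("zero power over the band: degenerate (dead) channel",
           call. = FALSE)
    out <- psd
    out$freqs <- f[sel]
    out$power <- p[sel] / tot
    out$kind <- "relative"
    return(out)
  }
  stopifnot(is.matrix(psd), !is.null(freqs), length(freqs) == ncol(psd))
  sel <- freqs >= band[1] - 1e-9 & freqs <= band[2] + 1e-9
  sub <- psd[, sel, drop = FALSE]
  tot <- rowSums(sub)
  if (any(tot <= 0))
    stop("zero band power in row(s): ",
         paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  list(freqs = freqs[sel], power = sub / tot, kind = "relative")
}
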