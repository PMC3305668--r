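# Inter-frame shift estimation by phase correlation, used to correct for
# patient/C-arm motion between snapshots before re-using a previous pose
# solution.

#' Estimate the translation between two frames
#'
#' Phase correlation: the normalized cross-power spectrum of the two frames
#' has a delta-like inverse transform at the displacement. The integer peak
#' is refined to subpixel precision by a local upsampled DFT evaluation.
#' Returns the displacement `(du, dv)` such that `frame_b` is `frame_a`
#' shifted by that many pixels (content moving right/down is positive), with
#' a confidence equal to the ratio of the main peak to the second-highest
#' peak outside its neighborhood.
#'
#' @param frame_a,frame_b equal-size numeric matrices.
#' @param upsample subpixel grid refinement factor.
#' @return list with `shift_px` (length 2), `confidence` and `peak`.
#' @export
estimate_frame_shift <- function(frame_a, frame_b, upsample = 20L) {
  stopifnot(is.matrix(frame_a), all(dim(frame_a) == dim(frame_b)))
  h <- nrow(frame_a); w <- ncol(frame_a)
  fa <- stats::fft(frame_a - mean(frame_a))
  fb <- stats::fft(frame_b - mean(frame_b))
  cp <- fb * Conj(fa)
  mag <- Mod(cp)
  q <- cp / pmax(mag, 1e-12 * max(mag, 1e-300))
  corr <- Re(stats::fft(q, inverse = TRUE)) / (h * w)
  pk <- unname(which(corr == max(corr), arr.ind = TRUE)[1, ])
  # wrap indices to signed shifts
  dv <- pk[1] - 1L; if (dv > h / 2) dv <- dv - h
  du <- pk[2] - 1L; if (du > w / 2) du <- du - w
  peak1 <- max(corr)
  # second peak outside a 5x5 neighborhood of the first
  vidx <- ((pk[1] - 3):(pk[1] + 3) - 1) %% h + 1
  uidx <- ((pk[2] - 3):(pk[2] + 3) - 1) %% w + 1
  masked <- corr
  masked[vidx, uidx] <- -Inf
  peak2 <- max(masked)
  confidence <- if (is.finite(peak2) && peak2 > 0) peak1 / peak2 else Inf

  # subpixel refinement: evaluate the inverse DFT of q on a fine local grid
  kv <- c(0:(floor(h / 2)), (ceiling(h / 2) - h + 1):-1)[1:h]
  ku <- c(0:(floor(w / 2)), (ceiling(w / 2) - w + 1):-1)[1:w]
  fine <- seq(-1, 1, length.out = 2L * upsample + 1L)
  Ev <- exp(2i * pi * outer(fine + dv, kv) / h)        # nf x h
  Eu <- exp(2i * pi * outer(ku, fine + du) / w)        # w x nf
  local <- Re(Ev %*% q %*% Eu) / (h * w)
  m <- which(local == max(local), arr.ind = TRUE)[1, ]
  shift <- c(du + fine[m[2]], dv + fine[m[1]])
  # parabolic polish within the fine grid
  if (m[1] > 1 && m[1] < nrow(local)) {
    y <- local[(m[1] - 1):(m[1] + 1), m[2]]
    den <- y[1] - 2 * y[2] + y[3]
    if (abs(den) > 1e-15) {
      shift[2] <- shift[2] + 0.5 * (y[1] - y[3]) / den * (fine[2] - fine[1])
    }
  }
  if (m[2] > 1 && m[2] < ncol(local)) {
    y <- local[m[1], (m[2] - 1):(m[2] + 1)]
    den <- y[1] - 2 * y[2] + y[3]
    if (abs(den) > 1e-15) {
      shift[1] <- shift[1] + 0.5 * (y[1] - y[3]) / den * (fine[2] - fine[1])
    }
  }
  list(shift_px = shift, confidence = confidence, peak = peak1)
}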