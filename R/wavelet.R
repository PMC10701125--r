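#' Undecimated 2-D Haar wavelet channels
#'
#' Single-level, per-slice stationary Haar decomposition with averaging
#' filter (1/2, 1/2) and differencing filter (1/2, -1/2), edge-replicated.
#' Because the transform is undecimated, every subband is congruent with the
#' input, so the original muscle mask applies to all channels unchanged.
#' Channel naming is `<horizontal><vertical>`: the first letter is the
#' filter applied along the image rows' horizontal axis (column index), the
#' second along the vertical axis.
#'
#' @param slab a [ct_slab()] or a 3-D array.
#' @return Named list of five arrays congruent with the input:
#'   `Original`, `Wavelet(LL)`, `Wavelet(LH)`, `Wavelet(HL)`, `Wavelet(HH)`.
#' @examples
#' ch <- wavelet_channels(ct_slab(array(7, c(4, 4, 1)), 1))
#' range(ch[["Wavelet(HH)"]])  # 0 for a constant image
#' @export
wavelet_channels <- function(slab) {
  vox <- if (inherits(slab, "ct_slab")) slab$voxels else slab
  d <- dim(vox)
  if (d[1] < 2 || d[2] < 2)
    stop("slab must be at least 2 x 2 in-plane for the wavelet transform",
         call. = FALSE)
  shift_col <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]
  shift_row <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]
  mk <- function() array(0, d)
  out <- list(`Original` = vox, `Wavelet(LL)` = mk(), `Wavelet(LH)` = mk(),
              `Wavelet(HL)` = mk(), `Wavelet(HH)` = mk())
  for (s in seq_len(d[3])) {
    m <- vox[, , s]
    lh <- (m + shift_col(m)) / 2   # horizontal low-pass
    hh <- (m - shift_col(m)) / 2   # horizontal high-pass
    out[["Wavelet(LL)"]][, , s] <- (lh + shift_row(lh)) / 2
    out[["Wavelet(LH)"]][, , s] <- (lh - shift_row(lh)) / 2
    out[["Wavelet(HL)"]][, , s] <- (hh + shift_row(hh)) / 2
    out[["Wavelet(HH)"]][, , s] <- (hh - shift_row(hh)) / 2
  }
  out
}
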