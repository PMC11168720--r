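#' Topographic scalp map of per-channel statistics
#'
#' Inverse-distance-weighted interpolation of per-channel values on a head
#' disc. For a corrected `stat_map`, non-significant regions are white,
#' the effect sign is colour-coded (red = preictal higher, blue = lower) and
#' darkness encodes the p value. For plain numeric values a diverging
#' red-white-blue scale is used.
#'
#' @param values a corrected `stat_map` or a numeric vector (one value per
#'   channel).
#' @param montage_xy data.frame with `label`, `x`, `y`; defaults to the
#'   built-in montage for `stat_map` channels.
#' @param grid_n interpolation grid resolution per axis (default 80).
#' @param idw_power inverse-distance weighting exponent (default 2).
#' @param draw plot the map (default TRUE); the interpolated field is always
#'   returned invisibly.
#' @param main title.
#' @return invisibly, a list with `x`, `y`, `z` (interpolated field, `NA`
#'   outside the disc) and `col` (the colour map used).
#' @export
render_topomap <- function(values, montage_xy = NULL, grid_n = 80L,
                           idw_power = 2, draw = TRUE, main = "") {
  if (inherits(values, "stat_map")) {
    if (is.null(montage_xy)) montage_xy <- montage_1020(values$channel)
    sig <- if (!is.null(values$corrected_significant))
      values$corrected_significant else values$raw_significant
    # signed significance strength: sign * -log10(p), zeroed where NS
    v <- ifelse(sig, values$sign * -log10(pmax(values$p, 1e-16)), 0)
  } else {
    v <- as.numeric(values)
    if (is.null(montage_xy)) stopf("montage_xy required for plain values")
  }
  if (length(v) < 3L) stopf("need at least 3 channels to interpolate")
  stopifnot(nrow(montage_xy) == length(v))
  r <- max(sqrt(montage_xy$x^2 + montage_xy$y^2)) * 1.05
  gx <- seq(-r, r, length.out = grid_n)
  gy <- seq(-r, r, length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    dx2 <- (gx[i] - montage_xy$x)^2
    for (j in seq_len(grid_n)) {
      if (gx[i]^2 + gy[j]^2 > r^2) next
      d2 <- dx2 + (gy[j] - montage_xy$y)^2
      hit <- which(d2 < 1e-12)
      z[i, j] <- if (length(hit)) v[hit[1L]] else {
        w <- 1 / d2^(idw_power / 2)
        sum(w * v) / sum(w)
      }
    }
  }
  neg <- grDevices::colorRampPalette(c("#08306b", "#c6dbef", "white"))(50)
  pos <- grDevices::colorRampPalette(c("white", "#fcbba1", "#67000d"))(50)
  col <- c(neg, pos)
  if (draw) {
    zmax <- max(abs(z), na.rm = TRUE)
    if (zmax == 0) zmax <- 1
    graphics::image(gx, gy, z, zlim = c(-zmax, zmax), col = col, asp = 1,
                    axes = FALSE, xlab = "", ylab = "", main = main)
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(r * cos(th), r * sin(th))
    graphics::points(montage_xy$x, montage_xy$y, pch = 20, cex = 0.5)
  }
  invisible(list(x = gx, y = gy, z = z, col = col))
}
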