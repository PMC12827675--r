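## Pseudo-color enhancement (PCE): a grayscale lesion patch is taken into
## HSV space, the hue channel is shifted by a fixed offset (modulo 180),
## saturation and value are scaled with clipping at 255, and the result is
## converted back to RGB. The 8-bit OpenCV-style HSV convention is used
## throughout: H in [0, 179], S and V in [0, 255]. Model-facing patches are
## floats in [0, 1]; colorspace arithmetic runs on an 8-bit integer view
## (multiply by 255, round half up).

round_half_up <- function(x) floor(x + 0.5)

#' Enhancement parameters for the pseudo-color transform
#'
#' @param delta_h integer hue shift (applied modulo 180). Default 30.
#' @param alpha saturation scale factor, >= 0. Default 0.8.
#' @param beta value (brightness) scale factor, >= 0. Default 15. Note that
#'   `beta = 15` saturates every pixel whose value is at least 17/255 of
#'   full scale; the clipping is applied literally.
#' @param colorize_mode how a single-channel image acquires color before the
#'   HSV adjustment. `"intensity_to_hue"` (default) maps intensity directly
#'   into hue (`H = round(intensity * 179)`, `S = 255`,
#'   `V = round(intensity * 255)`), producing a visibly colored image.
#'   `"replicate"` replicates the gray channel into RGB first, which leaves
#'   saturation zero and hue degenerate; both readings are supported.
#' @return a `pce_params` object.
#' @export
#' @examples
#' pce_params() # the default operating point
pce_params <- function(delta_h = 30L, alpha = 0.8, beta = 15,
                       colorize_mode = c("intensity_to_hue", "replicate")) {
  colorize_mode <- match.arg(colorize_mode)
  if (abs(delta_h - round(delta_h)) > 1e-8)
    stop("delta_h must be an integer hue shift")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  structure(list(delta_h = as.integer(round(delta_h)), alpha = alpha,
                 beta = beta, colorize_mode = colorize_mode),
            class = "pce_params")
}

#' Hue shift with modulo wrap-around
#'
#' Adds `delta_h` to every hue value and wraps into the valid 8-bit hue
#' range: `(H + delta_h) mod 180`.
#'
#' @param H hue channel, integer-valued in `[0, 179]` (non-integer input is
#'   rejected).
#' @param delta_h integer shift (any sign).
#' @return shifted hue channel in `[0, 179]`, same shape as `H`.
#' @export
#' @examples
#' adjust_hue(160, 30) # 10
adjust_hue <- function(H, delta_h) {
  if (any(abs(H - round(H)) > 1e-8))
    stop("hue channel must be integer-valued (round before calling)")
  if (abs(delta_h - round(delta_h)) > 1e-8)
    stop("delta_h must be an integer")
  if (any(H < 0 | H > 179)) stop("hue values must lie in [0, 179]")
  out <- (round(H) + round(delta_h)) %% 180
  dim(out) <- dim(H)
  out
}

#' Saturation scaling with clipping
#'
#' `min(S * alpha, 255)`, elementwise.
#'
#' @param S saturation channel in `[0, 255]`; @param alpha scale, >= 0.
#' @return scaled channel in `[0, 255]`.
#' @export
adjust_saturation <- function(S, alpha) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (any(S < 0 | S > 255)) stop("saturation values must lie in [0, 255]")
  pmin(S * alpha, 255)
}

#' Value (brightness) scaling with clipping
#'
#' `min(V * beta, 255)`, elementwise.
#'
#' @param V value channel in `[0, 255]`; @param beta scale, >= 0.
#' @return scaled channel in `[0, 255]`.
#' @export
adjust_value <- function(V, beta) {
  if (beta < 0) stop("beta must be non-negative")
  if (any(V < 0 | V > 255)) stop("value channel must lie in [0, 255]")
  pmin(V * beta, 255)
}

## RGB (8-bit) -> HSV (H in [0,179], S/V in [0,255]).
rgb8_to_hsv8 <- function(rgb) {
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  V <- mx
  S <- ifelse(mx > 0, round_half_up(255 * delta / pmax(mx, 1)), 0)
  S[mx == 0] <- 0
  H360 <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  isr <- nz & (mx == r)
  isg <- nz & (mx == g) & !isr
  isb <- nz & !isr & !isg
  H360[isr] <- (60 * (g[isr] - b[isr]) / delta[isr]) %% 360
  H360[isg] <- 60 * (b[isg] - r[isg]) / delta[isg] + 120
  H360[isb] <- 60 * (r[isb] - g[isb]) / delta[isb] + 240
  H <- round_half_up(H360 / 2) %% 180
  list(H = H, S = S, V = V)
}

## HSV (H in [0,179], S/V in [0,255]) -> RGB (8-bit).
hsv8_to_rgb8 <- function(H, S, V) {
  H <- as.matrix(H); S <- as.matrix(S); V <- as.matrix(V)
  h <- (2 * H) / 60 # sector coordinate in [0, 6)
  s <- S / 255; v <- V / 255
  cc <- v * s
  xx <- cc * (1 - abs(h %% 2 - 1))
  m <- v - cc
  sec <- floor(h) %% 6
  rp <- ifelse(sec == 0 | sec == 5, cc, ifelse(sec == 1 | sec == 4, xx, 0))
  gp <- ifelse(sec == 0 | sec == 3, xx, ifelse(sec == 1 | sec == 2, cc, 0))
  bp <- ifelse(sec == 2 | sec == 5, xx, ifelse(sec == 3 | sec == 4, cc, 0))
  out <- array(0, c(nrow(H), ncol(H), 3))
  out[, , 1] <- round_half_up((rp + m) * 255)
  out[, , 2] <- round_half_up((gp + m) * 255)
  out[, , 3] <- round_half_up((bp + m) * 255)
  out
}

#' Pseudo-color enhancement of a grayscale patch
#'
#' Colorizes the patch (per `params$colorize_mode`), converts to 8-bit HSV,
#' applies hue shift, saturation scaling and value scaling in that order,
#' and converts back to RGB.
#'
#' @param patch numeric matrix with values in `[0, 1]`.
#' @param params a [pce_params()] object.
#' @return `[H, W, 3]` array of RGB values in `[0, 1]`.
#' @export
#' @examples
#' p <- matrix(seq(0, 1, length.out = 64), 8, 8)
#' enh <- enhance_patch(p, pce_params())
enhance_patch <- function(patch, params = pce_params()) {
  stopifnot(inherits(params, "pce_params"))
  if (length(patch) == 0L) stop("empty patch")
  patch <- as.matrix(patch)
  if (any(patch < 0 | patch > 1)) stop("patch values must lie in [0, 1]")
  g8 <- round_half_up(patch * 255)
  if (params$colorize_mode == "replicate") {
    rgb <- array(0, c(nrow(patch), ncol(patch), 3))
    rgb[, , 1] <- g8; rgb[, , 2] <- g8; rgb[, , 3] <- g8
    hsv <- rgb8_to_hsv8(rgb)
  } else {
    hsv <- list(H = round_half_up(patch * 179),
                S = matrix(255, nrow(patch), ncol(patch)),
                V = round_half_up(patch * 255))
  }
  H <- adjust_hue(hsv$H, params$delta_h)
  S <- adjust_saturation(hsv$S, params$alpha)
  V <- adjust_value(hsv$V, params$beta)
  hsv8_to_rgb8(H, S, V) / 255
}

#' Histogram equalization (8-bit) of a grayscale patch
#'
#' Standard CDF-based 8-bit histogram equalization, the conventional
#' enhancement baseline. A constant patch (degenerate histogram) is
#' returned unchanged.
#'
#' @param patch numeric matrix in `[0, 1]`.
#' @return equalized matrix in `[0, 1]`, same shape.
#' @export
histogram_equalize <- function(patch) {
  if (length(patch) == 0L) stop("empty patch")
  patch <- as.matrix(patch)
  if (any(patch < 0 | patch > 1)) stop("patch values must lie in [0, 1]")
  g8 <- round_half_up(patch * 255)
  counts <- tabulate(g8 + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  npx <- length(g8)
  if (npx == cdf_min) return(patch) # constant image
  map <- round_half_up(255 * (cdf - cdf_min) / (npx - cdf_min))
  out <- matrix(map[g8 + 1L], nrow(patch), ncol(patch))
  out / 255
}

#' Read / write patches as 8-bit PNG for inspection
#'
#' @param x a grayscale matrix in `[0, 1]` or an `[H, W, 3]` RGB array.
#' @param path PNG file path.
#' @export
write_patch_png <- function(x, path) {
  png::writePNG(clamp(x, 0, 1), target = path)
  invisible(path)
}

#' @rdname write_patch_png
#' @export
read_patch_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE] # drop alpha
  img
}
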