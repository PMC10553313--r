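#' Square attention box
#'
#' An attention region is a square parameterised by its centre `(tx, ty)`
#' and half side length `tl`, in 0-based pixel-centre coordinates with x
#' rightward and y downward (origin at the upper-left pixel centre).
#'
#' @param tx,ty Box centre, in pixels.
#' @param tl Half side length, in pixels; must be positive.
#' @return An object of class `attention_box` (a named list).
#' @examples
#' box <- attention_box(100, 80, 30)
#' box_corners(box)
#' @export
attention_box <- function(tx, ty, tl) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(tl))
  if (tl <= 0) stop("half side length `tl` must be positive")
  structure(list(tx = as.numeric(tx), ty = as.numeric(ty),
                 tl = as.numeric(tl)),
            class = "attention_box")
}

#' @export
print.attention_box <- function(x, ...) {
  cat(sprintf("<attention_box> centre (%.2f, %.2f), half length %.2f\n",
              x$tx, x$ty, x$tl))
  invisible(x)
}

#' Corners of an attention box
#'
#' The upper-left corner is `(tx - tl, ty - tl)` and the lower-right corner
#' is `(tx + tl, ty + tl)`.
#'
#' @param box An [attention_box()].
#' @return Named numeric vector `(tx_tl, ty_tl, tx_br, ty_br)`.
#' @export
box_corners <- function(box) {
  c(tx_tl = box$tx - box$tl, ty_tl = box$ty - box$tl,
    tx_br = box$tx + box$tl, ty_br = box$ty + box$tl)
}

#' Crop configuration
#'
#' @param steepness Slope `k` of the logistic approximation to the step
#'   function in the soft-boxcar mask. Larger values make the mask closer
#'   to a hard 0/1 indicator; the default 10 keeps usable gradients at
#'   64-pixel resolution.
#' @param out_size Output side length of the zoomed crop, in pixels.
#' @param min_half_len Smallest admissible box half length, in pixels.
#' @param max_frac Largest admissible half length as a fraction of half the
#'   image side.
#' @return A `crop_config` list.
#' @export
crop_config <- function(steepness = 10, out_size = 64,
                        min_half_len = out_size / 8, max_frac = 0.45) {
  stopifnot(steepness > 0, is.finite(steepness), out_size >= 8,
            min_half_len > 0, max_frac > 0, max_frac <= 1)
  structure(list(steepness = steepness, out_size = as.integer(out_size),
                 min_half_len = min_half_len, max_frac = max_frac,
                 convention = "0-based pixel centres, x right, y down"),
            class = "crop_config")
}

#' Clamp a box into the image extent
#'
#' Shrinks `tl` into `[min_half_len, max_frac * side/2]` and moves the
#' centre so the square lies fully inside `[0, W-1] x [0, H-1]`. Clamping
#' an already-valid box is the identity.
#'
#' @param box An [attention_box()].
#' @param image_dim Integer `(H, W)` image extent in pixels.
#' @param cfg A [crop_config()].
#' @return A valid `attention_box`.
#' @export
clamp_box <- function(box, image_dim, cfg = crop_config()) {
  H <- image_dim[1]; W <- image_dim[2]
  tl <- min(max(box$tl, cfg$min_half_len),
            cfg$max_frac * min(H, W) / 2)
  tx <- min(max(box$tx, tl), (W - 1) - tl)
  ty <- min(max(box$ty, tl), (H - 1) - tl)
  attention_box(tx, ty, tl)
}

#' Soft boxcar attention mask
#'
#' Separable product mask
#' `M(x, y) = [H(x - tx_tl) - H(x - tx_br)] * [H(y - ty_tl) - H(y - ty_br)]`
#' with each step `H` approximated by the logistic `1 / (1 + exp(-k u))`.
#' The mask tends to the hard box indicator as `steepness` grows and is
#' differentiable everywhere in `(tx, ty, tl)`. Pixel-area convention:
#' pixel `x` spans `[x - 0.5, x + 0.5]`, so the soft edges sit half a
#' pixel outside the corners and a box whose corners land on pixel
#' centres fully includes those pixels in the hard limit.
#'
#' @param box An [attention_box()].
#' @param grid_shape Integer `(H, W)`.
#' @param steepness Logistic slope `k > 0`.
#' @return An `H x W` matrix with values in `(0, 1)`.
#' @export
attention_mask <- function(box, grid_shape, steepness = 10) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), steepness > 0)
  cpp_attention_mask(as.integer(grid_shape[1]), as.integer(grid_shape[2]),
                     box$tx, box$ty, box$tl, steepness)
}

#' Differentiable crop and zoom
#'
#' Multiplies the image elementwise with the soft boxcar mask of `box`,
#' then bilinearly resamples the square `[tx - tl, tx + tl] x
#' [ty - tl, ty + tl]` to `cfg$out_size` pixels per side. The whole map is
#' differentiable with respect to `(tx, ty, tl)` (see
#' [crop_and_zoom_grad()]), which lets classification gradients flow back
#' into the attention-proposal head.
#'
#' @param image `H x W x C` numeric array.
#' @param box An [attention_box()]; must lie inside the image (use
#'   [clamp_box()] first for arbitrary boxes).
#' @param cfg A [crop_config()].
#' @return `out_size x out_size x C` numeric array.
#' @export
crop_and_zoom <- function(image, box, cfg = crop_config()) {
  image <- as_image_array(image)
  if (anyNA(image)) stop("image contains NA/NaN pixels")
  cpp_crop_zoom(image, box$tx, box$ty, box$tl, cfg$steepness, cfg$out_size)
}

#' Backward pass of [crop_and_zoom()]
#'
#' Given the gradient of a scalar loss with respect to the crop output,
#' returns its gradient with respect to the box parameters `(tx, ty, tl)`
#' (analytic: grid-motion term plus mask-motion term) and with respect to
#' the source image.
#'
#' @param image Source image array `H x W x C`.
#' @param box The box used in the forward pass.
#' @param cfg The [crop_config()] used in the forward pass.
#' @param d_out Gradient array, same shape as the forward output.
#' @return List with `dbox` (length-3 numeric `(dtx, dty, dtl)`) and `dX`
#'   (array like `image`).
#' @export
crop_and_zoom_grad <- function(image, box, cfg, d_out) {
  image <- as_image_array(image)
  res <- cpp_crop_zoom_backward(image, box$tx, box$ty, box$tl,
                                cfg$steepness, cfg$out_size, d_out)
  list(dbox = as.numeric(res$dbox), dX = res$dX)
}

#' Sign structure of the mask derivative along x
#'
#' Numerically differentiates the mask with respect to the box centre `tx`
#' at probe x-locations (y fixed at the box centre) and classifies each
#' derivative as negative, zero, or positive with tolerance `eps`. For a
#' soft boxcar the derivative is negative near the left edge, positive
#' near the right edge, and vanishes deep inside and outside the box.
#'
#' @param box An [attention_box()].
#' @param probe_xs Numeric x-locations to probe.
#' @param grid_shape Integer `(H, W)`.
#' @param steepness Logistic slope.
#' @param eps Zero-classification tolerance.
#' @param h Finite-difference step.
#' @return Character vector in `{"neg", "zero", "pos"}`, one per probe.
#' @export
mask_gradient_signs <- function(box, probe_xs, grid_shape, steepness = 10,
                                eps = 1e-8, h = 1e-3) {
  y <- round(box$ty)
  vapply(probe_xs, function(px) {
    mval <- function(tx) {
      mx <- plogis(steepness * (px - (tx - box$tl) + 0.5)) -
        plogis(steepness * (px - (tx + box$tl) - 0.5))
      my <- plogis(steepness * (y - (box$ty - box$tl) + 0.5)) -
        plogis(steepness * (y - (box$ty + box$tl) - 0.5))
      mx * my
    }
    d <- (mval(box$tx + h) - mval(box$tx - h)) / (2 * h)
    if (d < -eps) "neg" else if (d > eps) "pos" else "zero"
  }, character(1))
}

#' @importFrom stats plogis
NULL

# Coerce greyscale matrices to H x W x 1 arrays; pass 3-d arrays through.
as_image_array <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  stopifnot(is.array(image), length(dim(image)) == 3)
  storage.mode(image) <- "double"
  image
}
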