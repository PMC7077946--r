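#' Similarity transform (scale, rotation, translation)
#'
#' Maps millimetre template coordinates into image pixel coordinates:
#' p' = s R(theta) p + t, with no reflection or shear.
#'
#' @param scale pixels per mm, > 0
#' @param rotation radians, counter-clockwise in the y-down pixel frame
#' @param translation length-2 numeric, pixels
#' @return an object of class `sct_transform`
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    sct_abort("scale", "must be a single finite value > 0")
  if (!is.numeric(rotation) || length(rotation) != 1 || !is.finite(rotation))
    sct_abort("rotation", "must be a single finite value (radians)")
  if (length(translation) != 2 || !all(is.finite(translation)))
    sct_abort("translation", "must be two finite values (px)")
  structure(list(scale = scale, rotation = rotation,
                 translation = as.numeric(translation)),
            class = "sct_transform")
}

#' @export
print.sct_transform <- function(x, ...) {
  cat(sprintf(
    "Similarity transform: scale %.6g px/mm, rotation %.6g rad, translation (%.6g, %.6g) px\n",
    x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Fit a similarity transform through two point correspondences
#'
#' The unique scale + rotation + translation (no reflection) mapping the two
#' source points exactly onto the two destination points, solved in closed
#' form via complex arithmetic: a = (d2 - d1)/(s2 - s1), b = d1 - a s1.
#' The default registration anchors the template's combined central-incisor
#' width — the distal incisal corners of teeth 11 and 21 — onto the same two
#' corners annotated on the photograph, so the central widths coincide.
#'
#' @param src 2x2 numeric matrix (rows = points) in the source (template)
#'   frame
#' @param dst 2x2 numeric matrix in the destination (pixel) frame
#' @return an `sct_transform`
#' @export
fit_transform <- function(src, dst) {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  if (nrow(src) != 2 || nrow(dst) != 2)
    sct_abort("src", "exactly two source and two destination points required")
  s <- complex(real = src[, 1], imaginary = src[, 2])
  d <- complex(real = dst[, 1], imaginary = dst[, 2])
  if (s[1] == s[2] || d[1] == d[2])
    sct_abort("src", "degenerate fit: the two points of a pair coincide")
  a <- (d[2] - d[1]) / (s[2] - s[1])
  b <- d[1] - a * s[1]
  similarity_transform(scale = Mod(a), rotation = Arg(a),
                       translation = c(Re(b), Im(b)))
}

#' Apply a similarity transform to coordinates
#'
#' @param tr an `sct_transform`
#' @param xy n x 2 matrix (or length-2 vector, or data frame with x/y)
#' @return transformed coordinates, same shape
#' @export
apply_transform <- function(tr, xy) {
  stopifnot(inherits(tr, "sct_transform"))
  df <- is.data.frame(xy)
  if (df) xy <- cbind(xy$x, xy$y)
  m <- matrix(as.numeric(xy), ncol = 2)
  cs <- tr$scale * cos(tr$rotation)
  sn <- tr$scale * sin(tr$rotation)
  out <- cbind(cs * m[, 1] - sn * m[, 2] + tr$translation[1],
               sn * m[, 1] + cs * m[, 2] + tr$translation[2])
  if (df) data.frame(x = out[, 1], y = out[, 2]) else
    if (is.null(dim(xy)) || length(xy) == 2) drop(out) else out
}

#' Invert a similarity transform
#'
#' @param tr an `sct_transform`
#' @return the inverse `sct_transform`; applying one after the other is the
#'   identity to machine precision
#' @export
invert_transform <- function(tr) {
  stopifnot(inherits(tr, "sct_transform"))
  inv_scale <- 1 / tr$scale
  th <- -tr$rotation
  cs <- inv_scale * cos(th); sn <- inv_scale * sin(th)
  t_inv <- c(-(cs * tr$translation[1] - sn * tr$translation[2]),
             -(sn * tr$translation[1] + cs * tr$translation[2]))
  similarity_transform(scale = inv_scale, rotation = th,
                       translation = t_inv)
}

#' Default registration anchors
#'
#' The template-frame source pair used when registering by the combined
#' central-incisor width: the distal incisal corners of teeth 11 and 21.
#'
#' @param geom an `sct_template`
#' @return 2x2 matrix, rows = (11 distal corner, 21 distal corner)
#' @export
default_anchors <- function(geom) {
  stopifnot(inherits(geom, "sct_template"))
  b11 <- geom$boxes[geom$boxes$tooth == "11", ]
  b21 <- geom$boxes[geom$boxes$tooth == "21", ]
  rbind(c(b11$x_distal, b11$y_incisal), c(b21$x_distal, b21$y_incisal))
}
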