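# Overlay rendering: vector-first SVG generation plus PNG compositing.
#
# The template line work is always produced as exact vector polylines in
# pixel coordinates; PNG output rasterizes those polylines directly on the
# photograph's own pixel grid, so the photograph is never resampled.

#' Overlay style
#'
#' @param color stroke colour, hex `#rrggbb`
#' @param line_width stroke width in output pixels
#' @param opacity stroke opacity in (0, 1]
#' @param crowns draw stylized rounded crown silhouettes (cosmetic only;
#'   the metric geometry is the boxes and lines)
#' @return a list of class `sct_style`
#' @export
overlay_style <- function(color = "#00a0c8", line_width = 2,
                          opacity = 0.6, crowns = TRUE) {
  if (!is.numeric(opacity) || length(opacity) != 1 || is.na(opacity) ||
      opacity <= 0 || opacity > 1)
    sct_abort("opacity", "must be in (0, 1]")
  if (!is.numeric(line_width) || line_width <= 0)
    sct_abort("line_width", "must be > 0")
  if (!grepl("^#[0-9a-fA-F]{6}$", color))
    sct_abort("color", "must be #rrggbb hex")
  structure(list(color = color, line_width = line_width, opacity = opacity,
                 crowns = crowns), class = "sct_style")
}

# flattened rounded-crown silhouette for one tooth box (quadratic Bezier
# rounding of the two gingival corners; cosmetic rendering only)
crown_outline <- function(box, r_frac = 0.3, n = 8) {
  w <- abs(box$x_distal - box$x_mesial)
  r <- r_frac * w
  x0 <- min(box$x_mesial, box$x_distal)
  x1 <- max(box$x_mesial, box$x_distal)
  yz <- box$y_zenith; yi <- box$y_incisal
  bez <- function(p0, p1, p2) {
    t <- seq(0, 1, length.out = n)
    cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
          (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
  }
  pts <- rbind(
    c(x0, yi),
    c(x0, yz + r),
    bez(c(x0, yz + r), c(x0, yz), c(x0 + r, yz)),
    c(x1 - r, yz),
    bez(c(x1 - r, yz), c(x1, yz), c(x1, yz + r)),
    c(x1, yi),
    c(x0, yi)
  )
  data.frame(x = pts[, 1], y = pts[, 2])
}

# every polyline to draw, in template mm coordinates
template_polylines <- function(geom, crowns = TRUE) {
  polys <- list()
  for (i in seq_len(nrow(geom$boxes))) {
    b <- geom$boxes[i, ]
    x0 <- min(b$x_mesial, b$x_distal); x1 <- max(b$x_mesial, b$x_distal)
    polys[[paste0("box_", b$tooth)]] <- data.frame(
      x = c(x0, x1, x1, x0, x0),
      y = c(b$y_zenith, b$y_zenith, b$y_incisal, b$y_incisal, b$y_zenith))
    if (crowns)
      polys[[paste0("crown_", b$tooth)]] <- crown_outline(b)
  }
  for (nm in names(geom$lines))
    polys[[paste0("line_", nm)]] <- geom$lines[[nm]]
  polys
}

svg_points <- function(df) {
  paste(sprintf("%.6f,%.6f", df$x, df$y), collapse = " ")
}

#' Render a template as an SVG document
#'
#' With the identity transform the template frame is exported at 1 mm = 1
#' SVG user unit; with a fitted [fit_transform()] the line work lands in
#' pixel coordinates, optionally over a linked photograph.
#'
#' @param geom an `sct_template`
#' @param transform an `sct_transform`, or `NULL` for the raw mm frame
#' @param style an [overlay_style()]
#' @param image_href optional photograph reference written as an `<image>`
#'   element behind the line work (linked, never embedded)
#' @param width,height canvas size; defaults to the template bounding box
#'   (plus margin) or, when `image_href` is given, must be supplied as the
#'   photo's pixel size
#' @return SVG document as a single character string
#' @export
template_svg <- function(geom, transform = NULL, style = overlay_style(),
                         image_href = NULL, width = NULL, height = NULL) {
  stopifnot(inherits(geom, "sct_template"))
  polys <- template_polylines(geom, crowns = style$crowns)
  if (!is.null(transform))
    polys <- lapply(polys, function(p) apply_transform(transform, p))
  xs <- unlist(lapply(polys, `[[`, "x"))
  ys <- unlist(lapply(polys, `[[`, "y"))
  if (is.null(width)) width <- diff(range(xs)) + 10
  if (is.null(height)) height <- diff(range(ys)) + 10
  view <- if (is.null(transform))
    sprintf("%.6f %.6f %.6f %.6f", min(xs) - 5, min(ys) - 5, width, height)
  else sprintf("0 0 %.6f %.6f", width, height)
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'xmlns:xlink="http://www.w3.org/1999/xlink" ',
                   'width="%.6f" height="%.6f" viewBox="%s">'),
            width, height, view),
    if (!is.null(image_href))
      sprintf('<image xlink:href="%s" x="0" y="0" width="%.6f" height="%.6f"/>',
              image_href, width, height),
    sprintf('<g fill="none" stroke="%s" stroke-width="%.4f" stroke-opacity="%.4f">',
            style$color, style$line_width, style$opacity)
  )
  for (nm in names(polys))
    lines <- c(lines, sprintf('<polyline id="%s" points="%s"/>',
                              nm, svg_points(polys[[nm]])))
  paste(c(lines, "</g>", "</svg>"), collapse = "\n")
}

#' Read a photograph into an RGBA array
#'
#' PNG and TIFF are read natively; JPEG requires the EBImage package.
#'
#' @param path image path (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`)
#' @return numeric array, height x width x 4, values in \[0, 1\]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) sct_abort("image", paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        sct_abort("image", "JPEG input requires the EBImage package")
      aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
    },
    sct_abort("image", paste0("unsupported image format: .", ext))
  )
  to_rgba(img)
}

to_rgba <- function(img) {
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  h <- dim(img)[1]; w <- dim(img)[2]; ch <- dim(img)[3]
  out <- array(1, c(h, w, 4))
  out[, , 1:min(ch, 3)] <- img[, , 1:min(ch, 3)]
  if (ch == 2) { out[, , 2] <- out[, , 3] <- out[, , 1]; out[, , 4] <- img[, , 2] }
  if (ch >= 4) out[, , 4] <- img[, , 4]
  out
}

hex_rgb <- function(color) {
  c(strtoi(substr(color, 2, 3), 16L),
    strtoi(substr(color, 4, 5), 16L),
    strtoi(substr(color, 6, 7), 16L)) / 255
}

# stamp one segment into an RGBA canvas with alpha blending; coordinates in
# continuous pixels, y-down; pixels outside the canvas are clipped
draw_segment <- function(canvas, p0, p1, rgb, alpha, lwd) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / 0.35))
  t <- seq(0, 1, length.out = n)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  r <- max(0L, floor((lwd - 1) / 2))
  off <- expand.grid(ox = -r:r, oy = -r:r)
  # painted pixel set: sampled centres stamped with the square brush
  px <- cbind(rep(round(xs), each = nrow(off)) + rep(off$ox, times = n),
              rep(round(ys), each = nrow(off)) + rep(off$oy, times = n))
  keep <- px[, 1] >= 0 & px[, 1] < w & px[, 2] >= 0 & px[, 2] < h
  px <- unique(px[keep, , drop = FALSE])
  if (!nrow(px)) return(canvas)
  ii <- px[, 2] + 1L; jj <- px[, 1] + 1L
  for (k in 1:3) {
    idx <- cbind(ii, jj, k)
    canvas[idx] <- alpha * rgb[k] + (1 - alpha) * canvas[idx]
  }
  idx <- cbind(ii, jj, 4)
  canvas[idx] <- alpha + (1 - alpha) * canvas[idx]
  canvas
}

#' Render the template overlay
#'
#' Maps the template line work through a similarity transform and writes
#' either an SVG (vector, photograph linked) or a PNG with alpha
#' (photograph composited, or a pure transparent-background template when no
#' image is given). The output format follows the extension of `out`.
#'
#' @param geom an `sct_template`
#' @param transform an `sct_transform` (template mm to image px); see
#'   [fit_transform()] and [default_anchors()]
#' @param image optional photograph: a file path or an RGBA array from
#'   [read_image()]
#' @param out output path, `.png` or `.svg`
#' @param style an [overlay_style()]
#' @param canvas `c(width, height)` in px, used when no image is given
#' @return an `sct_overlay` list (`path`, `transform`, `style`, `width`,
#'   `height`), invisibly
#' @export
render_overlay <- function(geom, transform, image = NULL, out,
                           style = overlay_style(),
                           canvas = c(800, 600)) {
  stopifnot(inherits(geom, "sct_template"), inherits(transform, "sct_transform"))
  img <- NULL
  image_path <- NULL
  if (is.character(image)) {
    image_path <- image
    img <- read_image(image)
  } else if (is.array(image)) {
    img <- to_rgba(image)
  }
  if (!is.null(img)) {
    h <- dim(img)[1]; w <- dim(img)[2]
  } else {
    w <- canvas[1]; h <- canvas[2]
  }
  polys <- template_polylines(geom, crowns = style$crowns)
  polys_px <- lapply(polys, function(p) apply_transform(transform, p))
  xs <- unlist(lapply(polys_px, `[[`, "x"))
  ys <- unlist(lapply(polys_px, `[[`, "y"))
  if (max(xs) < 0 || min(xs) > w || max(ys) < 0 || min(ys) > h)
    warning("transform maps the template entirely outside the canvas; output is clipped")
  ext <- tolower(tools::file_ext(out))
  if (ext == "svg") {
    doc <- template_svg(geom, transform = transform, style = style,
                        image_href = image_path, width = w, height = h)
    writeLines(doc, out)
  } else if (ext == "png") {
    if (is.null(img)) img <- array(0, c(h, w, 4))
    rgb <- hex_rgb(style$color)
    for (p in polys_px) {
      for (i in seq_len(nrow(p) - 1)) {
        img <- draw_segment(img,
                            c(p$x[i], p$y[i]), c(p$x[i + 1], p$y[i + 1]),
                            rgb, style$opacity, style$line_width)
      }
    }
    png::writePNG(img, out)
  } else {
    sct_abort("out", "output must be .png or .svg")
  }
  invisible(structure(
    list(path = out, transform = transform, style = style,
         width = w, height = h),
    class = "sct_overlay"))
}
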