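#' Build the ideal anterior-tooth template
#'
#' Constructs the six tooth boxes (FDI 13-23), the five connector zones and
#' the four dental reference lines (cervical, papillary, contact-point,
#' incisal) from a parameter set.
#'
#' Coordinate convention (normative): a millimetre "template frame" with x
#' increasing to the viewer's right and y increasing downward (raster image
#' convention). The origin sits on the dental midline at the level of the
#' central-incisor incisal edges. The patient's right teeth (11, 12, 13)
#' occupy x < 0, i.e. the viewer's left.
#'
#' Construction rules, with W1 = `central_width`, H1 = W1 / `wh_ratio`,
#' r = `regressive_factor`:
#' * central box: width W1, y from -H1 (zenith) to 0 (incisal edge);
#' * lateral box: width W2 = W1 r, zenith at -H1 + `lateral_zenith_drop`,
#'   incisal edge at -`incisal_step`;
#' * canine box: width W3 = W1 r^2, zenith at -H1, incisal edge (cusp tip
#'   line) at 0, level with the central edges, so the incisal outline forms
#'   a "soup plate";
#' * boxes abut without gaps and mirror exactly across x = 0;
#' * all five papilla tips sit on one horizontal line at
#'   -H1 * `papilla_line_fraction`; each contact point lies f * H1 below its
#'   papilla tip, where f is the pair's connector fraction (50-40-30 rule).
#'
#' @param params an [sct_params()] object
#' @return an object of class `sct_template` with elements `params`, `boxes`
#'   (data frame: tooth, x_mesial, x_distal, y_zenith, y_incisal),
#'   `connectors` (data frame: pair, x, y_papilla_tip, y_contact_point) and
#'   `lines` (named list of x/y polyline data frames: cervical, papillary,
#'   contact, incisal)
#' @examples
#' geom <- build_template(sct_params(central_width = 8))
#' subset(geom$boxes, tooth == "21") # height 10 mm
#' @export
build_template <- function(params = sct_params()) {
  params <- validate_sct_params(params)
  w1 <- params$central_width
  h1 <- w1 / params$wh_ratio
  r <- params$regressive_factor
  w2 <- w1 * r
  w3 <- w2 * r
  drop <- params$lateral_zenith_drop
  step <- params$incisal_step

  # patient-left quadrant (x > 0): 21 centrals, 22 lateral, 23 canine
  left <- data.frame(
    tooth = c("21", "22", "23"),
    x_mesial = c(0, w1, w1 + w2),
    x_distal = c(w1, w1 + w2, w1 + w2 + w3),
    y_zenith = c(-h1, -h1 + drop, -h1),
    y_incisal = c(0, -step, 0),
    stringsAsFactors = FALSE
  )
  right <- left
  right$tooth <- c("11", "12", "13")
  right$x_mesial <- -left$x_mesial
  right$x_distal <- -left$x_distal
  boxes <- rbind(right[3:1, ], left)
  rownames(boxes) <- NULL

  cf <- params$connector_fractions
  y_pap <- -h1 * params$papilla_line_fraction
  connectors <- data.frame(
    pair = c("12-13", "11-12", "11-21", "21-22", "22-23"),
    x = c(-(w1 + w2), -w1, 0, w1, w1 + w2),
    y_papilla_tip = rep(y_pap, 5),
    y_contact_point = y_pap + c(cf[3], cf[2], cf[1], cf[2], cf[3]) * h1,
    stringsAsFactors = FALSE
  )

  mid <- function(b) (b$x_mesial + b$x_distal) / 2
  ord <- boxes[order(mid(boxes)), ]
  lines <- list(
    cervical = data.frame(x = mid(ord), y = ord$y_zenith),
    papillary = data.frame(x = connectors$x, y = connectors$y_papilla_tip),
    contact = data.frame(x = connectors$x, y = connectors$y_contact_point),
    incisal = incisal_outline_polyline(ord)
  )

  structure(
    list(params = params, boxes = boxes, connectors = connectors,
         lines = lines),
    class = "sct_template"
  )
}

# step outline through every incisal corner, in x order
incisal_outline_polyline <- function(ord) {
  xs <- ys <- numeric(0)
  for (i in seq_len(nrow(ord))) {
    xa <- min(ord$x_mesial[i], ord$x_distal[i])
    xb <- max(ord$x_mesial[i], ord$x_distal[i])
    xs <- c(xs, xa, xb)
    ys <- c(ys, ord$y_incisal[i], ord$y_incisal[i])
  }
  keep <- c(TRUE, !(diff(xs) == 0 & diff(ys) == 0))
  data.frame(x = xs[keep], y = ys[keep])
}

#' @export
print.sct_template <- function(x, ...) {
  w1 <- x$params$central_width
  h1 <- w1 / x$params$wh_ratio
  cat("Anterior-tooth template (sct_template)\n")
  cat(sprintf("  central incisor: %.2f x %.2f mm (W/H %.0f%%)\n",
              w1, h1, 100 * x$params$wh_ratio))
  cat(sprintf("  total width    : %.3f mm across six teeth\n",
              max(x$boxes$x_distal) - min(x$boxes$x_distal)))
  cat(sprintf("  connectors     : %s%% of central height\n",
              paste(round(100 * x$params$connector_fractions), collapse = "-")))
  invisible(x)
}

#' Export a template as a self-describing JSON document
#'
#' Writes the parameter set and every constructed coordinate (boxes,
#' connectors, reference lines) in millimetres.
#'
#' @param geom an `sct_template`
#' @param path output file path (`.json`)
#' @return `path`, invisibly
#' @export
write_template <- function(geom, path) {
  stopifnot(inherits(geom, "sct_template"))
  doc <- list(
    format = "smilecurves-template",
    version = 1L,
    units = "mm",
    params = unclass(geom$params),
    boxes = geom$boxes,
    connectors = geom$connectors,
    lines = geom$lines
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Landmark set of a perfect template
#'
#' Exports the template's own landmark positions as a [sct_landmarks()]
#' object in the millimetre template frame: per tooth the mesial and distal
#' incisal corners, the incisal midpoint and the gingival zenith (placed on
#' the box midline), plus the five papilla tips and five contact points.
#' Running the metric suite on this set reproduces every ideal value and
#' classification, which is the backbone of the package's self-consistency
#' tests.
#'
#' @param geom an `sct_template`
#' @return an `sct_landmarks` object, frame `"template"`, units `"mm"`
#' @export
ideal_landmarks <- function(geom) {
  stopifnot(inherits(geom, "sct_template"))
  b <- geom$boxes
  nm <- x <- y <- character(0)
  px <- py <- numeric(0)
  for (i in seq_len(nrow(b))) {
    t <- b$tooth[i]
    xm <- (b$x_mesial[i] + b$x_distal[i]) / 2
    px <- c(px, xm, xm, b$x_mesial[i], b$x_distal[i])
    py <- c(py, b$y_zenith[i], b$y_incisal[i], b$y_incisal[i], b$y_incisal[i])
    nm <- c(nm, paste0(t, c("_zenith", "_incisal_mid",
                            "_mesial_incisal", "_distal_incisal")))
  }
  cn <- gsub("-", "_", geom$connectors$pair)
  nm <- c(nm, paste0("cp_", cn), paste0("pap_", cn))
  px <- c(px, geom$connectors$x, geom$connectors$x)
  py <- c(py, geom$connectors$y_contact_point, geom$connectors$y_papilla_tip)
  sct_landmarks(
    points = data.frame(name = nm, x = px, y = py, stringsAsFactors = FALSE),
    frame = "template", units = "mm"
  )
}
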