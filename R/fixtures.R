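# Synthetic smile generator: ideal and deliberately deformed landmark sets
# so every metric and the full pipeline are testable without a photograph.

# evaluate code under a seed without disturbing global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# leading quadratic coefficient of the ideal incisal curve through the four
# incisor midpoints (mm^-1, negative: opens toward the gingiva in y-down)
ideal_incisal_curvature <- function(params = sct_params()) {
  w1 <- params$central_width
  w2 <- w1 * params$regressive_factor
  u1 <- (w1 / 2)^2
  u2 <- (w1 + w2 / 2)^2
  -params$incisal_step / (u2 - u1)
}

lip_polyline <- function(a, y0, half_span = 18, n = 13) {
  x <- seq(-half_span, half_span, length.out = n)
  data.frame(x = x, y = y0 + a * x^2)
}

#' Generate a synthetic smile landmark set
#'
#' Starts from the ideal template's own landmarks ([ideal_landmarks()] of
#' `build_template(params)`), adds lip polylines, applies the preset's
#' documented deterministic deformation, then adds i.i.d. isotropic Gaussian
#' noise to every point and lip vertex. The same (preset, noise_sd, seed)
#' always yields the same coordinates; the seed is an explicit argument and
#' global RNG state is left untouched.
#'
#' Presets (all magnitudes in mm, template frame):
#' * `ideal` — the unperturbed template with consonant lips: the lower lip
#'   follows the incisal quadratic 2 mm below the edges, the upper lip
#'   rests 1 mm down the central crowns (medium lip line).
#' * `gummy` — upper lip raised to `lift` mm above the gingival zeniths
#'   (default 3): a high lip line with `lift` mm of gingival display.
#' * `deep_bite` — central incisal edges extended `extend` mm (default 1.5),
#'   the over-erupted centrals of a deep overbite.
#' * `reverse_arc` — incisal curvature inverted (centrals 0.8 mm shorter
#'   than the laterals): a reverse smile arc and inverted soup plate.
#' * `asymmetric` — every landmark of tooth 22 shifted `shift` mm to the
#'   viewer's right (default 0.5).
#' * `flat_plate` — lateral incisal edges levelled with centrals and
#'   canines: a flat-plate incisal outline and flat arc.
#'
#' @param preset one of `"ideal"`, `"gummy"`, `"deep_bite"`,
#'   `"reverse_arc"`, `"asymmetric"`, `"flat_plate"`
#' @param noise_sd Gaussian noise standard deviation in mm, >= 0
#' @param seed integer RNG seed for the noise
#' @param params template parameters defining the ideal
#' @param lift,extend,shift preset deformation magnitudes (mm)
#' @return an `sct_landmarks` in the template frame
#' @examples
#' make_smile("gummy", noise_sd = 0, seed = 1)
#' @export
make_smile <- function(preset = c("ideal", "gummy", "deep_bite",
                                  "reverse_arc", "asymmetric", "flat_plate"),
                       noise_sd = 0, seed = 1, params = sct_params(),
                       lift = 3, extend = 1.5, shift = 0.5) {
  if (is.character(preset) && length(preset) == 1 &&
      !preset %in% eval(formals(make_smile)$preset))
    sct_abort("preset", paste0("unknown preset: ", preset))
  preset <- match.arg(preset)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    sct_abort("noise_sd", "must be >= 0")
  geom <- build_template(params)
  ls <- ideal_landmarks(geom)
  h1 <- params$central_width / params$wh_ratio
  a <- ideal_incisal_curvature(params)
  half_span <- max(geom$boxes$x_distal) + 1

  # consonant lips by construction: lower lip parallel to the incisal curve
  ls$lower_lip <- lip_polyline(a, y0 = 2, half_span = half_span)
  ls$upper_lip <- lip_polyline(-0.003, y0 = -h1 + 1, half_span = half_span)

  pts <- ls$points
  set_y <- function(names, value) pts$y[pts$name %in% names] <<- value
  shift_y <- function(names, dy) {
    i <- pts$name %in% names
    pts$y[i] <<- pts$y[i] + dy
  }
  incisal_names <- function(teeth)
    as.vector(outer(teeth, c("_incisal_mid", "_mesial_incisal",
                             "_distal_incisal"), paste0))
  if (preset == "gummy") {
    ls$upper_lip$y <- ls$upper_lip$y + (-h1 - lift) - (-h1 + 1)
  } else if (preset == "deep_bite") {
    shift_y(incisal_names(c("11", "21")), extend)
  } else if (preset == "reverse_arc") {
    set_y(incisal_names(c("11", "21")), -params$incisal_step)
    set_y(incisal_names(c("12", "22")), 0)
  } else if (preset == "asymmetric") {
    i <- startsWith(pts$name, "22")
    pts$x[i] <- pts$x[i] + shift
  } else if (preset == "flat_plate") {
    set_y(incisal_names(c("12", "22")), 0)
  }
  ls$points <- pts

  if (noise_sd > 0) {
    ls <- with_seed(seed, {
      jitter_df <- function(df) {
        df$x <- df$x + stats::rnorm(nrow(df), 0, noise_sd)
        df$y <- df$y + stats::rnorm(nrow(df), 0, noise_sd)
        df
      }
      ls$points <- jitter_df(ls$points)
      ls$upper_lip <- jitter_df(ls$upper_lip)
      ls$lower_lip <- jitter_df(ls$lower_lip)
      ls
    })
  }
  validate_landmarks(ls)
}

#' Render a toy raster image for a synthetic smile
#'
#' Draws the default template, registered at a fixed pixel scale, onto a
#' blank canvas — a stand-in photograph for pipeline tests (clearly
#' synthetic; no photorealism intended).
#'
#' @param path output PNG path
#' @param params template parameters
#' @param px_per_mm raster scale
#' @param canvas `c(width, height)` px
#' @return the fitted `sct_transform`, invisibly
#' @export
make_toy_image <- function(path, params = sct_params(), px_per_mm = 20,
                           canvas = c(900, 500)) {
  geom <- build_template(params)
  src <- default_anchors(geom)
  cx <- canvas[1] / 2; cy <- canvas[2] * 0.7
  dst <- rbind(c(cx + px_per_mm * src[1, 1], cy),
               c(cx + px_per_mm * src[2, 1], cy))
  tr <- fit_transform(src, dst)
  img <- array(1, c(canvas[2], canvas[1], 4))
  render_overlay(geom, tr, image = img, out = path,
                 style = overlay_style(opacity = 1, color = "#333333"))
  invisible(tr)
}
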