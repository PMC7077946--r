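#' Validation error constructor
#'
#' All user-input validation failures signal a condition of class
#' `sct_validation_error` whose message names the offending field, so callers
#' (including the command-line interface) can distinguish bad input from
#' internal errors.
#'
#' @param field name of the offending field
#' @param msg human-readable description
#' @noRd
sct_abort <- function(field, msg) {
  stop(structure(
    list(message = sprintf("invalid `%s`: %s", field, msg),
         call = sys.call(-1)),
    class = c("sct_validation_error", "error", "condition")
  ))
}

#' Template parameters
#'
#' The scalar inputs and proportion constants that fully determine one
#' instance of the anterior-tooth template. Defaults encode the ideal values
#' used in aesthetic smile analysis: a central incisor of width 8.0 mm with a
#' width/height ratio of 80% (so height 10.0 mm), adjacent apparent widths
#' scaled by the diagonal-of-a-square proportion 1/sqrt(2) (the 1:1.414
#' regressive proportion, ~71% per step), lateral-incisor gingival zeniths
#' 0.6 mm below the central/canine zenith line, a 0.8 mm incisal step between
#' central and lateral edges, and connector-space heights of 50/40/30% of the
#' central crown height (the 50-40-30 rule).
#'
#' @param central_width central incisor width in mm (> 0)
#' @param wh_ratio width/height ratio of the central incisor, in (0, 1]
#' @param regressive_factor adjacent-width ratio, in (0, 1)
#' @param lateral_zenith_drop mm the lateral zenith sits below the
#'   central/canine zenith line (>= 0)
#' @param incisal_step mm the lateral incisal edge sits above (gingival to)
#'   the central incisal edge (>= 0)
#' @param connector_fractions three strictly decreasing fractions in (0, 1):
#'   connector height / central crown height for the central-central,
#'   central-lateral and lateral-canine pairs
#' @param papilla_line_fraction depth of the papillary line below the central
#'   zenith as a fraction of central crown height, in (0, 1); must be at
#'   least `connector_fractions[1]` so no contact point falls beyond the
#'   incisal edge
#' @return an object of class `sct_params`
#' @examples
#' p <- sct_params()
#' p$central_width / p$wh_ratio # central crown height, 10 mm
#' @export
sct_params <- function(central_width = 8.0,
                       wh_ratio = 0.80,
                       regressive_factor = 1 / sqrt(2),
                       lateral_zenith_drop = 0.6,
                       incisal_step = 0.8,
                       connector_fractions = c(0.50, 0.40, 0.30),
                       papilla_line_fraction = 0.70) {
  p <- structure(
    list(
      central_width = as.numeric(central_width),
      wh_ratio = as.numeric(wh_ratio),
      regressive_factor = as.numeric(regressive_factor),
      lateral_zenith_drop = as.numeric(lateral_zenith_drop),
      incisal_step = as.numeric(incisal_step),
      connector_fractions = as.numeric(connector_fractions),
      papilla_line_fraction = as.numeric(papilla_line_fraction)
    ),
    class = "sct_params"
  )
  validate_sct_params(p)
}

#' Validate template parameters
#'
#' @param p an `sct_params` object (or bare list with the same fields)
#' @return `p`, invisibly classed, if valid; otherwise signals an
#'   `sct_validation_error` naming the field
#' @export
validate_sct_params <- function(p) {
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  if (!num1(p$central_width) || p$central_width <= 0)
    sct_abort("central_width", "must be a single finite value > 0 (mm)")
  if (!num1(p$wh_ratio) || p$wh_ratio <= 0 || p$wh_ratio > 1)
    sct_abort("wh_ratio", "must be in (0, 1]")
  if (!num1(p$regressive_factor) || p$regressive_factor <= 0 ||
      p$regressive_factor >= 1)
    sct_abort("regressive_factor", "must be in (0, 1)")
  if (!num1(p$lateral_zenith_drop) || p$lateral_zenith_drop < 0)
    sct_abort("lateral_zenith_drop", "must be >= 0 (mm)")
  if (!num1(p$incisal_step) || p$incisal_step < 0)
    sct_abort("incisal_step", "must be >= 0 (mm)")
  cf <- p$connector_fractions
  if (length(cf) != 3L || !all(is.finite(cf)))
    sct_abort("connector_fractions", "must be three finite values")
  if (any(cf <= 0) || any(cf >= 1) || !all(diff(cf) < 0))
    sct_abort("connector_fractions",
              "must be strictly decreasing and each in (0, 1)")
  if (!num1(p$papilla_line_fraction) || p$papilla_line_fraction <= 0 ||
      p$papilla_line_fraction >= 1)
    sct_abort("papilla_line_fraction", "must be in (0, 1)")
  if (p$papilla_line_fraction < cf[1])
    sct_abort("papilla_line_fraction",
              sprintf("must be >= connector_fractions[1] (%.3g) so the deepest contact point stays gingival to the incisal edge", cf[1]))
  h1 <- p$central_width / p$wh_ratio
  if (h1 - p$lateral_zenith_drop - p$incisal_step <= 0)
    sct_abort("lateral_zenith_drop",
              "lateral crown height (central height - drop - step) must be > 0")
  invisible(structure(p, class = "sct_params"))
}

#' @export
print.sct_params <- function(x, ...) {
  cat("Template parameters (sct_params)\n")
  cat(sprintf("  central incisor width : %.3f mm\n", x$central_width))
  cat(sprintf("  width/height ratio    : %.3f (height %.3f mm)\n",
              x$wh_ratio, x$central_width / x$wh_ratio))
  cat(sprintf("  regressive factor     : %.5f (1:%.3f)\n",
              x$regressive_factor, 1 / x$regressive_factor))
  cat(sprintf("  lateral zenith drop   : %.2f mm\n", x$lateral_zenith_drop))
  cat(sprintf("  incisal step          : %.2f mm\n", x$incisal_step))
  cat(sprintf("  connector fractions   : %s\n",
              paste(format(x$connector_fractions), collapse = " / ")))
  cat(sprintf("  papillary line depth  : %.2f of central height\n",
              x$papilla_line_fraction))
  invisible(x)
}
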