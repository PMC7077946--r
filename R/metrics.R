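# Metric suite: the six horizontal smile lines, dental proportions,
# connector ratios, smile arc, lip line and bilateral symmetry.
#
# Every function accepts a partial landmark set and returns
# list(available = FALSE, note = ...) when its required landmarks are
# missing: sparse annotations degrade the report, they never error.

absent <- function(note) list(available = FALSE, note = note)

#' Apparent mesiodistal tooth widths and regressive ratios
#'
#' Width per tooth is the Euclidean distance between its mesial and distal
#' incisal corner landmarks (a frontal-view projection; no parallax
#' correction is attempted). Per side the lateral/central and canine/lateral
#' ratios are reported; on the ideal template both equal the regressive
#' factor 1/sqrt(2). `dominance_ok` is TRUE when widths strictly decrease
#' from central to canine on both sides.
#'
#' @param ls an `sct_landmarks`
#' @return list with `widths` (data frame tooth/width), `ratios` (per side),
#'   `dominance_ok`, `skipped` (teeth lacking corners), `available`
#' @export
apparent_widths <- function(ls) {
  ls <- canonicalize_landmarks(ls)
  w <- setNames(rep(NA_real_, 6), TEETH)
  for (t in TEETH) {
    m <- lm_point(ls, paste0(t, "_mesial_incisal"))
    d <- lm_point(ls, paste0(t, "_distal_incisal"))
    if (!is.null(m) && !is.null(d)) w[t] <- sqrt(sum((m - d)^2))
  }
  if (all(is.na(w))) return(absent("no incisal corner pairs annotated"))
  ratio <- function(a, b) if (is.na(w[a]) || is.na(w[b])) NA_real_ else
    unname(w[a] / w[b])
  ratios <- list(
    right = c(lateral_central = ratio("12", "11"),
              canine_lateral = ratio("13", "12")),
    left = c(lateral_central = ratio("22", "21"),
             canine_lateral = ratio("23", "22"))
  )
  dom_side <- function(ts) {
    ws <- w[ts]
    if (any(is.na(ws))) NA else all(diff(ws) < 0)
  }
  dom <- c(dom_side(c("11", "12", "13")), dom_side(c("21", "22", "23")))
  list(
    widths = data.frame(tooth = TEETH, width = unname(w)),
    ratios = ratios,
    dominance_ok = if (any(is.na(dom))) NA else all(dom),
    skipped = TEETH[is.na(w)],
    available = TRUE
  )
}

#' Cervical (gingival) line analysis
#'
#' Per side, the offset d = y(lateral zenith) - midpoint of y(central
#' zenith) and y(canine zenith); in the upright y-down frame positive d
#' means the lateral zenith sits more incisally. The line is classified
#' convex when d exceeds the tolerance on both sides (the ideal: canine and
#' central zeniths level, lateral a little below), concave when d is below
#' minus the tolerance on both, flat otherwise.
#'
#' @param ls an `sct_landmarks`
#' @param tol classification tolerance in mm for a 10 mm central crown
#'   (rescaled by the measured crown height); default 0.2
#' @return list with per-side `offsets`, `class`, `available`
#' @export
cervical_line_analysis <- function(ls, tol = 0.2) {
  ls <- canonicalize_landmarks(ls)
  off <- c(right = NA_real_, left = NA_real_)
  for (side in names(off)) {
    ts <- if (side == "right") c("11", "12", "13") else c("21", "22", "23")
    z <- lapply(paste0(ts, "_zenith"), lm_point, ls = ls)
    if (any(vapply(z, is.null, TRUE))) next
    off[side] <- z[[2]][2] - (z[[1]][2] + z[[3]][2]) / 2
  }
  if (all(is.na(off)))
    return(absent("zeniths missing on both sides"))
  tl <- tol_length(ls, tol)
  ok <- off[!is.na(off)]
  cls <- if (all(ok > tl)) "convex" else if (all(ok < -tl)) "concave" else "flat"
  list(offsets = off, class = cls, tol = tl,
       flagged_sides = names(off)[is.na(off)], available = TRUE)
}

#' Incisal outline classification
#'
#' s = mean over sides of y(central incisal midpoint) - y(lateral incisal
#' midpoint); positive s means the central edges extend further incisally.
#' Classified `soup_plate` when s exceeds the tolerance (the ideal young
#' smile), `inverted_soup_plate` below minus the tolerance, `flat_plate`
#' otherwise.
#'
#' @param ls an `sct_landmarks`
#' @param tol tolerance in mm for a 10 mm central crown; default 0.2
#' @return list with `s`, per-side `offsets`, `class`, `available`
#' @export
incisal_outline <- function(ls, tol = 0.2) {
  ls <- canonicalize_landmarks(ls)
  off <- c(right = NA_real_, left = NA_real_)
  for (side in names(off)) {
    ts <- if (side == "right") c("11", "12") else c("21", "22")
    ce <- lm_point(ls, paste0(ts[1], "_incisal_mid"))
    la <- lm_point(ls, paste0(ts[2], "_incisal_mid"))
    if (!is.null(ce) && !is.null(la)) off[side] <- ce[2] - la[2]
  }
  if (all(is.na(off)))
    return(absent("incisal midpoints missing"))
  s <- mean(off, na.rm = TRUE)
  tl <- tol_length(ls, tol)
  cls <- if (s > tl) "soup_plate" else if (s < -tl) "inverted_soup_plate"
  else "flat_plate"
  list(s = s, offsets = off, class = cls, tol = tl, available = TRUE)
}

#' Connector-space ratios (the 50-40-30 rule)
#'
#' Each connector height is the vertical span from papilla tip to contact
#' point, expressed as a percentage of the mean central-incisor crown
#' height. Central-lateral and lateral-canine connectors are averaged over
#' the sides where both landmarks exist. On the ideal template the three
#' percentages are exactly 50, 40, 30.
#'
#' @param ls an `sct_landmarks`
#' @return list with `ratios` (central_central, central_lateral,
#'   lateral_canine, percent), `per_pair` data frame, `flagged` pairs with
#'   non-positive height (annotation errors), `available`
#' @export
connector_ratios <- function(ls) {
  ls <- canonicalize_landmarks(ls)
  hc <- central_height(ls)
  if (!is.finite(hc) || hc <= 0)
    return(absent("central incisor height unavailable as reference"))
  per <- data.frame(pair = CONNECTOR_PAIRS, height = NA_real_,
                    ratio_pct = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(CONNECTOR_PAIRS)) {
    cp <- lm_point(ls, paste0("cp_", CONNECTOR_PAIRS[i]))
    pp <- lm_point(ls, paste0("pap_", CONNECTOR_PAIRS[i]))
    if (!is.null(cp) && !is.null(pp)) {
      per$height[i] <- cp[2] - pp[2]
      per$ratio_pct[i] <- 100 * per$height[i] / hc
    }
  }
  if (all(is.na(per$ratio_pct)))
    return(absent("no papilla tip / contact point pairs annotated"))
  agg <- function(pairs) {
    v <- per$ratio_pct[per$pair %in% pairs]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  list(
    ratios = c(central_central = agg("11_21"),
               central_lateral = agg(c("11_12", "21_22")),
               lateral_canine = agg(c("12_13", "22_23"))),
    per_pair = per,
    flagged = per$pair[!is.na(per$height) & per$height <= 0],
    available = TRUE
  )
}

quad_fit <- function(x, y) {
  if (length(unique(round(x, 12))) < 3) return(NULL)
  X <- cbind(1, x, x^2)
  fit <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit))) return(NULL)
  c(c = fit[1], b = fit[2], a = fit[3])
}

#' Smile-arc classification
#'
#' Fits a quadratic y = ax^2 + bx + c (x centred on the midline) to the
#' incisal midpoints of the four incisors and, separately, to the lower-lip
#' polyline vertices. In the upright y-down frame a consonant smile has both
#' curves opening toward the gingiva (a < 0). Classes: `flat` when the
#' incisal curvature magnitude is below `curvature_tol`; `reverse` when the
#' incisal and lip leading coefficients have opposite signs; `consonant`
#' when they share sign and their ratio rho = a_incisal / a_lip lies in
#' `rho_range`; otherwise `flat` (curved but far from parallel). The canine
#' tips are excluded from the fit: with the soup-plate ideal they sit level
#' with the central edges and would flatten the parabola.
#'
#' @param ls an `sct_landmarks`
#' @param curvature_tol flatness threshold on |a_incisal|, 1/mm for a 10 mm
#'   central crown (rescaled with the crown height); default 0.002
#' @param rho_range consonance band for a_incisal / a_lip; default c(0.5, 2)
#' @return list with `class`, `a_incisal`, `a_lip`, `delta_a`, `rho`,
#'   `available`
#' @export
smile_arc <- function(ls, curvature_tol = 0.002, rho_range = c(0.5, 2)) {
  ls <- canonicalize_landmarks(ls)
  if (is.null(ls$lower_lip)) return(absent("lower lip polyline missing"))
  inc <- lapply(paste0(c("11", "21", "12", "22"), "_incisal_mid"),
                lm_point, ls = ls)
  inc <- do.call(rbind, inc[!vapply(inc, is.null, TRUE)])
  if (is.null(inc) || nrow(inc) < 3)
    return(absent("fewer than 3 incisal edge points"))
  f_inc <- quad_fit(inc[, 1], inc[, 2])
  f_lip <- quad_fit(ls$lower_lip$x, ls$lower_lip$y)
  if (is.null(f_inc) || is.null(f_lip))
    return(list(class = "undetermined", available = TRUE,
                note = "degenerate quadratic fit (collinear x)"))
  a_i <- unname(f_inc["a"]); a_l <- unname(f_lip["a"])
  tolc <- tol_curvature(ls, curvature_tol)
  eps <- 1e-12
  rho <- if (abs(a_l) > eps) a_i / a_l else NA_real_
  cls <- if (abs(a_i) < tolc) "flat"
  else if (a_i * a_l < 0) "reverse"
  else if (is.finite(rho) && rho >= rho_range[1] && rho <= rho_range[2])
    "consonant"
  else "flat"
  list(class = cls, a_incisal = a_i, a_lip = a_l, delta_a = a_i - a_l,
       rho = rho, tol = tolc, available = TRUE)
}

#' Upper lip line classification
#'
#' The crown-coverage fraction c = (y_lip - y_zenith) / (y_incisal -
#' y_zenith), evaluated at the dental midline, measures how far the lower
#' border of the upper lip sits down the central crown. Classes: `high` when
#' the lip rides above the zeniths (c < 0, gingiva on display; the display
#' height zenith - lip is reported), `low` when more than `low_threshold` of
#' the crown is covered (c > threshold), `medium` otherwise. Boundary cases
#' go to `medium`.
#'
#' @param ls an `sct_landmarks`
#' @param low_threshold covered-crown fraction above which the lip line is
#'   low; default 0.25
#' @return list with `class`, `coverage`, `gingival_display` (input units;
#'   0 unless class is high), `available`
#' @export
lip_line <- function(ls, low_threshold = 0.25) {
  ls <- canonicalize_landmarks(ls)
  if (is.null(ls$upper_lip)) return(absent("upper lip polyline missing"))
  zen <- lapply(paste0(c("11", "21"), "_zenith"), lm_point, ls = ls)
  mid <- lapply(paste0(c("11", "21"), "_incisal_mid"), lm_point, ls = ls)
  if (any(vapply(c(zen, mid), is.null, TRUE)))
    return(absent("central zeniths / incisal midpoints missing"))
  y_zen <- mean(vapply(zen, `[`, 0, 2))
  y_inc <- mean(vapply(mid, `[`, 0, 2))
  x_span <- range(vapply(zen, `[`, 0, 1))
  lip <- ls$upper_lip
  if (min(lip$x) > x_span[1] || max(lip$x) < x_span[2])
    return(absent("upper lip polyline does not span the central incisors"))
  y_lip <- stats::approx(lip$x, lip$y, xout = 0, ties = mean)$y
  cov <- (y_lip - y_zen) / (y_inc - y_zen)
  cls <- if (cov < 0) "high" else if (cov > low_threshold) "low" else "medium"
  list(class = cls, coverage = cov,
       gingival_display = max(0, y_zen - y_lip),
       available = TRUE)
}

#' Parallelism of the papillary and contact-point lines
#'
#' Angle in degrees between the least-squares lines fitted through the
#' papilla tips and through the contact points. On the ideal template both
#' fitted lines are horizontal (angle 0), even though per side the contact
#' line slopes under the 50-40-30 rule.
#'
#' @param ls an `sct_landmarks`
#' @return list with `angle_deg`, per-line slopes, `available`
#' @export
papillary_contact_parallelism <- function(ls) {
  ls <- canonicalize_landmarks(ls)
  slope <- function(prefix) {
    p <- lapply(paste0(prefix, CONNECTOR_PAIRS), lm_point, ls = ls)
    p <- do.call(rbind, p[!vapply(p, is.null, TRUE)])
    if (is.null(p) || nrow(p) < 2 || length(unique(p[, 1])) < 2)
      return(NA_real_)
    stats::cov(p[, 1], p[, 2]) / stats::var(p[, 1])
  }
  s_pap <- slope("pap_"); s_cp <- slope("cp_")
  if (!is.finite(s_pap) || !is.finite(s_cp))
    return(absent("need at least two papilla tips and two contact points"))
  list(angle_deg = abs(atan(s_cp) - atan(s_pap)) * 180 / pi,
       slope_papillary = s_pap, slope_contact = s_cp, available = TRUE)
}

#' Bilateral symmetry score
#'
#' The midline is the vertical through the midline contact point `cp_11_21`
#' (fallback: mean midpoint of all bilateral pairs). Each patient-left
#' landmark is compared with the mirror image of its patient-right partner
#' across that line; the score is the mean Euclidean discrepancy, in input
#' units (0 for a perfectly symmetric smile).
#'
#' @param ls an `sct_landmarks`
#' @return list with `score`, `n_pairs`, `per_landmark` table, `available`
#' @export
symmetry_score <- function(ls) {
  ls <- canonicalize_landmarks(ls)
  pts <- ls$points
  pr <- if (nrow(pts)) paired_indices(pts) else NULL
  if (is.null(pr) || nrow(pr) < 2)
    return(absent("fewer than 2 bilateral landmark pairs"))
  x0 <- {
    m <- lm_point(ls, "cp_11_21")
    if (!is.null(m)) m[1] else
      mean((pts$x[pr$left] + pts$x[pr$right]) / 2)
  }
  dx <- pts$x[pr$left] - (2 * x0 - pts$x[pr$right])
  dy <- pts$y[pr$left] - pts$y[pr$right]
  d <- sqrt(dx^2 + dy^2)
  list(score = mean(d), n_pairs = nrow(pr),
       per_landmark = data.frame(right = pr$name_right,
                                 left = mirror_name(pr$name_right),
                                 discrepancy = d),
       available = TRUE)
}

#' Full smile report
#'
#' Runs the complete metric suite on one landmark set and attaches the
#' deviation from the template ideal for every quantity that has one:
#' regressive width ratios and W/H against the parameter set, connector
#' percentages against the 50-40-30 fractions, the lateral zenith drop and
#' the incisal step against their configured offsets. Millimetre quantities
#' (gingival display, symmetry score) are converted only when the set is in
#' the template frame or a pixel scale is supplied; otherwise they stay in
#' pixels.
#'
#' @param ls an `sct_landmarks`
#' @param params the [sct_params()] defining the ideal; defaults
#' @param scale optional mm per pixel, for sets in the pixel frame
#' @param ... tolerance overrides passed to the individual metrics
#'   (`cervical_tol`, `incisal_tol`, `curvature_tol`, `rho_range`,
#'   `low_threshold`)
#' @return an object of class `smile_report`
#' @export
full_report <- function(ls, params = sct_params(), scale = NULL,
                        cervical_tol = 0.2, incisal_tol = 0.2,
                        curvature_tol = 0.002, rho_range = c(0.5, 2),
                        low_threshold = 0.25) {
  validate_landmarks(ls)
  ls <- canonicalize_landmarks(ls)
  mm_per_unit <- if (identical(ls$units, "mm")) 1 else scale
  aw <- apparent_widths(ls)
  cl <- cervical_line_analysis(ls, tol = cervical_tol)
  io <- incisal_outline(ls, tol = incisal_tol)
  cr <- connector_ratios(ls)
  sa <- smile_arc(ls, curvature_tol = curvature_tol, rho_range = rho_range)
  ll <- lip_line(ls, low_threshold = low_threshold)
  pp <- papillary_contact_parallelism(ls)
  sy <- symmetry_score(ls)

  dev <- list()
  if (isTRUE(aw$available)) {
    for (side in c("right", "left")) {
      dev[[paste0("regressive_lateral_central_", side)]] <-
        aw$ratios[[side]]["lateral_central"] - params$regressive_factor
      dev[[paste0("regressive_canine_lateral_", side)]] <-
        aw$ratios[[side]]["canine_lateral"] - params$regressive_factor
    }
  }
  wh <- c(right = NA_real_, left = NA_real_)
  for (side in c(right = "11", left = "21")) {
    m <- lm_point(ls, paste0(side, "_mesial_incisal"))
    d <- lm_point(ls, paste0(side, "_distal_incisal"))
    z <- lm_point(ls, paste0(side, "_zenith"))
    im <- lm_point(ls, paste0(side, "_incisal_mid"))
    if (!is.null(m) && !is.null(d) && !is.null(z) && !is.null(im)) {
      i <- if (side == "11") "right" else "left"
      wh[i] <- sqrt(sum((m - d)^2)) / (im[2] - z[2])
      dev[[paste0("wh_ratio_", i)]] <- wh[i] - params$wh_ratio
    }
  }
  if (isTRUE(cr$available)) {
    nm <- c("central_central", "central_lateral", "lateral_canine")
    for (i in 1:3)
      dev[[paste0("connector_", nm[i])]] <-
        cr$ratios[nm[i]] / 100 - params$connector_fractions[i]
  }
  # mm offsets are compared after normalizing the measured crown height to
  # the height the parameters imply, so a uniformly rescaled annotation of
  # the same smile reports identical deviations
  scale_h <- central_height(ls) / (params$central_width / params$wh_ratio)
  if (!is.finite(scale_h) || scale_h <= 0) scale_h <- 1
  if (isTRUE(cl$available)) {
    for (side in c("right", "left"))
      if (is.finite(cl$offsets[side]))
        dev[[paste0("zenith_drop_", side)]] <-
          cl$offsets[side] / scale_h - params$lateral_zenith_drop
  }
  if (isTRUE(io$available)) {
    dev[["incisal_step"]] <- io$s / scale_h - params$incisal_step
  }
  dev <- lapply(dev, unname)

  to_mm <- function(v) if (!is.null(mm_per_unit)) v * mm_per_unit else NULL
  structure(
    list(
      params = params,
      units = ls$units,
      mm_per_unit = mm_per_unit,
      widths = if (isTRUE(aw$available)) aw$widths else NULL,
      regressive_ratios = if (isTRUE(aw$available)) aw$ratios else NULL,
      dominance_ok = if (isTRUE(aw$available)) aw$dominance_ok else NULL,
      wh_ratio_central = wh,
      cervical_line = cl,
      incisal_outline = io,
      connector_ratios = cr,
      papillary_contact_parallelism = pp,
      smile_arc = sa,
      lip_line = ll,
      gingival_display_mm =
        if (isTRUE(ll$available)) to_mm(ll$gingival_display) else NULL,
      symmetry_score = sy,
      symmetry_score_mm =
        if (isTRUE(sy$available)) to_mm(sy$score) else NULL,
      deviations = dev
    ),
    class = "smile_report"
  )
}

#' @export
print.smile_report <- function(x, ...) {
  cat("Smile report\n")
  cls <- function(m) if (isTRUE(m$available)) m$class else "absent"
  cat(sprintf("  cervical line : %s\n", cls(x$cervical_line)))
  cat(sprintf("  incisal line  : %s\n", cls(x$incisal_outline)))
  cat(sprintf("  smile arc     : %s\n", cls(x$smile_arc)))
  cat(sprintf("  lip line      : %s\n", cls(x$lip_line)))
  if (isTRUE(x$connector_ratios$available))
    cat(sprintf("  connectors    : %s %% of central height\n",
                paste(sprintf("%.1f", x$connector_ratios$ratios),
                      collapse = " / ")))
  if (!is.null(x$dominance_ok))
    cat(sprintf("  dominance     : %s\n",
                if (isTRUE(x$dominance_ok)) "ok" else "violated"))
  if (isTRUE(x$symmetry_score$available))
    cat(sprintf("  symmetry      : %.4g %s mean mirrored discrepancy\n",
                x$symmetry_score$score, x$units))
  if (length(x$deviations)) {
    mx <- max(abs(unlist(x$deviations)), na.rm = TRUE)
    cat(sprintf("  max |deviation from ideal| : %.3g\n", mx))
  }
  invisible(x)
}

#' Flatten a smile report to one row per metric
#'
#' @param report a `smile_report`
#' @return data frame with columns `metric`, `value`, `class`
#' @export
report_table <- function(report) {
  rows <- list()
  add <- function(metric, value = NA_real_, class = NA_character_) {
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, value = as.numeric(value), class = class,
      stringsAsFactors = FALSE)
  }
  if (!is.null(report$widths))
    for (i in seq_len(nrow(report$widths)))
      add(paste0("width_", report$widths$tooth[i]), report$widths$width[i])
  if (!is.null(report$regressive_ratios))
    for (side in c("right", "left"))
      for (nm in names(report$regressive_ratios[[side]]))
        add(paste0(nm, "_", side), report$regressive_ratios[[side]][nm])
  for (side in c("right", "left"))
    add(paste0("wh_ratio_", side), report$wh_ratio_central[side])
  if (isTRUE(report$cervical_line$available)) {
    add("cervical_offset_right", report$cervical_line$offsets["right"],
        report$cervical_line$class)
    add("cervical_offset_left", report$cervical_line$offsets["left"],
        report$cervical_line$class)
  }
  if (isTRUE(report$incisal_outline$available))
    add("incisal_step", report$incisal_outline$s,
        report$incisal_outline$class)
  if (isTRUE(report$connector_ratios$available))
    for (nm in names(report$connector_ratios$ratios))
      add(paste0("connector_", nm), report$connector_ratios$ratios[nm])
  if (isTRUE(report$papillary_contact_parallelism$available))
    add("papillary_contact_angle_deg",
        report$papillary_contact_parallelism$angle_deg)
  if (isTRUE(report$smile_arc$available))
    add("smile_arc_delta_a", report$smile_arc$delta_a,
        report$smile_arc$class)
  if (isTRUE(report$lip_line$available))
    add("lip_coverage", report$lip_line$coverage, report$lip_line$class)
  if (isTRUE(report$symmetry_score$available))
    add("symmetry_score", report$symmetry_score$score)
  if (!is.null(report$dominance_ok))
    add("dominance_ok", as.numeric(report$dominance_ok))
  for (nm in names(report$deviations))
    add(paste0("deviation_", nm), report$deviations[[nm]])
  do.call(rbind, rows)
}

#' Write a smile report to disk
#'
#' JSON (`.json`, full structure) or a flat tab-separated table (`.tsv`,
#' via [report_table()]).
#'
#' @param report a `smile_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = I(17), dataframe = "columns",
                         null = "null", force = TRUE)
  } else {
    utils::write.table(report_table(report), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
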