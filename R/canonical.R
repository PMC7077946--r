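# Bilateral pairing and frame canonicalization.
#
# Every metric is defined in an upright, midline-centred frame (x = 0 on the
# dental midline, y increasing incisally). Landmark sets annotated on tilted
# photographs are first rotated/translated into that frame, which is what
# makes all metrics invariant under global rotation and translation of the
# input.

#' Mirror partner of a landmark name
#'
#' Swaps FDI quadrant 1 and 2 in every tooth token, so `11_zenith` maps to
#' `21_zenith` and `cp_11_12` to `cp_21_22`. Midline names (`cp_11_21`,
#' `pap_11_21`) map to themselves.
#'
#' @param name character vector of landmark names
#' @return character vector of partner names
#' @export
mirror_name <- function(name) {
  swap <- function(tok) chartr("12", "21", substr(tok, 1, 1))
  vapply(name, function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    is_tooth <- grepl("^[12][123]$", parts)
    parts[is_tooth] <- paste0(swap(parts[is_tooth]),
                              substr(parts[is_tooth], 2, 2))
    if (parts[1] %in% c("cp", "pap")) {
      pair <- paste(parts[2], parts[3], sep = "_")
      i <- match(pair, CONNECTOR_PAIRS)
      if (is.na(i)) {
        rev_pair <- paste(parts[3], parts[2], sep = "_")
        i <- match(rev_pair, CONNECTOR_PAIRS)
        if (!is.na(i)) pair <- rev_pair
      }
      return(paste0(parts[1], "_", pair))
    }
    paste(parts, collapse = "_")
  }, "", USE.NAMES = FALSE)
}

#' Side of a landmark
#'
#' @param name character vector of landmark names
#' @return `"right"` (patient's right, FDI quadrant 1), `"left"` (quadrant 2)
#'   or `"mid"` for the midline connector landmarks
#' @export
landmark_side <- function(name) {
  vapply(name, function(nm) {
    if (nm %in% c("cp_11_21", "pap_11_21")) return("mid")
    q <- regmatches(nm, regexpr("[12][123]", nm))
    if (!length(q)) return("mid")
    if (substr(q, 1, 1) == "1") "right" else "left"
  }, "", USE.NAMES = FALSE)
}

# rows of paired (right, left) landmarks present in the set
paired_indices <- function(pts) {
  side <- landmark_side(pts$name)
  r <- which(side == "right")
  partner <- match(mirror_name(pts$name[r]), pts$name)
  keep <- !is.na(partner)
  data.frame(right = r[keep], left = partner[keep],
             name_right = pts$name[r[keep]],
             stringsAsFactors = FALSE)
}

#' Canonicalize a landmark set
#'
#' Rotates and translates a landmark set into the template's upright frame:
#' the axis from the centroid of patient-right landmarks to the centroid of
#' their patient-left partners becomes +x, the midline contact point
#' `cp_11_21` (fallback: mean midpoint of all bilateral pairs) becomes the
#' origin, and the set is spun 180 degrees if the gingival zeniths end up
#' below the incisal edges. A pure rigid motion — no scaling, no reflection —
#' so lengths and ratios are untouched.
#'
#' Idempotent; metric functions apply it on entry.
#'
#' @param ls an `sct_landmarks`
#' @return the canonicalized `sct_landmarks`
#' @export
canonicalize_landmarks <- function(ls) {
  if (isTRUE(attr(ls, "canonical"))) return(ls)
  pts <- ls$points
  pr <- if (nrow(pts)) paired_indices(pts) else
    data.frame(right = integer(0), left = integer(0))
  theta <- 0
  if (nrow(pr) >= 1) {
    v <- c(mean(pts$x[pr$left]) - mean(pts$x[pr$right]),
           mean(pts$y[pr$left]) - mean(pts$y[pr$right]))
    if (sqrt(sum(v^2)) > 0) theta <- atan2(v[2], v[1])
  }
  rot <- function(x, y, th) {
    c_ <- cos(th); s_ <- sin(th)
    list(x = c_ * x + s_ * y, y = -s_ * x + c_ * y)
  }
  apply_rigid <- function(ls, th, origin) {
    tr <- function(df) {
      if (is.null(df)) return(NULL)
      r <- rot(df$x, df$y, th)
      df$x <- r$x - origin[1]; df$y <- r$y - origin[2]
      df
    }
    ls$points <- tr(ls$points)
    ls$upper_lip <- tr(ls$upper_lip)
    ls$lower_lip <- tr(ls$lower_lip)
    ls
  }
  origin <- c(0, 0)
  mid <- lm_point(ls, "cp_11_21")
  if (!is.null(mid)) {
    r <- rot(mid[1], mid[2], theta)
    origin <- c(r$x, r$y)
  } else if (nrow(pr) >= 1) {
    r <- rot((pts$x[pr$left] + pts$x[pr$right]) / 2,
             (pts$y[pr$left] + pts$y[pr$right]) / 2, theta)
    origin <- c(mean(r$x), mean(r$y))
  }
  out <- apply_rigid(ls, theta, origin)
  # upright check: zeniths must be gingival (smaller y) to incisal edges
  zen <- grepl("_zenith$", out$points$name)
  inc <- grepl("_incisal_mid$", out$points$name)
  if (any(zen) && any(inc) &&
      mean(out$points$y[zen]) > mean(out$points$y[inc])) {
    flip <- function(df) {
      if (is.null(df)) return(NULL)
      df$x <- -df$x; df$y <- -df$y; df
    }
    out$points <- flip(out$points)
    out$upper_lip <- flip(out$upper_lip)
    out$lower_lip <- flip(out$lower_lip)
  }
  attr(out, "canonical") <- TRUE
  out
}

# mean clinical crown height of the central incisors, in input units;
# NA when the needed landmarks are missing
central_height <- function(ls) {
  hs <- c()
  for (t in c("11", "21")) {
    z <- lm_point(ls, paste0(t, "_zenith"))
    m <- lm_point(ls, paste0(t, "_incisal_mid"))
    if (!is.null(z) && !is.null(m)) hs <- c(hs, m[2] - z[2])
  }
  if (length(hs)) mean(hs) else NA_real_
}

# Classification tolerances are stated in mm for a 10 mm central crown and
# rescaled by the measured crown height, so class labels are invariant under
# uniform scaling of the landmark set (and work unchanged in pixel frames).
REF_CENTRAL_HEIGHT <- 10

tol_length <- function(ls, tol_mm) {
  h <- central_height(ls)
  if (is.finite(h) && h > 0) tol_mm * h / REF_CENTRAL_HEIGHT else tol_mm
}

tol_curvature <- function(ls, tol_mm_inv) {
  h <- central_height(ls)
  if (is.finite(h) && h > 0) tol_mm_inv * REF_CENTRAL_HEIGHT / h else tol_mm_inv
}
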