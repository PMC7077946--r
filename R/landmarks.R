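TEETH <- c("13", "12", "11", "21", "22", "23")
CONNECTOR_PAIRS <- c("12_13", "11_12", "11_21", "21_22", "22_23")

#' Landmark name dictionary
#'
#' The fixed vocabulary of point landmarks: per tooth (FDI 13, 12, 11, 21,
#' 22, 23) a gingival zenith, incisal midpoint and mesial/distal incisal
#' corners; plus the five interproximal contact points and five papilla tips.
#' 34 names in all. Lip borders are polylines, not named points.
#'
#' FDI two-digit numbering is normative throughout. For users of the
#' Universal system: 13/12/11/21/22/23 correspond to teeth 6/7/8/9/10/11.
#'
#' @return character vector of the 34 valid landmark names
#' @export
landmark_dictionary <- function() {
  c(
    as.vector(t(outer(TEETH, c("_zenith", "_incisal_mid", "_mesial_incisal",
                               "_distal_incisal"), paste0))),
    paste0("cp_", CONNECTOR_PAIRS),
    paste0("pap_", CONNECTOR_PAIRS)
  )
}

#' Landmark set for one photograph
#'
#' Named 2D anatomical points (and optional lip polylines) annotated on a
#' frontal smile or intraoral photograph, or expressed in the millimetre
#' template frame. Pixel coordinates follow the y-down raster convention; a
#' coordinate is the continuous position of the anatomical point and no
#' pixel-centre offset is applied (annotation tools differ on this; be
#' consistent within a study).
#'
#' Partial sets are allowed — metrics that lack their required landmarks are
#' reported as absent, never fabricated. Incisal corners must however come in
#' mesial/distal pairs, since an apparent width needs both.
#'
#' @param points data frame with columns `name`, `x`, `y` (or a named list of
#'   length-2 numeric vectors); names must come from [landmark_dictionary()]
#' @param upper_lip,lower_lip optional polylines (matrix or data frame with
#'   columns x, y, at least 3 vertices): lower border of the upper lip and
#'   upper border of the lower lip
#' @param frame `"pixel"` or `"template"`
#' @param units `"px"` or `"mm"`; must match the frame (pixel/px,
#'   template/mm)
#' @param image_ref optional path or identifier of the photograph
#' @return an object of class `sct_landmarks`
#' @export
sct_landmarks <- function(points = NULL, upper_lip = NULL, lower_lip = NULL,
                          frame = c("pixel", "template"),
                          units = NULL, image_ref = NULL) {
  frame <- match.arg(frame)
  if (is.null(units)) units <- if (frame == "template") "mm" else "px"
  if (is.null(points)) {
    points <- data.frame(name = character(0), x = numeric(0), y = numeric(0),
                         stringsAsFactors = FALSE)
  } else if (is.list(points) && !is.data.frame(points)) {
    points <- data.frame(
      name = names(points),
      x = vapply(points, function(p) as.numeric(p[[1]]), 0),
      y = vapply(points, function(p) as.numeric(p[[2]]), 0),
      stringsAsFactors = FALSE
    )
  }
  as_poly <- function(p) {
    if (is.null(p)) return(NULL)
    p <- as.data.frame(p)
    names(p)[1:2] <- c("x", "y")
    data.frame(x = as.numeric(p$x), y = as.numeric(p$y))
  }
  ls <- structure(
    list(image_ref = image_ref, frame = frame, units = units,
         points = points[, c("name", "x", "y")],
         upper_lip = as_poly(upper_lip), lower_lip = as_poly(lower_lip)),
    class = "sct_landmarks"
  )
  validate_landmarks(ls)
}

#' Validate a landmark set
#'
#' Checks the name dictionary, uniqueness, finiteness, mesial/distal corner
#' pairing, frame/units consistency and polyline lengths. Signals an
#' `sct_validation_error` naming the offending field or landmark.
#'
#' @param ls an `sct_landmarks` object
#' @return `ls` invisibly if valid
#' @export
validate_landmarks <- function(ls) {
  if (!ls$frame %in% c("pixel", "template"))
    sct_abort("frame", "must be \"pixel\" or \"template\"")
  want <- if (ls$frame == "template") "mm" else "px"
  if (!identical(ls$units, want))
    sct_abort("units", sprintf("frame \"%s\" requires units \"%s\", got \"%s\"",
                               ls$frame, want, ls$units))
  pts <- ls$points
  bad <- setdiff(pts$name, landmark_dictionary())
  if (length(bad))
    sct_abort("points", paste0("unknown landmark name(s): ",
                               paste(bad, collapse = ", ")))
  dup <- unique(pts$name[duplicated(pts$name)])
  if (length(dup))
    sct_abort("points", paste0("duplicate landmark name(s): ",
                               paste(dup, collapse = ", ")))
  if (nrow(pts) && !all(is.finite(pts$x) & is.finite(pts$y))) {
    nf <- pts$name[!(is.finite(pts$x) & is.finite(pts$y))]
    sct_abort("points", paste0("non-finite coordinate(s) at: ",
                               paste(nf, collapse = ", ")))
  }
  for (t in TEETH) {
    has <- paste0(t, c("_mesial_incisal", "_distal_incisal")) %in% pts$name
    if (xor(has[1], has[2]))
      sct_abort("points", sprintf(
        "tooth %s has only one incisal corner; mesial and distal must both be present", t))
  }
  for (side in c("upper_lip", "lower_lip")) {
    p <- ls[[side]]
    if (is.null(p)) next
    if (nrow(p) < 3) sct_abort(side, "polyline needs at least 3 vertices")
    if (!all(is.finite(p$x) & is.finite(p$y)))
      sct_abort(side, "non-finite vertex coordinate")
  }
  invisible(ls)
}

#' @export
print.sct_landmarks <- function(x, ...) {
  cat(sprintf("Landmark set (sct_landmarks): %d points, frame %s [%s]\n",
              nrow(x$points), x$frame, x$units))
  if (!is.null(x$image_ref)) cat("  image:", x$image_ref, "\n")
  cat(sprintf("  upper lip: %s   lower lip: %s\n",
              if (is.null(x$upper_lip)) "absent" else
                paste0(nrow(x$upper_lip), " vertices"),
              if (is.null(x$lower_lip)) "absent" else
                paste0(nrow(x$lower_lip), " vertices")))
  invisible(x)
}

#' Look up one landmark
#'
#' @param ls an `sct_landmarks`
#' @param name a landmark name
#' @return numeric `c(x, y)`, or `NULL` if absent
#' @export
lm_point <- function(ls, name) {
  i <- match(name, ls$points$name)
  if (is.na(i)) return(NULL)
  c(x = ls$points$x[i], y = ls$points$y[i])
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a landmark set to disk
#'
#' Two dialects, chosen by extension: a structured JSON document (`.json`)
#' or a tab-separated table (`.tsv`/`.txt`) with a `name  x  y` header and
#' `# key: value` comment lines for frame, units and image reference; lip
#' polylines appear as rows named `upper_lip.1`, `upper_lip.2`, ... in
#' vertex order. Coordinates are written with 17 significant digits so a
#' read-back reproduces the doubles exactly.
#'
#' @param ls an `sct_landmarks`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_landmarks <- function(ls, path) {
  validate_landmarks(ls)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- list(
      format = "smilecurves-landmarks", version = 1L,
      image_ref = ls$image_ref, frame = ls$frame, units = ls$units,
      points = ls$points, upper_lip = ls$upper_lip, lower_lip = ls$lower_lip
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         dataframe = "columns", null = "null")
  } else {
    lines <- c("# smilecurves landmarks v1",
               paste0("# frame: ", ls$frame),
               paste0("# units: ", ls$units))
    if (!is.null(ls$image_ref)) lines <- c(lines, paste0("# image: ", ls$image_ref))
    lines <- c(lines, "name\tx\ty")
    row <- function(n, x, y) paste(n, fmt_num(x), fmt_num(y), sep = "\t")
    if (nrow(ls$points))
      lines <- c(lines, row(ls$points$name, ls$points$x, ls$points$y))
    for (side in c("upper_lip", "lower_lip")) {
      p <- ls[[side]]
      if (!is.null(p))
        lines <- c(lines, row(paste0(side, ".", seq_len(nrow(p))), p$x, p$y))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a landmark set from disk
#'
#' Accepts both dialects written by [write_landmarks()]. Unknown landmark
#' names, duplicates and non-finite coordinates are rejected with an error
#' naming the offender; partial sets are fine.
#'
#' @param path file path (`.json`, `.tsv` or `.txt`)
#' @return a validated `sct_landmarks`
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) sct_abort("path", paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- data.frame(
      name = as.character(unlist(doc$points$name)),
      x = as.numeric(unlist(doc$points$x)),
      y = as.numeric(unlist(doc$points$y)),
      stringsAsFactors = FALSE
    )
    lip <- function(p) if (is.null(p) || !length(unlist(p))) NULL else
      as.data.frame(p)
    return(sct_landmarks(
      points = pts,
      upper_lip = lip(doc$upper_lip), lower_lip = lip(doc$lower_lip),
      frame = doc$frame, units = doc$units,
      image_ref = doc$image_ref
    ))
  }
  raw <- readLines(path)
  meta <- raw[startsWith(raw, "#")]
  body <- raw[!startsWith(raw, "#") & nzchar(raw)]
  get_meta <- function(key, default = NULL) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  if (!length(body) || !identical(strsplit(body[1], "\t")[[1]], c("name", "x", "y")))
    sct_abort("path", "tabular landmark file must have a name\\tx\\ty header")
  tab <- if (length(body) > 1) {
    utils::read.delim(text = body, header = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), x = numeric(0), y = numeric(0))
  }
  is_lip <- grepl("^(upper_lip|lower_lip)\\.[0-9]+$", tab$name)
  lips <- list(upper_lip = NULL, lower_lip = NULL)
  for (side in names(lips)) {
    sel <- tab[grepl(paste0("^", side, "\\."), tab$name) & is_lip, ]
    if (nrow(sel)) {
      ord <- order(as.integer(sub(".*\\.", "", sel$name)))
      lips[[side]] <- data.frame(x = sel$x[ord], y = sel$y[ord])
    }
  }
  sct_landmarks(
    points = tab[!is_lip, c("name", "x", "y")],
    upper_lip = lips$upper_lip, lower_lip = lips$lower_lip,
    frame = get_meta("frame", "pixel"), units = get_meta("units"),
    image_ref = get_meta("image")
  )
}
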