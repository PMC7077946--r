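# shared fixtures, all built in code

default_geom <- function() build_template(sct_params())

ideal_ls <- function() ideal_landmarks(default_geom())

# rigid motion of a landmark set (rotation th, then translation dx, dy)
rigid_move <- function(ls, th, dx, dy) {
  f <- function(df) {
    if (is.null(df)) return(NULL)
    x <- cos(th) * df$x - sin(th) * df$y + dx
    y <- sin(th) * df$x + cos(th) * df$y + dy
    df$x <- x; df$y <- y
    df
  }
  ls$points <- f(ls$points)
  ls$upper_lip <- f(ls$upper_lip)
  ls$lower_lip <- f(ls$lower_lip)
  attr(ls, "canonical") <- NULL
  ls
}

# uniform scaling about the origin
scale_ls <- function(ls, s) {
  f <- function(df) {
    if (is.null(df)) return(NULL)
    df$x <- s * df$x; df$y <- s * df$y
    df
  }
  ls$points <- f(ls$points)
  ls$upper_lip <- f(ls$upper_lip)
  ls$lower_lip <- f(ls$lower_lip)
  attr(ls, "canonical") <- NULL
  ls
}

# reflect across the vertical midline (x -> -x) and relabel so the set is
# a valid annotation of the mirrored smile
reflect_ls <- function(ls) {
  ls$points$x <- -ls$points$x
  ls$points$name <- mirror_name(ls$points$name)
  # mirroring swaps each tooth's mesial/distal corner roles
  nm <- ls$points$name
  mes <- grepl("_mesial_incisal$", nm)
  dis <- grepl("_distal_incisal$", nm)
  nm[mes] <- sub("_mesial_incisal$", "_distal_incisal", nm[mes])
  nm[dis] <- sub("_distal_incisal$", "_mesial_incisal", nm[dis])
  ls$points$name <- nm
  if (!is.null(ls$upper_lip)) ls$upper_lip$x <- -ls$upper_lip$x
  if (!is.null(ls$lower_lip)) ls$lower_lip$x <- -ls$lower_lip$x
  attr(ls, "canonical") <- NULL
  ls
}

# displace one named landmark
nudge <- function(ls, name, dx = 0, dy = 0) {
  i <- match(name, ls$points$name)
  ls$points$x[i] <- ls$points$x[i] + dx
  ls$points$y[i] <- ls$points$y[i] + dy
  attr(ls, "canonical") <- NULL
  ls
}

# random valid landmark set for round-trip property tests
random_ls <- function(seed) {
  set.seed(seed)
  dict <- landmark_dictionary()
  n <- sample(3:34, 1)
  nms <- sample(dict, n)
  # honour the corner-pairing rule
  for (t in c("13", "12", "11", "21", "22", "23")) {
    pairnames <- paste0(t, c("_mesial_incisal", "_distal_incisal"))
    have <- pairnames %in% nms
    if (xor(have[1], have[2])) nms <- c(nms, pairnames[!have])
  }
  pts <- data.frame(name = unique(nms),
                    x = stats::runif(length(unique(nms)), -20, 20),
                    y = stats::runif(length(unique(nms)), -15, 5))
  lip <- function() data.frame(x = sort(stats::runif(5, -18, 18)),
                               y = stats::runif(5, -12, 4))
  sct_landmarks(points = pts,
                upper_lip = if (stats::runif(1) > 0.5) lip() else NULL,
                lower_lip = if (stats::runif(1) > 0.5) lip() else NULL,
                frame = "template", units = "mm")
}
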