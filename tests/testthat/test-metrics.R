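test_that("apparent widths recover the regressive proportion on the ideal set", {
  aw <- apparent_widths(ideal_ls())
  for (side in c("right", "left")) {
    expect_equal(unname(aw$ratios[[side]]["lateral_central"]), 1 / sqrt(2),
                 tolerance = 1e-9)
    expect_equal(unname(aw$ratios[[side]]["canine_lateral"]), 1 / sqrt(2),
                 tolerance = 1e-9)
  }
  expect_true(aw$dominance_ok)
  # arithmetic oracle: widths 8.0 / 5.657 / 4.0
  expect_equal(round(4.0 / 5.657, 4), 0.7071)
})

test_that("equal widths break dominance and give unit ratios", {
  ls <- ideal_ls()
  # widen every tooth to the central width, keeping midlines
  for (t in c("13", "12", "11", "21", "22", "23")) {
    m <- lm_point(ls, paste0(t, "_mesial_incisal"))
    d <- lm_point(ls, paste0(t, "_distal_incisal"))
    mid <- (m + d) / 2
    dir <- sign(d[1] - m[1])
    ls <- nudge(ls, paste0(t, "_mesial_incisal"),
                dx = (mid[1] - 4 * dir) - m[1])
    ls <- nudge(ls, paste0(t, "_distal_incisal"),
                dx = (mid[1] + 4 * dir) - d[1])
  }
  aw <- apparent_widths(ls)
  expect_equal(unname(aw$ratios$left["lateral_central"]), 1)
  expect_false(aw$dominance_ok)
})

test_that("cervical line classification follows the zenith offsets", {
  cl <- cervical_line_analysis(ideal_ls())
  expect_equal(unname(cl$offsets), c(0.6, 0.6))
  expect_identical(cl$class, "convex")
  # all zeniths level -> flat
  ls <- ideal_ls()
  ls$points$y[grepl("_zenith$", ls$points$name)] <- -10
  expect_identical(cervical_line_analysis(ls)$class, "flat")
  # laterals 1 mm gingival to the central/canine line -> concave
  ls2 <- ideal_ls()
  ls2 <- nudge(ls2, "12_zenith", dy = -1.6)
  ls2 <- nudge(ls2, "22_zenith", dy = -1.6)
  cl2 <- cervical_line_analysis(ls2)
  expect_equal(unname(cl2$offsets), c(-1, -1))
  expect_identical(cl2$class, "concave")
})

test_that("incisal outline trichotomy matches the edge offsets", {
  io <- incisal_outline(ideal_ls())
  expect_equal(io$s, 0.8)
  expect_identical(io$class, "soup_plate")
  ls <- ideal_ls()
  inc <- grepl("_incisal", ls$points$name)
  ls$points$y[inc] <- 0
  expect_identical(incisal_outline(ls)$class, "flat_plate")
  ls2 <- ideal_ls()
  for (t in c("11", "21"))
    for (sfx in c("_incisal_mid", "_mesial_incisal", "_distal_incisal"))
      ls2 <- nudge(ls2, paste0(t, sfx), dy = -1.8) # centrals 1 mm shorter
  expect_identical(incisal_outline(ls2)$class, "inverted_soup_plate")
})

test_that("connector ratios reproduce the 50-40-30 rule", {
  cr <- connector_ratios(ideal_ls())
  expect_equal(unname(cr$ratios), c(50, 40, 30), tolerance = 1e-12)
  expect_length(cr$flagged, 0)
  # arithmetic oracle: heights 5/4/3 over a 10 mm crown
  expect_equal(100 * c(5, 4, 3) / 10, c(50, 40, 30))
  # papilla tip meeting the contact point is flagged
  ls <- ideal_ls()
  i <- ls$points$name == "pap_11_21"
  ls$points$y[i] <- lm_point(ls, "cp_11_21")[2]
  cr2 <- connector_ratios(ls)
  expect_equal(unname(cr2$ratios["central_central"]), 0)
  expect_identical(cr2$flagged, "11_21")
})

test_that("smile arc separates consonant, flat and reverse", {
  expect_identical(smile_arc(make_smile("ideal"))$class, "consonant")
  # collinear horizontal incisal points -> flat
  ls <- make_smile("flat_plate")
  sa <- smile_arc(ls)
  expect_identical(sa$class, "flat")
  expect_lt(abs(sa$a_incisal), sa$tol)
  # inverted incisal curvature against the same lip -> reverse
  sr <- smile_arc(make_smile("reverse_arc"))
  expect_identical(sr$class, "reverse")
  expect_true(sr$a_incisal * sr$a_lip < 0)
})

test_that("lip line classes follow the coverage rule with medium boundaries", {
  base <- make_smile("ideal")
  set_lip <- function(ls, y0) {
    ls$upper_lip <- data.frame(x = seq(-18, 18, length.out = 7),
                               y = rep(y0, 7))
    attr(ls, "canonical") <- NULL
    ls
  }
  hi <- lip_line(set_lip(base, -12)) # 2 mm above the zeniths
  expect_identical(hi$class, "high")
  expect_equal(hi$gingival_display, 2)
  expect_identical(lip_line(set_lip(base, -10))$class, "medium") # boundary
  expect_identical(lip_line(set_lip(base, -7))$class, "low") # 30% covered
  expect_identical(lip_line(set_lip(base, -9))$class, "medium")
})

test_that("symmetry score is zero on the ideal set and localizes a nudge", {
  sy <- symmetry_score(ideal_ls())
  expect_equal(sy$score, 0)
  ls <- nudge(ideal_ls(), "22_zenith", dx = 1)
  sy2 <- symmetry_score(ls)
  expect_equal(sy2$score, 1 / sy2$n_pairs)
  tab <- sy2$per_landmark
  expect_equal(tab$discrepancy[tab$left == "22_zenith"], 1)
  # one-sided sets have no pairs: absent, not an error
  one_side <- ideal_ls()
  keep <- landmark_side(one_side$points$name) == "left"
  one_side$points <- one_side$points[keep, ]
  expect_false(symmetry_score(one_side)$available)
})

test_that("papillary and contact fitted lines are parallel on the ideal set", {
  pp <- papillary_contact_parallelism(ideal_ls())
  expect_equal(pp$angle_deg, 0, tolerance = 1e-9)
})

test_that("full report on the ideal template has zero deviations everywhere", {
  r <- full_report(ideal_ls())
  expect_lt(max(abs(unlist(r$deviations))), 1e-9)
  expect_identical(r$cervical_line$class, "convex")
  expect_identical(r$incisal_outline$class, "soup_plate")
  expect_true(r$dominance_ok)
})

test_that("metric constants recover non-default template parameters exactly", {
  p <- sct_params(central_width = 9, wh_ratio = 0.75,
                  regressive_factor = 0.72, lateral_zenith_drop = 0.9,
                  incisal_step = 0.5,
                  connector_fractions = c(0.45, 0.35, 0.25),
                  papilla_line_fraction = 0.72)
  ls <- ideal_landmarks(build_template(p))
  r <- full_report(ls, params = p)
  expect_lt(max(abs(unlist(r$deviations))), 1e-9)
  aw <- apparent_widths(ls)
  expect_equal(unname(aw$ratios$right["lateral_central"]), 0.72)
  cr <- connector_ratios(ls)
  expect_equal(unname(cr$ratios), c(45, 35, 25), tolerance = 1e-12)
})

test_that("empty and sparse landmark sets degrade to absent fields", {
  empty <- sct_landmarks(frame = "template")
  r <- full_report(empty)
  expect_false(r$cervical_line$available)
  expect_false(r$connector_ratios$available)
  expect_false(r$smile_arc$available)
  expect_false(r$lip_line$available)
  expect_false(r$symmetry_score$available)
  expect_length(r$deviations, 0)
  # widened lateral: regressive deviation flagged, dominance broken
  ls <- ideal_ls()
  ls <- nudge(ls, "22_mesial_incisal", dx = -1.2)
  ls <- nudge(ls, "22_distal_incisal", dx = 1.2)
  r2 <- full_report(ls)
  expect_false(r2$dominance_ok)
  expect_gt(abs(r2$deviations$regressive_lateral_central_left), 0.1)
})

test_that("metrics are invariant under rigid motion and classes under scaling", {
  ls <- make_smile("ideal", noise_sd = 0.05, seed = 11)
  r0 <- full_report(ls)
  for (case in list(c(0.35, 14, -6), c(-1.2, -30, 40), c(3.1, 5, 5))) {
    r1 <- full_report(rigid_move(ls, case[1], case[2], case[3]))
    expect_equal(r1$cervical_line$offsets, r0$cervical_line$offsets,
                 tolerance = 1e-8)
    expect_equal(r1$incisal_outline$s, r0$incisal_outline$s,
                 tolerance = 1e-8)
    expect_equal(r1$connector_ratios$ratios, r0$connector_ratios$ratios,
                 tolerance = 1e-8)
    expect_equal(r1$smile_arc$a_incisal, r0$smile_arc$a_incisal,
                 tolerance = 1e-10)
    expect_equal(r1$symmetry_score$score, r0$symmetry_score$score,
                 tolerance = 1e-8)
    expect_identical(r1$smile_arc$class, r0$smile_arc$class)
    expect_identical(r1$lip_line$class, r0$lip_line$class)
  }
  for (s in c(0.05, 3, 40)) {
    r2 <- full_report(scale_ls(ls, s))
    expect_identical(r2$cervical_line$class, r0$cervical_line$class)
    expect_identical(r2$incisal_outline$class, r0$incisal_outline$class)
    expect_identical(r2$smile_arc$class, r0$smile_arc$class)
    expect_identical(r2$lip_line$class, r0$lip_line$class)
    expect_equal(r2$connector_ratios$ratios, r0$connector_ratios$ratios,
                 tolerance = 1e-8)
    expect_equal(unlist(r2$regressive_ratios),
                 unlist(r0$regressive_ratios), tolerance = 1e-8)
  }
})

test_that("mirror reflection leaves scalars unchanged and swaps sides", {
  ls <- make_smile("asymmetric")
  r0 <- full_report(ls)
  r1 <- full_report(reflect_ls(ls))
  expect_equal(r1$symmetry_score$score, r0$symmetry_score$score,
               tolerance = 1e-9)
  expect_equal(r1$incisal_outline$s, r0$incisal_outline$s, tolerance = 1e-9)
  expect_equal(unname(r1$cervical_line$offsets["right"]),
               unname(r0$cervical_line$offsets["left"]), tolerance = 1e-9)
  expect_equal(unname(r1$regressive_ratios$right["lateral_central"]),
               unname(r0$regressive_ratios$left["lateral_central"]),
               tolerance = 1e-9)
})

test_that("report exports round-trip through JSON and the flat table", {
  r <- full_report(make_smile("ideal"))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(r, f1)
  write_report(r, f2)
  doc <- jsonlite::read_json(f1, simplifyVector = TRUE)
  expect_identical(doc$cervical_line$class, "convex")
  tab <- utils::read.delim(f2)
  expect_true("connector_central_central" %in% tab$metric)
  expect_equal(tab$value[tab$metric == "connector_central_central"], 50,
               tolerance = 1e-9)
})
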