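test_that("default template encodes the stated construction constants", {
  g <- default_geom()
  b <- function(t) g$boxes[g$boxes$tooth == t, ]
  # central: 8 mm wide, 10 mm high, incisal edge on y = 0
  expect_equal(b("21")$x_distal - b("21")$x_mesial, 8)
  expect_equal(b("21")$y_incisal - b("21")$y_zenith, 10)
  expect_equal(b("21")$y_incisal, 0)
  # regressive widths: two applications of the diagonal proportion
  expect_equal(b("22")$x_distal - b("22")$x_mesial, 8 / sqrt(2))
  expect_equal(b("23")$x_distal - b("23")$x_mesial, 4)
  # lateral zenith 0.6 below, lateral edge 0.8 above, canines level
  expect_equal(b("22")$y_zenith - b("21")$y_zenith, 0.6)
  expect_equal(b("21")$y_incisal - b("22")$y_incisal, 0.8)
  expect_equal(b("23")$y_zenith, b("21")$y_zenith)
  expect_equal(b("23")$y_incisal, b("21")$y_incisal)
  # midline connector: contact at -2, papilla line at -7
  cc <- g$connectors[g$connectors$pair == "11-21", ]
  expect_equal(cc$y_contact_point, -2)
  expect_equal(cc$y_papilla_tip, -7)
})

test_that("boxes abut without gaps and mirror exactly across the midline", {
  g <- default_geom()
  b <- function(t) g$boxes[g$boxes$tooth == t, ]
  expect_identical(b("21")$x_distal, b("22")$x_mesial)
  expect_identical(b("22")$x_distal, b("23")$x_mesial)
  for (pair in list(c("11", "21"), c("12", "22"), c("13", "23"))) {
    expect_identical(b(pair[1])$x_mesial, -b(pair[2])$x_mesial)
    expect_identical(b(pair[1])$x_distal, -b(pair[2])$x_distal)
    expect_identical(b(pair[1])$y_zenith, b(pair[2])$y_zenith)
    expect_identical(b(pair[1])$y_incisal, b(pair[2])$y_incisal)
  }
  # connectors mirror too
  cs <- g$connectors
  expect_identical(cs$x[cs$pair == "11-12"], -cs$x[cs$pair == "21-22"])
  expect_identical(cs$x[cs$pair == "12-13"], -cs$x[cs$pair == "22-23"])
})

test_that("template is exactly scale-equivariant under doubled dimensions", {
  # the zenith drop and incisal step are absolute mm lengths, so a doubled
  # template doubles them along with the central width
  g1 <- build_template(sct_params(central_width = 8))
  g2 <- build_template(sct_params(central_width = 16,
                                  lateral_zenith_drop = 1.2,
                                  incisal_step = 1.6))
  for (col in c("x_mesial", "x_distal", "y_zenith", "y_incisal"))
    expect_identical(g2$boxes[[col]], 2 * g1$boxes[[col]])
  for (col in c("x", "y_papilla_tip", "y_contact_point"))
    expect_identical(g2$connectors[[col]], 2 * g1$connectors[[col]])
})

test_that("connector heights match the configured fractions to machine precision", {
  p <- sct_params(central_width = 7.3, wh_ratio = 0.78,
                  connector_fractions = c(0.55, 0.37, 0.22),
                  papilla_line_fraction = 0.66)
  g <- build_template(p)
  h1 <- p$central_width / p$wh_ratio
  got <- (g$connectors$y_contact_point - g$connectors$y_papilla_tip) / h1
  expect_equal(got, c(0.22, 0.37, 0.55, 0.37, 0.22), tolerance = 1e-15)
})

test_that("total template width follows the closed form 2 W1 (1 + r + r^2)", {
  for (w1 in c(6.5, 8, 9.1)) {
    r <- 1 / sqrt(2)
    g <- build_template(sct_params(central_width = w1))
    expect_equal(max(g$boxes$x_distal) - min(g$boxes$x_distal),
                 2 * w1 * (1 + r + r^2))
  }
})

test_that("widths strictly decrease from central to canine (dominance)", {
  for (rf in c(0.6, 1 / sqrt(2), 0.9)) {
    g <- build_template(sct_params(regressive_factor = rf))
    w <- abs(g$boxes$x_distal - g$boxes$x_mesial)
    names(w) <- g$boxes$tooth
    expect_true(w["11"] > w["12"] && w["12"] > w["13"])
    expect_true(w["21"] > w["22"] && w["22"] > w["23"])
  }
})

test_that("parameter validation names the offending field", {
  expect_error(sct_params(central_width = 0), "central_width",
               class = "sct_validation_error")
  expect_error(sct_params(wh_ratio = 1.2), "wh_ratio",
               class = "sct_validation_error")
  expect_error(sct_params(regressive_factor = 1), "regressive_factor",
               class = "sct_validation_error")
  expect_error(sct_params(connector_fractions = c(0.3, 0.4, 0.5)),
               "connector_fractions", class = "sct_validation_error")
  expect_error(sct_params(lateral_zenith_drop = -1), "lateral_zenith_drop",
               class = "sct_validation_error")
  expect_error(sct_params(papilla_line_fraction = 0.4),
               "papilla_line_fraction", class = "sct_validation_error")
})

test_that("ideal landmarks export the template's own geometry", {
  ls <- ideal_ls()
  expect_s3_class(validate_landmarks(ls), "sct_landmarks")
  expect_identical(nrow(ls$points), 34L)
  # tooth 22 zenith: lateral box midline, 9.4 mm gingival to the edge line
  z22 <- lm_point(ls, "22_zenith")
  expect_equal(unname(z22), c(8 + (8 / sqrt(2)) / 2, -9.4))
  expect_equal(unname(lm_point(ls, "cp_11_21")), c(0, -2))
  expect_equal(unname(lm_point(ls, "pap_22_23")), c(8 + 8 / sqrt(2), -7))
})

test_that("template JSON export is a self-describing document", {
  g <- default_geom()
  f <- withr::local_tempfile(fileext = ".json")
  write_template(g, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(doc$units, "mm")
  expect_equal(doc$params$central_width, 8)
  expect_equal(sort(doc$boxes$tooth), sort(g$boxes$tooth))
  expect_equal(doc$connectors$y_contact_point,
               g$connectors$y_contact_point)
})
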