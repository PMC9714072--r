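make_model <- function() {
  prim <- root_organ(c(10, 10.5, 11, 12), c(5, 20, 40, 60), c(1, 2, 3, 4))
  l1 <- root_organ(c(10.6, 16, 21), c(22, 24, 25), c(2, 3, 4), order = 2)
  l2 <- root_organ(c(11, 5, 2), c(41, 43, 44.5), c(3, 3.5, 4), order = 2,
                   extrapolated = c(FALSE, FALSE, TRUE))
  root_system_model(list(list(primary = prim, laterals = list(l1, l2))),
                    px_size_um = 19, timestep_h = 8, n_timesteps = 4,
                    seed_row = 5)
}

test_that("RSML round-trips models exactly", {
  model <- make_model()
  path <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(model, path)
  back <- read_rsml(path)
  expect_equal(length(back$plants), 1)
  expect_equal(length(back$plants[[1]]$laterals), 2)
  for (i in seq_along(model$plants[[1]]$laterals)) {
    a <- model$plants[[1]]$laterals[[i]]
    b <- back$plants[[1]]$laterals[[i]]
    expect_equal(a$x, b$x, tolerance = 1e-6)
    expect_equal(a$y, b$y, tolerance = 1e-6)
    expect_equal(a$t, b$t, tolerance = 1e-6)
    expect_identical(a$extrapolated, b$extrapolated)
  }
  expect_equal(back$px_size_um, 19)
  expect_equal(back$timestep_h, 8)
  expect_equal(back$n_timesteps, 4L)
})

test_that("RSML structure nests laterals and writes deterministically", {
  model <- make_model()
  p1 <- withr::local_tempfile(fileext = ".rsml")
  p2 <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(model, p1)
  write_rsml(model, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  doc <- xml2::read_xml(p1)
  expect_length(xml2::xml_find_all(doc, "./scene/plant"), 1)
  expect_length(xml2::xml_find_all(doc, "./scene/plant/root"), 1)
  expect_length(xml2::xml_find_all(doc, "./scene/plant/root/root"), 2)
})

test_that("time-free RSML is parsed with a fallback warning", {
  minimal <- '<?xml version="1.0"?>
  <rsml><metadata><resolution>19</resolution>
  <time-sequence><timestep>8</timestep><observations>6</observations>
  </time-sequence></metadata>
  <scene><plant id="1"><root id="1">
  <geometry><polyline>
  <point x="1" y="2"/><point x="3" y="4"/><point x="5" y="8"/>
  </polyline></geometry>
  </root></plant></scene></rsml>'
  path <- withr::local_tempfile(fileext = ".rsml")
  writeLines(minimal, path)
  expect_warning(model <- read_rsml(path), "assuming all nodes at t = 6")
  expect_equal(model$plants[[1]]$primary$t, rep(6, 3))
})

test_that("malformed function sample counts are parse errors", {
  bad <- '<?xml version="1.0"?>
  <rsml><metadata><resolution>19</resolution></metadata>
  <scene><plant id="1"><root id="r1">
  <geometry><polyline>
  <point x="1" y="2"/><point x="3" y="4"/>
  </polyline></geometry>
  <functions><function name="time" domain="polyline">
  <sample value="1"/></function></functions>
  </root></plant></scene></rsml>'
  path <- withr::local_tempfile(fileext = ".rsml")
  writeLines(bad, path)
  expect_error(read_rsml(path), "1 samples for 2 points")
  # organs with fewer than 2 points cannot be serialized
  broken <- root_system_model(list(list(
    primary = root_organ(1, 1, 1), laterals = list())), 19, 8, 1)
  expect_error(write_rsml(broken, withr::local_tempfile()),
               "fewer than 2 points")
})
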