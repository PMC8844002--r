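test_that("an empty scene is all sun", {
  scn <- scene(1.35, 103.68)
  f <- cast_fractions(scn, rect_strip(0, 5), sun_position(123, 37))
  expect_equal(f$f_sun, 1)
  expect_equal(f$f_tree + f$f_building, 0)
})

test_that("wall shadow matches the analytic shadow depth", {
  scn <- wall_scene(h = 10)  # sun west at 45 deg: shadow covers x in [0, 10]
  sun <- sun_position(270, 45)
  inside <- cast_fractions(scn, rect_strip(2, 3.2), sun)
  expect_equal(inside$f_building, 1)
  beyond <- cast_fractions(scn, rect_strip(12, 13.2), sun)
  expect_equal(beyond$f_sun, 1)
  # straddling strip: fraction matches the analytic cover
  str <- cast_fractions(scn, rect_strip(9, 11), sun)
  expect_lt(abs(str$f_building - analytic_wall_fraction(9, 11, 10, 45)),
            2 * 0.1 / 1.2)
})

test_that("shade fractions always sum to one and casting is deterministic", {
  set.seed(5)
  scn <- scene(1.35, 103.68,
               buildings = list(list(footprint = rect_strip(-8, -2, -20, 20),
                                     height = 12)),
               trees = data.frame(x = c(3, 6), y = c(0, 4), z = 5,
                                  rx = 2.5, rz = 2))
  for (i in 1:10) {
    sun <- sun_position(runif(1, 0, 360), runif(1, 5, 85))
    f <- cast_fractions(scn, rect_strip(0, 10, -3, 3), sun)
    expect_equal(f$f_sun + f$f_tree + f$f_building, 1)
    g <- cast_fractions(scn, rect_strip(0, 10, -3, 3), sun)
    expect_identical(unclass(f)[c("f_sun", "f_tree", "f_building")],
                     unclass(g)[c("f_sun", "f_tree", "f_building")])
  }
})

test_that("lowering the sun never shrinks building shade on the shadow side", {
  scn <- wall_scene(h = 10)
  strip <- rect_strip(2, 8)
  els <- seq(80, 10, by = -10)
  fb <- vapply(els, function(el)
    cast_fractions(scn, strip, sun_position(270, el))$f_building, 0)
  expect_true(all(diff(fb) >= 0))
})

test_that("a ray through both a tree and a building counts as building shade", {
  # crown directly between the strip and the low western sun, wall behind it
  scn <- scene(1.35, 103.68,
               buildings = list(list(footprint = rect_strip(-30, -28, -20, 20),
                                     height = 40)),
               trees = data.frame(x = -5, y = 0, z = 5, rx = 3, rz = 3))
  sun <- sun_position(270, 30)
  f <- cast_fractions(scn, rect_strip(-1, 1, -1, 1), sun)
  expect_equal(f$f_building, 1)
  expect_equal(f$f_tree, 0)
  # without the wall the same rays are tree-shaded
  scn2 <- scene(1.35, 103.68, trees = scn$trees)
  f2 <- cast_fractions(scn2, rect_strip(-1, 1, -1, 1), sun)
  expect_gt(f2$f_tree, 0.9)
})

test_that("overhead sun puts points under a crown in tree shade", {
  scn <- scene(1.35, 103.68, trees = data.frame(x = 0, y = 0, z = 6,
                                                rx = 3, rz = 2))
  f <- cast_fractions(scn, rect_strip(-1, 1, -1, 1), sun_position(0, 90))
  expect_equal(f$f_tree, 1)
})

test_that("degenerate strips and bad grids are rejected with context", {
  scn <- scene(1.35, 103.68)
  expect_error(cast_fractions(scn, rect_strip(0, 0.04, 0, 0.04),
                              sun_position(0, 60), strip_label = "strip 3"),
               "strip 3")
  expect_error(cast_fractions(scn, rect_strip(0, 5), sun_position(0, 60),
                              grid_step = -1), "grid_step")
})

test_that("the representative strip has the lowest sun fraction, first on ties", {
  a <- shade_fractions(0.8, 0.1, 0.1)
  b <- shade_fractions(0.2, 0.3, 0.5)
  r <- representative_composition(list(a, b))
  expect_equal(r$f_sun, 0.2)
  expect_equal(attr(r, "strip"), 2L)
  expect_equal(attr(representative_composition(list(b)), "strip"), 1L)
  t1 <- shade_fractions(0.3, 0.7, 0); t2 <- shade_fractions(0.3, 0, 0.7)
  tie <- representative_composition(list(t1, t2))
  expect_equal(attr(tie, "strip"), 1L)
  expect_equal(tie$f_tree, 0.7)
  expect_error(representative_composition(list()), "empty")
})

test_that("insufficient building shade on wide paths is re-counted as sun", {
  f <- shade_fractions(0.917, 0, 0.083)
  out <- apply_min_building_shade_rule(f, path_is_wide = TRUE)
  expect_equal(out$f_sun, 1)
  expect_equal(out$f_building, 0)
  # the rule is strictly 'less than 15%'
  at <- apply_min_building_shade_rule(shade_fractions(0.85, 0, 0.15), TRUE)
  expect_equal(at$f_building, 0.15)
  # narrow paths are untouched
  nr <- apply_min_building_shade_rule(shade_fractions(0.9, 0, 0.1), FALSE)
  expect_equal(nr$f_building, 0.1)
})

test_that("fractions scale into metric lengths along the centreline", {
  pc <- compose_lengths(100, shade_fractions(0.5, 0.2, 0.3))
  expect_equal(c(pc$a_sun, pc$a_tree, pc$a_shade), c(50, 20, 30))
  pc2 <- compose_lengths(137.4, shade_fractions(0.25, 0.25, 0.5))
  expect_equal(c(pc2$a_sun, pc2$a_tree, pc2$a_shade), c(34.35, 34.35, 68.7))
  expect_equal(total_length(pc2), 137.4)
  expect_error(compose_lengths(-5, shade_fractions(1, 0, 0)), "positive")
})

test_that("a scene round-trips through GeoJSON with identical shading", {
  cs <- generate_scene(n_trees = 2)
  sun <- sun_position(200, 35)
  before <- path_option_composition(cs$scene, "north", sun, grid_step = 0.3)
  tmp <- tempfile(fileext = ".geojson")
  write_scene_geojson(cs$scene, tmp)
  scn2 <- read_scene_geojson(tmp)
  after <- path_option_composition(scn2, "north", sun, grid_step = 0.3)
  expect_equal(before$a_sun, after$a_sun)
  expect_equal(before$a_tree, after$a_tree)
  expect_equal(before$a_shade, after$a_shade)
  unlink(tmp)
})

test_that("the full option pipeline shades the path along a sun-side building", {
  cs <- generate_scene(n_trees = 0, building_height = 15)
  # low southern sun: the south building shadows the south path entirely
  sun <- sun_position(180, 25)
  south <- path_option_composition(cs$scene, "south", sun, grid_step = 0.2)
  expect_equal(south$a_shade, 100)
  # the lawn-crossing narrow path is fully sun-lit under an overhead sun
  cross <- path_option_composition(cs$scene, "cross_east", sun_position(0, 89.9),
                                   grid_step = 0.2)
  expect_equal(cross$a_sun, 38)
})
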