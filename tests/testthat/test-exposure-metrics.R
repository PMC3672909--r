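test_that("dietary intake is the portion-weighted contaminant sum", {
  tab <- data.frame(item_id = c("a", "b"),
                    cd_per_medium_serving = c(5, 2),
                    kcal_per_medium_serving = c(800, 400))
  one <- data.frame(item_id = "a", frequency = 1, portion = "medium")
  expect_equal(dietary_cd_intake(one, tab)$intake, 5)
  small <- data.frame(item_id = "a", frequency = 1, portion = "small")
  expect_equal(dietary_cd_intake(small, tab, kcal_range = c(0, Inf))$intake,
               2.5)
  # additive over items (independent weighted-sum oracle)
  set.seed(8)
  resp <- data.frame(item_id = sample(c("a", "b"), 6, TRUE),
                     frequency = runif(6, 0, 2),
                     portion = sample(c("small", "medium", "large"), 6,
                                      TRUE))
  pw <- c(small = 0.5, medium = 1, large = 1.5)
  oracle <- sum(resp$frequency * pw[resp$portion] *
                  tab$cd_per_medium_serving[match(resp$item_id,
                                                  tab$item_id)])
  expect_equal(dietary_cd_intake(resp, tab,
                                 kcal_range = c(0, Inf))$intake, oracle)
})

test_that("implausible energy or absent responses give a reasoned missing", {
  tab <- data.frame(item_id = "a", cd_per_medium_serving = 5,
                    kcal_per_medium_serving = 500)
  low <- data.frame(item_id = "a", frequency = 1, portion = "medium")
  out <- dietary_cd_intake(low, tab)        # 500 kcal < 600
  expect_true(is.na(out$intake))
  expect_identical(out$reason, "implausible energy")
  high <- data.frame(item_id = "a", frequency = 11, portion = "medium")
  expect_identical(dietary_cd_intake(high, tab)$reason,
                   "implausible energy")
  none <- dietary_cd_intake(NULL, tab)
  expect_true(is.na(none$intake))
  expect_identical(none$reason, "no responses")
  bad <- data.frame(item_id = "zz", frequency = 1, portion = "medium")
  expect_error(dietary_cd_intake(bad, tab), "missing from contaminant")
})

test_that("traffic density clips segments against the buffer exactly", {
  # fully interior segment: VKT / (pi r^2)
  inside <- data.frame(x1 = -0.05, y1 = 0, x2 = 0.05, y2 = 0,
                       aadt = 10000)
  expect_equal(traffic_density(c(0, 0), inside),
               10000 * 0.1 / (pi * 0.3^2))
  expect_equal(round(pi * 0.3^2, 2), 0.28)
  expect_identical(traffic_density(c(10, 10), inside), 0)
  expect_identical(traffic_density(c(0, 0), NULL), 0)

  # partial overlaps: numeric point-sampling oracle along each segment
  set.seed(21)
  for (i in 1:8) {
    seg <- data.frame(x1 = runif(1, -0.6, 0.6), y1 = runif(1, -0.6, 0.6),
                      x2 = runif(1, -0.6, 0.6), y2 = runif(1, -0.6, 0.6),
                      aadt = 1000)
    tt <- seq(0, 1, length.out = 200001)
    px <- seg$x1 + tt * (seg$x2 - seg$x1)
    py <- seg$y1 + tt * (seg$y2 - seg$y1)
    seg_len <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2)
    oracle_len <- mean(px^2 + py^2 < 0.3^2) * seg_len
    expect_equal(traffic_density(c(0, 0), seg),
                 1000 * oracle_len / (pi * 0.3^2), tolerance = 1e-3)
  }
})

test_that("traffic density is rigid-motion invariant and AADT-linear", {
  set.seed(22)
  roads <- data.frame(x1 = runif(5, -1, 1), y1 = runif(5, -1, 1),
                      x2 = runif(5, -1, 1), y2 = runif(5, -1, 1),
                      aadt = runif(5, 1000, 50000))
  res <- c(0.1, -0.2)
  base <- traffic_density(res, roads)
  th <- 0.83; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(5, -3)
  rot <- function(x, y) t(Rm %*% rbind(x, y) + shift)
  p1 <- rot(roads$x1, roads$y1); p2 <- rot(roads$x2, roads$y2)
  moved <- data.frame(x1 = p1[, 1], y1 = p1[, 2],
                      x2 = p2[, 1], y2 = p2[, 2], aadt = roads$aadt)
  res2 <- as.numeric(Rm %*% res + shift)
  expect_equal(traffic_density(res2, moved), base, tolerance = 1e-10)
  scaled <- roads; scaled$aadt <- scaled$aadt * 3.7
  expect_equal(traffic_density(res, scaled), 3.7 * base)
  bad <- roads; bad$x1[2] <- NA
  expect_error(traffic_density(res, bad), "malformed")
  expect_error(traffic_density(res, roads, radius_km = 0), "positive")
})

test_that("industrial emissions sum within the radius and grow with it", {
  fac <- data.frame(x = c(3, 6), y = c(0, 0), emissions_kg = c(10, 100))
  expect_equal(as.numeric(industrial_emissions(c(0, 0), fac)), 10)
  expect_equal(as.numeric(industrial_emissions(c(0, 0), NULL)), 0)
  three <- data.frame(x = c(1, 2, 4), y = 0, emissions_kg = c(1, 2, 4))
  expect_equal(as.numeric(industrial_emissions(c(0, 0), three)), 7)
  set.seed(23)
  fac2 <- data.frame(x = runif(30, -10, 10), y = runif(30, -10, 10),
                     emissions_kg = rlnorm(30))
  radii <- c(1, 2, 5, 8, 15)
  tot <- vapply(radii, function(r)
    as.numeric(industrial_emissions(c(0, 0), fac2, r)), numeric(1))
  expect_true(!is.unsorted(tot))
})

test_that("air linkage is an exact lookup that fails loudly", {
  tab <- data.frame(tract_id = c("t1", "t2"), air_cd = c(0.15, 0.4))
  expect_identical(link_air("t1", tab), 0.15)
  expect_identical(link_air(c("t2", "t1"), tab), c(0.4, 0.15))
  expect_error(link_air("t9", tab), "t9")
})

test_that("derived anthropometric covariates follow their formulas", {
  expect_equal(body_surface_area(65, 165),
               0.007184 * 65^0.425 * 165^0.725)
  expect_equal(round(body_surface_area(65, 165), 2), 1.72)
  # the variant exponent is exposed but not the default
  expect_true(body_surface_area(65, 165, height_exp = 0.275) < 0.3)
  expect_equal(body_mass_index(65, 165), 65 / 1.65^2)
  expect_identical(intensity_years(2, 10), 20)
  expect_error(body_surface_area(0, 165), "positive")
  expect_error(intensity_years(4, 3), "intensity")
})

test_that("exposure profiles assemble per participant", {
  s <- default_study()
  ex <- s$exposures
  expect_identical(ex$participant_id, s$cohort$id)
  num <- ex[, c("traffic_density", "industrial_kg_5km", "air_cd",
                "bsa", "bmi", "pack_years")]
  expect_true(all(num >= 0, na.rm = TRUE))
  expect_true(all(is.na(ex$dietary_cd) == !is.na(ex$dietary_reason) |
                    !is.na(ex$dietary_cd)))
  expect_true(all(ex$air_cd >= 0.05 & ex$air_cd <= 0.65))
})
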