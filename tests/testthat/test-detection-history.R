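test_that("occasions partition the deployment and photos land in the right cells", {
  dep <- data.frame(site_id = "s1", start = as.Date("2020-01-01"),
                    end = as.Date("2020-02-29"))  # 60 days
  dm <- build_detection_matrix(data.frame(site_id = character(),
                                          timestamp = as.Date(character())),
                               dep, occasion_length = 4)
  expect_equal(ncol(dm$y), 15)
  expect_equal(dm$anchors$days, 60L)
  expect_false(dm$anchors$short_final)

  # photos on days 1, 2, 9 of a 12-day deployment -> history (1, 0, 1)
  dep2 <- data.frame(site_id = "a", start = as.Date("2021-03-01"),
                     end = as.Date("2021-03-12"))
  ph2 <- data.frame(site_id = "a",
                    timestamp = as.Date("2021-03-01") + c(0, 1, 8))
  dm2 <- build_detection_matrix(ph2, dep2, occasion_length = 4)
  expect_equal(unname(dm2$y[1, ]), c(1L, 0L, 1L))

  # no photos, 8-day deployment -> (0, 0)
  dep3 <- data.frame(site_id = "b", start = as.Date("2021-03-01"),
                     end = as.Date("2021-03-08"))
  dm3 <- build_detection_matrix(ph2[0, ], dep3, occasion_length = 4)
  expect_equal(unname(dm3$y[1, ]), c(0L, 0L))

  # 10-day deployment at 4-day occasions: final short occasion retained
  dep4 <- data.frame(site_id = "c", start = as.Date("2021-03-01"),
                     end = as.Date("2021-03-10"))
  dm4 <- build_detection_matrix(ph2[0, ], dep4, occasion_length = 4)
  expect_equal(ncol(dm4$y), 3)
  expect_true(dm4$anchors$short_final)

  # occasion windows tile the deployment: no gap, no overlap
  expect_true(all(dm4$anchors$n_occasions * 4 >= dm4$anchors$days))
  expect_true(all((dm4$anchors$n_occasions - 1) * 4 < dm4$anchors$days))
})

test_that("unequal deployments give trailing NAs, never empty rows", {
  dep <- data.frame(site_id = c("a", "b"),
                    start = as.Date("2021-01-01"),
                    end = as.Date(c("2021-01-16", "2021-01-08")))
  dm <- build_detection_matrix(data.frame(site_id = "a",
                                          timestamp = as.Date("2021-01-15")),
                               dep, occasion_length = 4)
  expect_equal(dim(dm$y), c(2L, 4L))
  expect_equal(unname(dm$y["b", ]), c(0L, 0L, NA_integer_, NA_integer_))
  expect_equal(unname(dm$y["a", ]), c(0L, 0L, 0L, 1L))
  expect_true(all(rowSums(!is.na(dm$y)) >= 1))
})

test_that("photos outside deployments and unknown sites are handled", {
  dep <- data.frame(site_id = "a", start = as.Date("2021-01-01"),
                    end = as.Date("2021-01-08"))
  stray <- data.frame(site_id = "a", timestamp = as.Date("2021-02-01"))
  expect_warning(dm <- build_detection_matrix(stray, dep, 4), "outside")
  expect_equal(sum(dm$y, na.rm = TRUE), 0)
  expect_error(build_detection_matrix(stray, dep, 4, outside = "error"),
               "outside")
  expect_error(build_detection_matrix(
    data.frame(site_id = "zzz", timestamp = as.Date("2021-01-02")), dep, 4),
    "unknown site")
})

test_that("matrix round-trips through photo simulation and rebuilding", {
  sim <- make_test_sim()
  rebuilt <- build_detection_matrix(sim$photos, sim$deployments,
                                    sim$design$occasion_length)
  expect_identical(unname(rebuilt$y), unname(sim$matrix$y))
})

test_that("adding a photo is monotone for cells and naive occupancy", {
  dep <- data.frame(site_id = c("a", "b"), start = as.Date("2021-01-01"),
                    end = as.Date("2021-01-16"))
  ph <- data.frame(site_id = "a", timestamp = as.Date("2021-01-02"))
  dm1 <- build_detection_matrix(ph, dep, 4)
  ph2 <- rbind(ph, data.frame(site_id = "b",
                              timestamp = as.Date("2021-01-10")))
  dm2 <- build_detection_matrix(ph2, dep, 4)
  expect_true(all(dm2$y >= dm1$y, na.rm = TRUE))
  expect_gte(naive_occupancy(dm2), naive_occupancy(dm1))
})

test_that("naive occupancy matches its definition and edge cases", {
  y <- matrix(0L, 380, 15)
  y[seq_len(149), 1] <- 1L
  expect_equal(round(naive_occupancy(y), 3), 0.392)
  expect_equal(naive_occupancy(matrix(0L, 5, 3)), 0)
  expect_equal(naive_occupancy(matrix(1L, 5, 3)), 1)
  expect_error(naive_occupancy(matrix(integer(0), 0, 3)), "zero sites")
})

test_that("independent detections collapse within the time window", {
  ph <- function(times) data.frame(
    site_id = "a",
    timestamp = as.POSIXct(times, tz = "UTC")
  )
  expect_equal(independent_detections(
    ph(c("2021-01-01 10:00:00", "2021-01-01 10:10:00")), 30), 1L)
  expect_equal(independent_detections(
    ph(c("2021-01-01 10:00:00", "2021-01-01 11:00:00")), 30), 2L)
  # chain of photos each 10 min apart collapses into one event
  chain <- ph(as.POSIXct("2021-01-01 10:00:00", tz = "UTC") +
                seq(0, 3600, by = 600))
  expect_equal(independent_detections(chain, 30), 1L)
  expect_equal(independent_detections(chain[0, ], 30), 0L)
  # same times at two sites never collapse together
  two <- rbind(chain, transform(chain, site_id = "b"))
  expect_equal(independent_detections(two, 30), 2L)
})

test_that("detection matrix serialization round-trips", {
  sim <- make_test_sim(n_sites = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_matrix(sim$matrix, path)
  back <- read_detection_matrix(path)
  expect_equal(unname(back$y), unname(sim$matrix$y))
  expect_equal(back$occasion_length, sim$matrix$occasion_length)
  expect_equal(back$site_ids, sim$matrix$site_ids)
})
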