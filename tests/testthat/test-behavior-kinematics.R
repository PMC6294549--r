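test_that("angle normalization maps each larva's maximum to 1", {
  expect_equal(normalize_angles(c(10, 20, 40), rep("a", 3)), c(0.25, 0.5, 1))
  expect_equal(normalize_angles(25, "a"), 1)
  # larvae are normalized independently
  out <- normalize_angles(c(10, 20, 5, 50), c("a", "a", "b", "b"))
  expect_equal(out, c(0.5, 1, 0.1, 1))
  # invariance under uniform rescaling of a larva's raw angles
  raw <- c(3, 7, 9)
  expect_equal(normalize_angles(raw * 13, rep("x", 3)),
               normalize_angles(raw, rep("x", 3)))
  expect_warning(z <- normalize_angles(c(0, 0), rep("a", 2)), "all-zero")
  expect_equal(z, c(0, 0))
  expect_error(normalize_angles(-1, "a"), ">= 0")
})

test_that("filament speed is the maximum per-frame displacement over the frame period", {
  expect_equal(filament_speed(10, fps = 250), 2.5)
  expect_equal(filament_speed(c(0, 0, 0), fps = 250), 0)
  expect_equal(filament_speed(c(1, 9, 4), fps = 300), 2.7)
  expect_error(filament_speed(numeric(0), fps = 250), "two frames")
})

test_that("response classification combines angle cutoff and closure flag", {
  expect_equal(as.character(classify_response(0.3, TRUE, 0.4)), "closure_lowE")
  expect_equal(as.character(classify_response(0.7, FALSE, 0.4)), "wideE_only")
  expect_equal(as.character(classify_response(0, FALSE, 0.4)), "no_response")
  expect_equal(as.character(classify_response(0, TRUE, 0.4)), "closure_only")
  expect_equal(as.character(classify_response(0.9, TRUE, 0.4)), "closure_wideE")
  # sub-cutoff elevation without closure is treated as no response
  expect_equal(as.character(classify_response(0.2, FALSE, 0.4)), "no_response")
  # monotone in angle: class boundary crossed exactly once
  cls <- classify_response(seq(0.05, 0.95, by = 0.1), TRUE, 0.4)
  expect_equal(sum(diff(cls == "closure_wideE") != 0), 1)
})

test_that("latency arithmetic is exact in frames and milliseconds", {
  expect_equal(onset_latency(110, 100, 250), 40)
  expect_equal(onset_latency(100, 100, 250), 0)
  expect_equal(onset_latency(115, 100, 300), 50)
  expect_error(onset_latency(99, 100, 250), "precedes")
})

test_that("latency summaries use the notched-boxplot convention", {
  s <- summarize_latencies(c(10, 20, 30))
  expect_equal(s$median, 20)
  expect_equal(s$notch_high - s$median, 1.58 * 10 / sqrt(3))
  s1 <- summarize_latencies(42)
  expect_equal(s1$notch_low, 42)
  expect_equal(s1$notch_high, 42)
  # Monte-Carlo: median of synthetic latencies near the distribution median
  set.seed(2)
  v <- rnorm(400, 32, 6)
  s2 <- summarize_latencies(v)
  se_med <- 1.2533 * 6 / sqrt(400)
  expect_lt(abs(s2$median - 32), 3 * se_med)
})

test_that("coordination delays report sub-frame differences as bounds", {
  tr <- data.frame(fps = 250,
                   elevation_onset_left = c(110, 110, 110),
                   elevation_onset_right = c(110, 111, NA),
                   elevation_onset_sg1 = 110, elevation_onset_sg2 = 111,
                   elevation_onset_sg3 = 111)
  d <- coordination_delays(tr)
  lr <- d[d$pair == "left-right", ]
  expect_equal(lr$delay_ms[1], 4)      # same frame: <= one frame period
  expect_true(lr$is_bound[1])
  expect_equal(lr$delay_ms[2], 4)      # one frame apart: exactly 4 ms
  expect_false(lr$is_bound[2])
  expect_false(lr$available[3])
  sg <- d[d$trial == 1 & grepl("sg", d$pair), ]
  expect_equal(nrow(sg), 3)            # all segment pairs
  expect_equal(sg$delay_ms[sg$pair == "sg2-sg3"], 4)
  expect_true(sg$is_bound[sg$pair == "sg2-sg3"])
})

test_that("response profiles are proportions summing to one per bin", {
  cls <- factor(c("closure_wideE", "closure_wideE", "closure_wideE", "wideE_only"),
                levels = levels(classify_response(0, FALSE)))
  p <- response_profile(cls)
  expect_equal(sum(p$proportion), 1)
  expect_equal(p$proportion[p$response_class == "closure_wideE"], 0.75)
  p1 <- response_profile(cls, bin = c("a", "a", "b", "b"))
  sums <- tapply(p1$proportion, p1$bin, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("swim speed is the Euclidean step distance per time unit", {
  expect_equal(swim_speed(c(0, 3), c(0, 4), fps = 15), 75)
  expect_equal(swim_speed(c(1, 1, 1), c(2, 2, 2), fps = 15), c(0, 0))
  expect_length(swim_speed(0, 0, fps = 15), 0)
})
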