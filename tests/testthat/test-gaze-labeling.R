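# Gaze-to-item translation, dwell accumulation, labeling, and session QC.

snap <- function(elements, t = 0) list(timestamp_ms = t, elements = elements)

two_el <- data.frame(item_id = c("a", "b"),
                     x0 = c(0, 100), y0 = c(0, 0),
                     x1 = c(100, 200), y1 = c(50, 50))

gaze_sample <- function(x, y, t = 10, valid = 1L) {
  list(timestamp_ms = t, x_px = x, y_px = y, valid = valid)
}

test_that("rectangle containment is half-open at both corners", {
  s <- snap(two_el)
  expect_identical(attribute_sample(gaze_sample(0, 0), s), "a")      # (x0,y0) in
  expect_identical(attribute_sample(gaze_sample(100, 0), s), "b")    # a's x1 belongs to b
  expect_identical(attribute_sample(gaze_sample(200, 50), s), NA_character_)
  expect_identical(attribute_sample(gaze_sample(99.999, 49.999), s), "a")
  expect_identical(attribute_sample(gaze_sample(50, 25, valid = 0L), s),
                   NA_character_)
})

test_that("overlapping rectangles resolve to the first element, with a warning", {
  ov <- snap(data.frame(item_id = c("first", "second"),
                        x0 = c(0, 0), y0 = c(0, 0),
                        x1 = c(100, 100), y1 = c(100, 100)))
  expect_warning(hit <- attribute_sample(gaze_sample(10, 10), ov), "overlap")
  expect_identical(hit, "first")
})

test_that("a snapshot that postdates the sample is rejected", {
  expect_error(attribute_sample(gaze_sample(5, 5, t = 10), snap(two_el, t = 20)),
               "postdates")
})

test_that("random points attribute identically to a brute-force containment scan", {
  set.seed(41)
  el <- data.frame(item_id = sprintf("e%02d", 1:12),
                   x0 = runif(12, 0, 800), y0 = runif(12, 0, 900))
  el$x1 <- el$x0 + runif(12, 20, 300)
  el$y1 <- el$y0 + runif(12, 20, 300)
  s <- snap(el)
  xs <- runif(2000, -50, 1200); ys <- runif(2000, -50, 1200)
  for (i in seq_along(xs)) {
    brute <- NA_character_
    for (e in seq_len(nrow(el))) {
      if (el$x0[e] <= xs[i] && xs[i] < el$x1[e] &&
          el$y0[e] <= ys[i] && ys[i] < el$y1[e]) { brute <- el$item_id[e]; break }
    }
    got <- suppressWarnings(attribute_sample(gaze_sample(xs[i], ys[i]), s))
    if (!identical(got, brute)) {
      fail(sprintf("mismatch at (%.2f, %.2f): %s vs %s", xs[i], ys[i], got, brute))
    }
  }
  succeed()
})

test_that("a stream with no valid samples accrues zero dwell", {
  g <- data.frame(timestamp_ms = c(0, 20, 40), x_px = 50, y_px = 25, valid = 0L)
  dw <- compute_dwell(g, list(snap(two_el)))
  expect_true(all(dw == 0))
})

test_that("steady fixation accrues the expected dwell", {
  period <- 1000 / 60
  g <- data.frame(timestamp_ms = (0:59) * period, x_px = 50, y_px = 25,
                  valid = 1L)
  dw <- compute_dwell(g, list(snap(two_el)))
  expect_equal(unname(dw[["a"]]), 1000, tolerance = period / 1000)
  expect_identical(unname(dw[["b"]]), 0)
})

test_that("dwell follows an element across a scroll snapshot", {
  # element "a" moves up 60 px at t=500; gaze tracks it; totals by hand:
  # 5 samples x 100 ms before the scroll, 5 x 100 ms after = 1000 ms
  lay <- list(
    snap(data.frame(item_id = "a", x0 = 0, y0 = 100, x1 = 100, y1 = 160), 0),
    snap(data.frame(item_id = "a", x0 = 0, y0 = 40, x1 = 100, y1 = 100), 500))
  g <- data.frame(timestamp_ms = (0:9) * 100,
                  x_px = 50,
                  y_px = c(rep(130, 5), rep(70, 5)),
                  valid = 1L)
  dw <- compute_dwell(g, lay, max_gap_ms = 150)
  expect_equal(unname(dw[["a"]]), 1000)
  # without tracking (gaze stays at the old position) the tail misses
  g2 <- g; g2$y_px <- 130
  dw2 <- compute_dwell(g2, lay, max_gap_ms = 150)
  expect_equal(unname(dw2[["a"]]), 500)
})

test_that("per-sample contributions are capped at max_gap_ms", {
  g <- data.frame(timestamp_ms = c(0, 1000, 1020), x_px = 50, y_px = 25,
                  valid = 1L)
  dw <- compute_dwell(g, list(snap(two_el)), max_gap_ms = 100)
  # contributions: min(1000,100) + min(20,100) + min(median diff = 510, 100)
  expect_equal(unname(dw[["a"]]), 100 + 20 + 100)
})

test_that("stream ordering and snapshot coverage are enforced", {
  g <- data.frame(timestamp_ms = c(10, 5), x_px = 1, y_px = 1, valid = 1L)
  expect_error(compute_dwell(g, list(snap(two_el))), "increasing")
  g2 <- data.frame(timestamp_ms = c(5, 10), x_px = 1, y_px = 1, valid = 1L)
  expect_error(compute_dwell(g2, list(snap(two_el, t = 8))), "5")
  expect_error(compute_dwell(g2[0, ], list(snap(two_el))), "nonempty")
})

test_that("dwell computation matches the brute-force oracle on random streams", {
  set.seed(99)
  for (rep in 1:20) {
    lay <- lapply(0:3, function(k) {
      el <- data.frame(item_id = c("p", "q", "r"),
                       x0 = c(0, 120, 240), y0 = 10 * k,
                       x1 = c(100, 220, 340), y1 = 10 * k + 80)
      snap(el, t = k * 500)
    })
    n <- 150
    g <- data.frame(timestamp_ms = sort(runif(n, 0, 2000)),
                    x_px = runif(n, -20, 400), y_px = runif(n, 0, 140),
                    valid = rbinom(n, 1, 0.9))
    dw <- compute_dwell(g, lay)
    expect_equal(unclass(dw)[order(names(dw))],
                 oracle_dwell(g, lay)[order(names(dw))])
  }
})

test_that("total dwell never exceeds the observed span plus one period", {
  set.seed(7)
  lay <- list(snap(two_el))
  g <- data.frame(timestamp_ms = sort(runif(200, 0, 3000)),
                  x_px = runif(200, 0, 220), y_px = runif(200, 0, 60),
                  valid = 1L)
  dw <- compute_dwell(g, lay)
  span <- max(g$timestamp_ms) - min(g$timestamp_ms)
  expect_lte(sum(dw), span + median(diff(g$timestamp_ms)))
})

test_that("the 250 ms dwell threshold is inclusive", {
  dw <- c(exactly = 250, under = 249.99, never = 0, over = 251)
  lab <- derive_gaze_labels(dw, names(dw))
  expect_identical(unname(lab[["exactly"]]), "positive")
  expect_identical(unname(lab[["under"]]), "negative")
  expect_identical(unname(lab[["never"]]), "negative")
  expect_identical(unname(lab[["over"]]), "positive")
})

test_that("raising the threshold never adds positives", {
  set.seed(13)
  for (rep in 1:25) {
    items <- sprintf("i%02d", 1:15)
    dw <- setNames(rexp(15, rate = 1 / 300), items)
    taus <- sort(runif(4, 10, 10000))
    pos <- lapply(taus, function(tau) {
      lab <- derive_gaze_labels(dw, items, threshold_ms = tau)
      names(lab)[lab == "positive"]
    })
    for (j in seq_len(length(taus) - 1)) {
      expect_true(all(pos[[j + 1]] %in% pos[[j]]))
    }
  }
})

test_that("labels honor the item universe and reject unknown dwell items", {
  lab <- derive_gaze_labels(c(a = 300), present_items = c("a", "b"),
                            universe = c("a", "b", "c"))
  expect_identical(unname(lab[c("a", "b", "c")]),
                   c("positive", "negative", "absent"))
  expect_error(derive_gaze_labels(c(zz = 300), present_items = c("a", "b")),
               "zz")
})

test_that("manual labels cover the empty, full, and counted cases", {
  items <- sprintf("m%d", 1:7)
  lab0 <- derive_manual_labels(character(0), items)
  expect_true(all(lab0 == "negative"))
  lab_all <- derive_manual_labels(items, items)
  expect_true(all(lab_all == "positive"))
  lab3 <- derive_manual_labels(items[c(2, 4, 6)], items)
  expect_identical(sum(lab3 == "positive"), 3L)
  expect_identical(sum(lab3 == "negative"), 4L)
  expect_error(derive_manual_labels("ghost", items), "ghost")
})

test_that("session QC reports rather than throws", {
  expect_true(qc_session(fake_session(valid_fraction = 1))$valid)
  r <- qc_session(fake_session(valid_fraction = 0.3))
  expect_false(r$valid)
  expect_identical(r$reasons, "gaze_incomplete")
  empty <- fake_session(valid_fraction = 1)
  empty$gaze <- empty$gaze[0, ]
  expect_identical(qc_session(empty)$reasons, "gaze_incomplete")
  skipped <- fake_session()
  skipped$manual_selections <- NULL
  expect_identical(qc_session(skipped)$reasons, "selection_skipped")
  both <- fake_session(valid_fraction = 0.2)
  both$manual_selections <- NULL
  expect_setequal(qc_session(both)$reasons,
                  c("gaze_incomplete", "selection_skipped"))
  # the boundary fraction passes (invalid strictly below the minimum)
  expect_true(qc_session(fake_session(valid_fraction = 0.5))$valid)
})
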