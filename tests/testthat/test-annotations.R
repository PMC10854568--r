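test_that("centroid CSV and ASAP XML dialects parse to the same records", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("slide_id,annotator_id,x,y",
               "S1,anno1,100.5,200.0",
               "S1,anno1,300,400",
               "S1,anno1,50,60"), csv)
  got <- parse_centroids(csv, "csv")
  expect_equal(nrow(got), 3)
  expect_equal(got$x[1], 100.5)

  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<ASAP_Annotations><Annotations>",
    '<Annotation Name="Annotation 0" Type="Dot" PartOfGroup="None" Color="#F4FA58">',
    '<Coordinates><Coordinate Order="0" X="100.5" Y="200.0"/></Coordinates>',
    "</Annotation>",
    "</Annotations></ASAP_Annotations>"), xml)
  got_xml <- parse_centroids(xml, "asap_xml", slide_id = "S1",
                             annotator_id = "anno1")
  expect_equal(nrow(got_xml), 1)
  expect_equal(got_xml$x, 100.5)
  expect_equal(got_xml$y, 200.0)

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_warning(none <- parse_centroids(empty, "csv"), "empty")
  expect_equal(nrow(none), 0)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("slide_id,annotator_id,x,y", "S1,anno1,oops,2"), bad)
  expect_error(parse_centroids(bad, "csv"), "non-numeric")
  expect_error(parse_centroids(csv, "nope"), "arg")
})

test_that("agreement pairing is greedy by distance, one-to-one, radius-bounded", {
  pts <- function(x, y, sid = "S1") data.frame(slide_id = sid, x = x, y = y)
  # identical lists pair completely
  a <- pts(c(0, 100, 200), c(0, 0, 0))
  m <- match_annotator_centroids(a, a, radius_px = 25)
  expect_equal(nrow(m$agreed), 3)
  expect_equal(length(m$unmatched_a), 0)
  expect_equal(length(m$unmatched_b), 0)
  # just outside the radius: no agreement
  m2 <- match_annotator_centroids(pts(0, 0), pts(6, 0), radius_px = 5)
  expect_equal(nrow(m2$agreed), 0)
  # 2x1 candidates: the closer a-point wins, the other is unmatched
  m3 <- match_annotator_centroids(pts(c(0, 10), c(0, 0)), pts(1, 0),
                                  radius_px = 5)
  expect_equal(m3$agreed$a_idx, 1L)
  expect_equal(m3$unmatched_a, 2L)
  # consensus position is the midpoint of the pair
  expect_equal(m3$agreed$x, 0.5)
  expect_error(match_annotator_centroids(pts(0, 0), pts(0, 0, sid = "S2")),
               "mixed")
})

test_that("agreement is symmetric in count and capped by the smaller list", {
  set.seed(5)
  for (rep in 1:50) {
    na <- sample(0:6, 1); nb <- sample(0:6, 1)
    a <- data.frame(x = runif(na, 0, 50), y = runif(na, 0, 50))
    b <- data.frame(x = runif(nb, 0, 50), y = runif(nb, 0, 50))
    mab <- match_annotator_centroids(a, b, radius_px = 10)
    mba <- match_annotator_centroids(b, a, radius_px = 10)
    expect_equal(nrow(mab$agreed), nrow(mba$agreed))
    expect_lte(nrow(mab$agreed), min(nrow(a), nrow(b)))
    # greedy matches maximum cardinality on these small instances
    if (nrow(a) > 0 && nrow(b) > 0) {
      expect_equal(nrow(mab$agreed), oracle_max_matching(a, b, 10))
    }
  }
})

test_that("agreement summary reproduces published per-slide percentages", {
  counts <- reference_agreement_counts()
  summ <- agreement_summary(counts)
  row <- summ$table[summ$table$slide_id == "F17-04773", ]
  expect_equal(row$pct_agree_anno1, 74.19)
  expect_equal(row$pct_agree_anno2, 74.19)
  expect_equal(unname(summ$avg["pct_agree_anno1"]), 74.72)
  expect_equal(unname(summ$avg["pct_agree_anno2"]), 81.12)
  totals <- summ$table[summ$table$slide_id == "Total:", ]
  expect_equal(totals$n_anno1, 3169)
  expect_equal(totals$n_anno2, 2673)
  expect_equal(totals$n_agreed, 2192)
  # perfect agreement on one slide
  one <- agreement_summary(data.frame(slide_id = "S", n_anno1 = 7,
                                      n_anno2 = 7, n_agreed = 7))
  expect_equal(one$table$pct_agree_anno1[1], 100.00)
  # a zero count leaves the percentage undefined and out of the average
  expect_message(
    z <- agreement_summary(data.frame(slide_id = c("A", "B"),
                                      n_anno1 = c(0, 10),
                                      n_anno2 = c(5, 10),
                                      n_agreed = c(0, 5))),
    "zero")
  expect_true(is.na(z$table$pct_agree_anno1[1]))
  expect_equal(unname(z$avg["pct_agree_anno1"]), 50.00)
})

test_that("centroid-to-box expansion is centred, clipped, and invertible", {
  ag <- data.frame(x = 100, y = 100)
  b <- centroids_to_boxes(ag, box_size_px = 32, level = 0, from_level = 0)
  expect_equal(unlist(b[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 84, y_min = 84, x_max = 116, y_max = 116))
  # near the origin the box is clipped
  edge <- centroids_to_boxes(data.frame(x = 5, y = 5), 32, level = 0,
                             from_level = 0, slide_dims = c(512, 512))
  expect_equal(unlist(edge[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 0, y_min = 0, x_max = 21, y_max = 21))
  expect_equal(nrow(centroids_to_boxes(ag[0, ], 32)), 0)
  expect_error(centroids_to_boxes(ag, 31), "even")
  # round trip: box centre recovers the (rescaled) centroid when unclipped
  set.seed(3)
  pts <- data.frame(x = runif(20, 1000, 2000), y = runif(20, 1000, 2000))
  bb <- centroids_to_boxes(pts, 32, level = 1, from_level = 0)
  expect_equal((bb$x_min + bb$x_max) / 2, pts$x / 2)
  expect_equal((bb$y_min + bb$y_max) / 2, pts$y / 2)
})

test_that("pyramid level rescaling divides by powers of two", {
  expect_equal(rescale_point(4096, 2560, 0, 1), list(x = 2048, y = 1280))
  expect_equal(rescale_point(123, 45, 1, 1), list(x = 123, y = 45))
  expect_equal(rescale_point(10, 10, 1, 0), list(x = 20, y = 20))
  expect_error(rescale_point(1, 1, -1, 0), ">= 0")
})
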