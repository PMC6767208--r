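test_that("domain types enforce their invariants", {
  expect_error(step_boxes(5, 5), "start < end")
  expect_error(step_boxes(-1, 5), "start < end")
  expect_error(event_annotation("walk_single", "staff", n_persons = 2),
               "n_persons = 1")
  expect_error(event_annotation("walk_multi", "staff", n_persons = 1),
               "n_persons > 1")
  expect_error(recording(matrix(0, 2, 10), rate_hz = -1), "positive")
  # boxes must fit within the signal
  expect_error(recording(matrix(0, 1, 10), id = "x",
                         annotation = event_annotation(
                           "walk_single", "staff",
                           step_boxes = step_boxes(0L, 20L))),
               "within")
  expect_silent(event_annotation("wheelchair", "elderly"))
})

test_that("recording files round-trip through write/read", {
  dir <- withr::local_tempdir()
  # identity case: zero matrix
  rz <- recording(matrix(0, 2, 3), id = "zero")
  p <- file.path(dir, "zero.csv")
  suppressWarnings(write_recording(rz, p))
  rt <- suppressWarnings(read_recording(p))
  expect_equal(rt$channels, matrix(0, 2, 3))

  # randomised round-trip, annotation included
  for (seed in 1:5) {
    r <- make_recording(K = 4L, T_len = 157L, seed = seed)
    p <- file.path(dir, sprintf("r%d.csv", seed))
    write_recording(r, p)
    r2 <- read_recording(p)
    expect_equal(r2$channels, r$channels)
    expect_equal(r2$rate_hz, r$rate_hz)
    expect_equal(r2$annotation$event_class, r$annotation$event_class)
    expect_equal(unclass(r2$annotation$step_boxes),
                 unclass(r$annotation$step_boxes),
                 ignore_attr = TRUE)
  }
})

test_that("sidecar JSON lists every step box, and an empty list explicitly", {
  dir <- withr::local_tempdir()
  r <- make_recording(seed = 3,
                      boxes = step_boxes(c(0L, 50L, 120L), c(30L, 80L, 150L)))
  write_recording(r, file.path(dir, "a.csv"))
  j <- jsonlite::fromJSON(file.path(dir, "a.json"),
                          simplifyVector = FALSE)
  expect_length(j$step_boxes, 3L)
  expect_equal(unlist(j$step_boxes[[1]]), c(0L, 30L))

  r0 <- make_recording(seed = 4, boxes = step_boxes())
  write_recording(r0, file.path(dir, "b.csv"))
  j0 <- jsonlite::fromJSON(file.path(dir, "b.json"), simplifyVector = FALSE)
  expect_true("step_boxes" %in% names(j0))
  expect_length(j0$step_boxes, 0L)
})

test_that("malformed files are rejected with the offending line", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")
  writeLines(c("# rate_hz=100", "# channels=2", "0.1,0.2", "0.3"), p)
  expect_error(suppressWarnings(read_recording(p)), "line 4")
  writeLines(c("no header", "# channels=2", "0.1,0.2"), p)
  expect_error(read_recording(p), "header")
  # missing sidecar is a warning, not an error
  writeLines(c("# rate_hz=100", "# channels=1", "0.5", "0.25"), p)
  expect_warning(read_recording(p), "sidecar")
})

test_that("stratified split rounds per stratum and partitions the data", {
  # single stratum of 40: round(40 * 0.3) = 12
  ds40 <- make_dataset(list(walk_single.staff = 40L))
  sp <- stratified_split(ds40, 0.3, seed = 1)
  expect_equal(length(sp$test), 12L)
  expect_equal(length(sp$train), 28L)

  # the six-stratum composition 40/8/7 staff, 18/3/17 elderly -> 12/2/2/5/1/5
  comp <- list(walk_single.staff = 40L, walk_multi.staff = 8L,
               other.staff = 7L, walk_single.elderly = 18L,
               walk_multi.elderly = 3L, wheelchair.elderly = 17L)
  ds <- make_dataset(comp)
  sp <- stratified_split(ds, 0.3, seed = 2)
  count_stratum <- function(d) {
    ec <- vapply(d$recordings, function(r) r$annotation$event_class, "")
    ps <- vapply(d$recordings, function(r) r$annotation$person_status, "")
    table(paste(floorgait:::activity_label(ec), ps, sep = "."))
  }
  ct <- count_stratum(sp$test)
  expect_equal(as.integer(ct[c("single.staff", "multi.staff", "other.staff",
                               "single.elderly", "multi.elderly",
                               "other.elderly")]),
               c(12L, 2L, 2L, 5L, 1L, 5L))

  # partition: disjoint union equals the input
  ids <- function(d) sort(vapply(d$recordings, function(r) r$id, ""))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_equal(sort(c(ids(sp$train), ids(sp$test))), ids(ds))

  # seeded determinism
  sp2 <- stratified_split(ds, 0.3, seed = 2)
  expect_identical(ids(sp2$test), ids(sp$test))
  # a different seed gives a different partition (with high probability)
  sp3 <- stratified_split(ds, 0.3, seed = 3)
  expect_false(identical(ids(sp3$test), ids(sp$test)))

  expect_error(stratified_split(ds, 1.2), "test_fraction")
})

test_that("manifest counts match the actual composition", {
  ds <- make_dataset(list(walk_single.staff = 3L, wheelchair.elderly = 2L))
  m <- dataset_manifest(ds)
  expect_equal(sum(m$count), 5L)
  expect_equal(m$count[m$event_class == "walk_single"], 3L)
  expect_equal(m$count[m$event_class == "wheelchair"], 2L)
})
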