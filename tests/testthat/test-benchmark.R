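# Institute ranking, paired scanner comparison and temporal monitoring.

fake_records <- function(n, institutes, seed = 1, scanner = "S1",
                         dates = "2020-06-01") {
  set.seed(seed)
  vals <- pmax(0, rnorm(n, 6, 3))
  data.frame(slide_id = paste0("sl", seq_len(n)),
             institute_id = rep_len(institutes, n),
             scanner_id = rep_len(scanner, n),
             date = rep_len(dates, n),
             fold_pct = vals / 5, dark_spot_foreign_pct = vals / 5,
             pen_marking_pct = vals / 5, air_bubble_edge_pct = vals / 5,
             out_of_focus_pct = vals / 5,
             artifact_free_pct = 100 - vals, any_artifact_pct = vals,
             tissue_area_mm2 = 50)
}

# sort-and-scan oracle for box-plot statistics
oracle_stats <- function(x) {
  x <- sort(x)
  n <- length(x)
  qat <- function(p) {            # type-7 linear interpolation
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  q1 <- qat(0.25); q3 <- qat(0.75); iqr <- q3 - q1
  wl <- NA; wh <- NA; out <- numeric(0)
  for (v in x) {
    if (v >= q1 - 1.5 * iqr && v <= q3 + 1.5 * iqr) {
      if (is.na(wl)) wl <- v
      wh <- v
    } else out <- c(out, v)
  }
  list(q1 = q1, q3 = q3, med = qat(0.5), wl = wl, wh = wh, out = out)
}

test_that("group statistics agree with a sort-and-scan oracle", {
  set.seed(71)
  for (i in 1:5) {
    x <- c(rnorm(46, 5, 2), rnorm(4, 25, 5))   # with genuine outliers
    st <- slideqc:::group_stats(x, "g")
    or <- oracle_stats(x)
    expect_equal(st$q1, or$q1)
    expect_equal(st$q3, or$q3)
    expect_equal(st$median, or$med)
    expect_equal(st$whisker_low, or$wl)
    expect_equal(st$whisker_high, or$wh)
    expect_equal(st$outliers, sort(or$out))
    expect_true(all(st$outliers < st$whisker_low | st$outliers > st$whisker_high))
  }
})

test_that("institutes are ranked ascending by mean artifact burden", {
  rec <- rbind(fake_records(30, "P1", seed = 1), fake_records(30, "P2", seed = 2),
               fake_records(30, "P3", seed = 3))
  rec$any_artifact_pct <- rec$any_artifact_pct +
    c(P1 = 5, P2 = 1, P3 = 3)[rec$institute_id]
  st <- institute_stats(rec, "any_artifact")
  expect_equal(nrow(st), 3)
  expect_true(!is.unsorted(st$mean))
  # simple three-slide institute
  one <- fake_records(3, "P9")
  one$any_artifact_pct <- c(1, 2, 3)
  st1 <- institute_stats(one)
  expect_equal(st1$mean, 2)
  expect_equal(st1$median, 2)
  # benchline is the overall mean
  expect_equal(attr(st, "benchline"), mean(rec$any_artifact_pct))
  # ranking is stable under duplicating a whole institute's records
  st2 <- institute_stats(rbind(rec, rec[rec$institute_id == "P2", ]))
  expect_equal(st2$group, st$group)
})

test_that("scanner comparison matches the closed-form paired t interval", {
  a <- fake_records(5, "P1", seed = 4, scanner = "A")
  b <- a; b$scanner_id <- "B"
  b$any_artifact_pct <- a$any_artifact_pct + c(1.2, -0.4, 2.5, 0.9, 0.3)
  cmp <- scanner_compare(rbind(a, b))
  d <- b$any_artifact_pct - a$any_artifact_pct
  tt <- t.test(b$any_artifact_pct, a$any_artifact_pct, paired = TRUE)
  expect_equal(cmp$mean_diff, mean(d))
  expect_equal(cmp$ci, as.numeric(tt$conf.int), tolerance = 1e-12)
  # antisymmetry under swapping scanners
  swapped <- scanner_compare(rbind(a, b), scanners = c("B", "A"))
  expect_equal(swapped$mean_diff, -cmp$mean_diff)
  expect_equal(swapped$ci, -rev(cmp$ci))
})

test_that("degenerate scanner pairs give degenerate intervals and errors", {
  a <- fake_records(6, "P1", seed = 5, scanner = "A")
  b <- a; b$scanner_id <- "B"
  same <- scanner_compare(rbind(a, b))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$ci, c(0, 0))
  # constant +2 offset: zero variance, interval collapses on 2
  b2 <- b; b2$any_artifact_pct <- a$any_artifact_pct + 2
  off <- scanner_compare(rbind(a, b2))
  expect_equal(off$mean_diff, 2)
  expect_equal(off$ci, c(2, 2))
  # unpaired slides are an error
  expect_error(scanner_compare(rbind(a, b[-1, ])),
               class = "slideqc_pairing_error")
})

test_that("temporal grouping partitions records chronologically", {
  rec <- fake_records(40, "P1", seed = 6,
                      dates = sprintf("20%02d-03-15", rep(10:13, each = 10)))
  st <- temporal_stats(rec, "year")
  expect_equal(st$group, c("2010", "2011", "2012", "2013"))
  expect_equal(sum(st$n), 40)
  oracle <- tapply(rec$any_artifact_pct, substr(rec$date, 1, 4), mean)
  expect_equal(st$mean, as.numeric(oracle[st$group]))
  # one period only
  st1 <- temporal_stats(fake_records(7, "P1", dates = "2021-01-05"), "year")
  expect_equal(nrow(st1), 1)
  # bad dates are dropped with a message
  bad <- fake_records(4, "P1")
  bad$date[2] <- "not-a-date"
  expect_message(st2 <- temporal_stats(bad, "year"), "dropped")
  expect_equal(sum(st2$n), 3)
})

test_that("per-class mean percentages conserve within groups", {
  rec <- rbind(fake_records(20, "P1", seed = 7), fake_records(20, "P2", seed = 8))
  for (inst in c("P1", "P2")) {
    sub <- rec[rec$institute_id == inst, ]
    cls <- c("fold_pct", "dark_spot_foreign_pct", "pen_marking_pct",
             "air_bubble_edge_pct", "out_of_focus_pct")
    total <- sum(vapply(cls, function(c) mean(sub[[c]]), 0)) + mean(sub$artifact_free_pct)
    expect_equal(total, 100, tolerance = 0.05)
  }
})

test_that("benchmark reports write CSV, JSON and figures that re-read cleanly", {
  rec <- rbind(fake_records(25, "P1", seed = 9), fake_records(25, "P2", seed = 10))
  st <- institute_stats(rec)
  dir <- tempfile()
  files <- write_report(list(institutes = st), dir)
  expect_true(file.exists(file.path(dir, "institutes.csv")))
  expect_true(file.exists(file.path(dir, "institutes.json")))
  expect_true(any(file.exists(file.path(dir, c("institutes.png", "institutes.pdf")))))
  back <- utils::read.csv(file.path(dir, "institutes.csv"))
  for (col in c("mean", "median", "q1", "q3", "whisker_low", "whisker_high"))
    expect_equal(back[[col]], st[[col]], tolerance = 1e-9)
})

test_that("records built from summaries round-trip through CSV", {
  masks <- lapply(81:83, function(s) random_mask(16, 16, seed = s, mpp = 2))
  sums <- lapply(seq_along(masks), function(i)
    slide_summary(masks[[i]], paste0("sl", i)))
  rec <- records_from_summaries(sums, "P1", "S1", "2022-05-01")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$any_artifact_pct,
               vapply(sums, `[[`, 0, "any_artifact_pct"))
  path <- tempfile(fileext = ".csv")
  write_records(rec, path)
  back <- read_records(path)
  expect_equal(back$any_artifact_pct, rec$any_artifact_pct, tolerance = 1e-9)
})
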