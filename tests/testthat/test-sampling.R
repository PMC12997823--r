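# Use-availability sampling design: availability arithmetic, random point
# draws, and the landscape / home-range / hourly table constructions.

fake_track <- function(id, n_fix, xmin = 0, size = 1000) {
  ts <- as.POSIXct("2016-06-01 00:00", tz = "UTC") + 3600 * (seq_len(n_fix) - 1)
  set.seed(nchar(id) + n_fix)
  structure(list(individual_id = id,
                 relocations = data.frame(timestamp = ts,
                                          x = runif(n_fix, xmin, xmin + size),
                                          y = runif(n_fix, 0, size)),
                 mcp = rect_polygon(xmin, 0, xmin + size, size),
                 area_id = "core"),
            class = "track")
}

test_that("availability count is ten times the mean hourly relocation count", {
  expect_equal(availability_count(211767), 88236)  # 10 x 8823.6, rounded
  expect_equal(availability_count(24), 10)
  expect_equal(availability_count(0), 0)
})

test_that("available draws are seeded and proportional to relocation effort", {
  region <- rect_polygon(0, 0, 5000, 5000)
  a <- draw_available(region = region, n = 500, seed = 9)
  b <- draw_available(region = region, n = 500, seed = 9)
  expect_identical(a, b)
  expect_true(all(point_in_polygon(region, a$x, a$y)))

  tracks <- structure(list(fake_track("A", 100), fake_track("B", 300, 2000)),
                      class = "track_list")
  pts <- draw_available(tracks = tracks, n = 40, seed = 2)
  expect_equal(as.vector(table(pts$individual_id)[c("A", "B")]), c(10L, 30L))
  eq <- draw_available(tracks = tracks, n = 40, seed = 2,
                       proportional_by_individual = FALSE)
  expect_equal(as.vector(table(eq$individual_id)[c("A", "B")]), c(20L, 20L))
})

test_that("regional draws are uniform (quadrat chi-square across seeds)", {
  region <- rect_polygon(0, 0, 4000, 4000)
  rejected <- 0L
  for (s in 1:200) {
    p <- draw_available(region = region, n = 400, seed = s)
    counts <- table(factor(floor(p$x / 1000), levels = 0:3),
                    factor(floor(p$y / 1000), levels = 0:3))
    if (suppressWarnings(chisq.test(as.vector(counts))$p.value) < 0.01)
      rejected <- rejected + 1L
  }
  expect_lte(rejected, 10L)  # nominal 1% rate, 5% bound
})

test_that("nodata-background points are dropped and counted, not resampled", {
  g <- cov_grid(matrix(c(NA, 1, 1, 1), 2, 2), c(0, 0), 2000, "WC")
  region <- rect_polygon(0, 0, 4000, 4000)
  pts <- draw_available(region = region, n = 400, seed = 1,
                        grids = list(WC = g))
  expect_gt(attr(pts, "n_dropped"), 0)
  expect_equal(nrow(pts) + attr(pts, "n_dropped"), 400)
  expect_false(any(pts$x < 2000 & pts$y < 2000))  # the nodata quadrant (SW)
})

test_that("landscape table uses a 10% MCP subsample against all region points", {
  pts <- fix_points()
  lt <- fix_tables()$landscape
  expect_equal(sum(lt$response == 0) + attr(lt, "n_dropped"),
               nrow(pts$region))
  expect_equal(sum(lt$response == 1), round(nrow(pts$mcp) * 0.1))
  expect_equal(levels(lt$in_out), c("inside", "outside"))
  # covariates equal a direct grid lookup at the point (extraction identity)
  stack <- covariate_stack(fix_bundle(), "mean")
  mp_used <- pts$mcp[seq_len(5), ]
  e <- extract_covariates(fix_bundle(), mp_used$x, mp_used$y, "mean")
  for (cv in names(stack))
    expect_equal(e[[cv]], grid_lookup(stack[[cv]], mp_used$x, mp_used$y))
})

test_that("home-range table subsamples 1/24th of relocations with matched metadata", {
  tb <- fix_tables()
  ht <- tb$homerange
  tr <- fix_tracks()
  n_reloc <- sum(vapply(tr, function(t) nrow(t$relocations), 0L))
  expect_equal(sum(ht$response == 1), round(n_reloc / 24))
  # 211,767 relocations would give 8,824 used rows under the same rule
  expect_equal(round(211767 / 24), 8824)
  expect_true(all(ht$season %in% c("short_dry", "long_rain", "long_dry",
                                   "short_rain")))
  expect_true(all(ht$moon_pct >= 0 & ht$moon_pct <= 100))
  expect_true(all(ht$hour %in% 0:23))
})

test_that("used-row season and year derive from the relocation timestamps", {
  tr <- fix_tracks(); tb <- fix_tables()
  reloc <- do.call(rbind, lapply(tr, function(t)
    data.frame(individual_id = t$individual_id, t$relocations)))
  ht <- tb$homerange
  used <- ht[ht$response == 1, ]
  # used rows are a subsample of relocations, so per-individual counts are
  # bounded by the tracking effort and years lie in the deployment window
  cnt_u <- table(used$individual_id)
  cnt_r <- table(reloc$individual_id)
  expect_true(all(cnt_u <= cnt_r[names(cnt_u)]))
  yrs <- unique(used$year)
  expect_true(all(yrs %in% 2016:2018))
})

test_that("hourly tables partition the relocations and share the available set", {
  tr <- fix_tracks(); pts <- fix_points(); tb <- fix_tables()
  hs <- build_hourly_tables(pts$mcp, tr, fix_bundle(), tb$moon, seed = 15)
  expect_length(hs, 24L)
  n_reloc <- sum(vapply(tr, function(t) nrow(t$relocations), 0L))
  used_counts <- vapply(hs, function(h) sum(h$response == 1), 0L)
  expect_equal(sum(used_counts), n_reloc)  # exhaustive partition
  for (h in 0:23)
    expect_true(all(hs[[h + 1]]$hour == h))
  # available rows identical in every table (same points, same count)
  av_n <- vapply(hs, function(h) sum(h$response == 0), 0L)
  expect_equal(length(unique(av_n)), 1L)
  av1 <- hs[[1]][hs[[1]]$response == 0, c("WC", "TRI")]
  av2 <- hs[[13]][hs[[13]]$response == 0, c("WC", "TRI")]
  expect_equal(av1$TRI, av2$TRI)
})

test_that("a 13:59 local-time fix lands in the h = 13 table (floor convention)", {
  # 10:59 UTC is 13:59 local (UTC+3)
  tr <- fix_tracks()
  ts <- as.POSIXct("2016-06-10 10:59:00", tz = "UTC")
  expect_equal(rsfscales:::local_hour(ts), 13L)
})

test_that("an hour without relocations aborts naming the hour", {
  t1 <- fake_track("A", 30)  # 30 hourly fixes cover hours 0..5 twice at most
  short <- structure(list(t1), class = "track_list")
  short[[1]]$relocations <- short[[1]]$relocations[1:5, ]
  pts <- data.frame(x = runif(50, 0, 1000), y = runif(50, 0, 1000),
                    individual_id = "A")
  moon <- moon_series_synthetic("2016-05-01", "2016-07-01")
  expect_error(build_hourly_tables(pts, short, fix_bundle(), moon),
               "no relocations for hour")
})

test_that("use-availability tables round-trip as CSV with a manifest", {
  lt <- fix_tables()$landscape
  f <- tempfile(fileext = ".csv")
  write_useavail_csv(lt, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(lt))
  man <- jsonlite::read_json(paste0(f, ".manifest.json"))
  expect_equal(man$n_used, sum(lt$response == 1))
  expect_equal(man$n_available, sum(lt$response == 0))
})
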