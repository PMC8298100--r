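# Migration statistics: closed-form track fixtures, lag statistics,
# invariances, superplot summaries, and the Fiji reader dialect.

zigzag_track <- function(n_steps = 8, step = 1, dt = 1) {
  # alternating east / north unit steps: perfect +/- 90 degree zigzag
  dx <- rep(c(step, 0), length.out = n_steps)
  dy <- rep(c(0, step), length.out = n_steps)
  data.frame(t = seq(0, by = dt, length.out = n_steps + 1),
             x = c(0, cumsum(dx)), y = c(0, cumsum(dy)))
}

l_track <- function() {
  # 3 um east then 4 um north, 1 um per 1-min step
  data.frame(t = 0:7, x = c(0, 1, 2, 3, 3, 3, 3, 3), y = c(0, 0, 0, 0, 1, 2, 3, 4))
}

test_that("speed and distance closed forms", {
  tr <- straight_track(v = 0.4, n_steps = 10)
  expect_equal(average_speed(tr), 0.4)
  expect_equal(instantaneous_speed(tr)$speed, rep(0.4, 10))
  # 3-4-5 triangle: one step of 5 um in 1 min
  tr2 <- data.frame(t = c(0, 1), x = c(0, 3), y = c(0, 4))
  expect_equal(instantaneous_speed(tr2)$speed, 5)
  # stationary cell
  tr3 <- data.frame(t = 0:3, x = rep(1, 4), y = rep(2, 4))
  expect_true(all(instantaneous_speed(tr3)$speed == 0))
  # cumulative distance on the hand track (0,0) -> (3,4) -> (6,8)
  tr4 <- data.frame(t = 0:2, x = c(0, 3, 6), y = c(0, 4, 8))
  expect_equal(cumulative_distance(tr4)$distance, c(0, 5, 10))
  expect_equal(average_speed(tr4), 5)
  # back-and-forth: path length, not displacement
  tr5 <- data.frame(t = 0:4, x = c(0, 1, 0, 1, 0), y = 0)
  expect_equal(cumulative_distance(tr5)$distance[5], 4)
  expect_error(average_speed(data.frame(t = c(0, 0), x = c(0, 1), y = c(0, 0))),
               "timestamps")
})

test_that("directionality ratio series", {
  expect_true(all(directionality_ratio(straight_track())$ratio[-1] == 1))
  # out-and-back: final value 0
  back <- data.frame(t = 0:2, x = c(0, 1, 0), y = 0)
  dr <- directionality_ratio(back)$ratio
  expect_equal(dr[3], 0)
  # L-track: final 5/7
  dr <- directionality_ratio(l_track())$ratio
  expect_equal(dr[8], 5 / 7)
  # zero-path entries are NA-flagged
  still <- data.frame(t = 0:2, x = c(0, 0, 1), y = 0)
  expect_true(is.na(directionality_ratio(still)$ratio[2]))
})

test_that("MSD: ballistic closed form, lag-1 consistency, step-law slope", {
  v <- 0.7; dt <- 2
  tr <- straight_track(v = v, dt = dt, n_steps = 12)
  tr$cell_id <- "c1"
  m <- msd(tr)
  expect_equal(m$msd, (v * m$lag)^2)
  expect_true(all(m$lag <= 0.5 * 12 * dt))
  # msd at one step equals the mean squared step length (any track)
  zz <- zigzag_track(); zz$cell_id <- "z"
  m1 <- msd(zz)$msd[1]
  expect_equal(m1, mean(diff(zz$x)^2 + diff(zz$y)^2))

  # Brownian cohort: linear MSD with slope 4D within 10%
  set.seed(61)
  d_true <- 0.3; dt <- 1; n <- 40
  cohort <- do.call(rbind, lapply(1:200, function(i) {
    data.frame(cell_id = sprintf("c%03d", i), t = 0:n,
               x = c(0, cumsum(rnorm(n, 0, sqrt(2 * d_true * dt)))),
               y = c(0, cumsum(rnorm(n, 0, sqrt(2 * d_true * dt)))))
  }))
  m <- msd(cohort)
  fit <- coef(lm(m$msd ~ m$lag, weights = m$n_cells))
  expect_equal(unname(fit[2]), 4 * d_true, tolerance = 0.1)
})

test_that("direction autocorrelation: straight, zigzag, PRW decay", {
  tr <- straight_track(n_steps = 10); tr$cell_id <- "c"
  d <- direction_autocorrelation(tr)
  expect_true(all(abs(d$dacf - 1) < 1e-12))
  zz <- zigzag_track(n_steps = 10); zz$cell_id <- "z"
  d <- direction_autocorrelation(zz)
  expect_equal(d$dacf[d$lag == 0], 1)
  expect_equal(d$dacf[d$lag == 1], 0)
  expect_equal(d$dacf[d$lag == 2], 1)

  # PRW: exponential decay with rate ~ 1/persistence_time
  p_true <- 30
  cohort <- simulate_tracks(n_cells = 200, persistence_time = p_true,
                            frame_interval = 5, duration = 250,
                            speed_sd_between_cells = 0, seed = 71)
  d <- direction_autocorrelation(cohort)
  d <- d[d$lag > 0 & d$dacf > 0.05, ]
  fit <- coef(lm(log(d$dacf) ~ 0 + d$lag))
  expect_equal(unname(-1 / fit), p_true, tolerance = 0.2)
})

test_that("turning angles: straight, square path, uniformity", {
  tr <- straight_track(n_steps = 6); tr$cell_id <- "c"
  expect_true(all(turning_angles(tr) == 0))
  # counterclockwise unit square: all turns +pi/2
  sq <- data.frame(cell_id = "s", t = 0:4,
                   x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  expect_equal(turning_angles(sq), rep(pi / 2, 3))
  # isotropic random walk: angles uniform on (-pi, pi]
  set.seed(81)
  n <- 10000
  rw <- data.frame(cell_id = "r", t = 0:n,
                   x = c(0, cumsum(rnorm(n))), y = c(0, cumsum(rnorm(n))))
  ang <- turning_angles(rw)
  h <- hist(ang, breaks = seq(-pi, pi, length.out = 13), plot = FALSE)
  gof <- chisq.test(h$counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("fastest segment time uses whole-step windows", {
  # straight at 1 um/min, 1-min sampling: 25 um takes 25 min
  expect_equal(fastest_segment_time(straight_track(v = 1, n_steps = 40)), 25)
  # v = 2: first window reaching >= 25 um is 13 steps
  expect_equal(fastest_segment_time(straight_track(v = 2, n_steps = 40)), 13)
  # total path below the segment: undefined (NA)
  expect_true(is.na(fastest_segment_time(straight_track(v = 1, n_steps = 10))))
  # speeding up mid-track: the fast stretch wins
  spd <- c(rep(1, 20), rep(5, 10))
  tr <- data.frame(t = 0:30, x = c(0, cumsum(spd)), y = 0)
  expect_equal(fastest_segment_time(tr, 25), 5)
})

test_that("statistics are invariant under rigid motion; turning angles flip under reflection", {
  cohort <- simulate_tracks(n_cells = 8, duration = 200, frame_interval = 10,
                            persistence_time = 30, seed = 91)
  th <- 0.83; shift <- c(12, -7)
  rot <- cohort
  rot$x <- cohort$x * cos(th) - cohort$y * sin(th) + shift[1]
  rot$y <- cohort$x * sin(th) + cohort$y * cos(th) + shift[2]
  s0 <- track_stats(cohort); s1 <- track_stats(rot)
  expect_equal(s1$average_speed, s0$average_speed)
  expect_equal(s1$directionality, s0$directionality)
  expect_equal(s1$fastest_segment_time, s0$fastest_segment_time)
  expect_equal(msd(rot)$msd, msd(cohort)$msd)
  expect_equal(direction_autocorrelation(rot)$dacf,
               direction_autocorrelation(cohort)$dacf)
  expect_equal(turning_angles(rot), turning_angles(cohort))
  refl <- cohort; refl$y <- -refl$y
  expect_equal(turning_angles(refl), -turning_angles(cohort))
  # path length >= net displacement on every track (triangle inequality)
  st <- track_stats(cohort)
  expect_true(all(st$directionality <= 1 + 1e-12))
})

test_that("superplot summary tests on experiment means", {
  # identical experiment means: difference 0, p = 1
  d <- data.frame(condition = rep(c("a", "b"), each = 4),
                  experiment_id = rep(c("e1", "e2"), 4),
                  speed = rep(c(1, 2), 4))
  sp <- superplot_summary(d, "speed")
  expect_equal(sp$test$difference, 0)
  expect_equal(sp$test$p, 1)
  # planted effect direction recovered (0.40 vs 0.32 um/min cohorts)
  set.seed(101)
  mk <- function(cond, mu) do.call(rbind, lapply(1:4, function(e)
    data.frame(condition = cond, experiment_id = sprintf("%s_e%d", cond, e),
               speed = rnorm(20, mu, 0.02))))
  d2 <- rbind(mk("siCtrl", 0.40), mk("siTPD54", 0.32))
  sp2 <- superplot_summary(d2, "speed")
  expect_gt(sp2$test$difference, 0)
  expect_lt(sp2$test$p, 0.05)
  # single experiment per condition: df = 0 error
  d3 <- data.frame(condition = c("a", "a", "b", "b"),
                   experiment_id = c("e1", "e1", "e2", "e2"), speed = 1:4)
  expect_error(superplot_summary(d3, "speed"), "experiments")
  # >2 conditions delegates to Dunnett and needs a control
  d4 <- rbind(mk("ctrl", 0.4), mk("kd1", 0.32), mk("kd2", 0.40))
  expect_error(superplot_summary(d4, "speed"), "control")
  sp4 <- superplot_summary(d4, "speed", control = "ctrl")
  expect_lt(sp4$test$p[["kd1"]], 0.05)
  expect_gt(sp4$test$p[["kd2"]], 0.05)
})

test_that("permuted condition labels give a null p distribution", {
  set.seed(111)
  base <- do.call(rbind, lapply(1:6, function(e)
    data.frame(experiment_id = sprintf("e%d", e), speed = rnorm(10, 0.4, 0.05))))
  ps <- replicate(40, {
    base$condition <- sample(rep(c("a", "b"), length.out = 6))[
      as.integer(factor(base$experiment_id))]
    superplot_summary(base, "speed")$test$p
  })
  expect_lt(mean(ps < 0.05), 0.25)        # close to the nominal 5%
  expect_gt(mean(ps < 0.5), 0.2)          # p spread over (0, 1), not stuck
  expect_lt(mean(ps < 0.5), 0.8)
})

test_that("Fiji Manual Tracking dialect and tidy round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(" ,Track n°,Slice n°,X,Y,Distance,Velocity,Pixel Value",
               "1,1,1,10,20,0,0,100",
               "2,1,2,13,24,5,5,100",
               "3,2,1,50,60,0,0,90",
               "4,2,2,50,61,1,1,90"), path)
  tr <- read_tracks(path, pixel_size = 0.5, frame_interval = 10)
  expect_equal(sort(unique(tr$cell_id)), c("track1", "track2"))
  t1 <- tr[tr$cell_id == "track1", ]
  expect_equal(t1$t, c(0, 10))
  expect_equal(t1$x, c(5, 6.5))  # pixels scaled to um
  expect_equal(average_speed(t1), sqrt(1.5^2 + 2^2) / 10)
  # tidy round-trip
  cohort <- simulate_tracks(n_cells = 3, duration = 60, seed = 5)
  out <- withr::local_tempfile(fileext = ".csv")
  write_tracks(cohort, out)
  back <- read_tracks(out)
  expect_equal(back$x, cohort$x, tolerance = 1e-9)
  expect_equal(back$cell_id, cohort$cell_id)
})
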