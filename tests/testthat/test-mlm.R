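test_that("association model pins the deterministic limits", {
  set.seed(3)
  d <- simulate_paired_assoc(40, 6, beta = 0.6)
  same <- d
  same$diary <- same$keyboard
  # outcome == predictor is numerically extreme for the optimizer; only the
  # estimates matter here
  res <- suppressWarnings(suppressMessages(fit_association(same)))
  expect_equal(res$beta_std, 1, tolerance = 1e-6)
  expect_gt(res$r2_marginal, 0.999)

  indep <- d
  indep$diary <- rnorm(nrow(d))
  res0 <- fit_association(indep)
  expect_lt(abs(res0$beta_std), 0.15)
  expect_true(res0$beta$ci_lo < 0 && res0$beta$ci_hi > 0)
})

test_that("standardized beta equals the raw slope times sd(x)/sd(y)", {
  set.seed(5)
  d <- simulate_paired_assoc(50, 6, beta = 0.7)
  d$keyboard <- d$keyboard * 3 + 10   # put the predictor on another scale
  d$diary <- d$diary * 0.5 - 2
  res <- fit_association(d)
  raw <- lmerTest::lmer(diary ~ keyboard + (1 | participant_id), data = d)
  raw_slope <- unname(lme4::fixef(raw)["keyboard"])
  expect_equal(res$beta_std,
               raw_slope * sd(d$keyboard) / sd(d$diary), tolerance = 1e-6)
})

test_that("cluster-mean centering decomposes exactly and shrinks sensibly", {
  set.seed(8)
  g <- rep(sprintf("S%02d", 1:30), each = 50)
  x <- rep(rnorm(30, 0, 1), each = 50) + rnorm(1500)
  cp <- center_predictor(x, g)
  # conservation: person mean + centered reconstructs the observation
  expect_equal(cp$person_mean + cp$centered, x, tolerance = 1e-12)
  # with many nights per person, EB means approach raw means
  raw_means <- tapply(x, g, mean)
  eb_means <- tapply(cp$person_mean, g, unique)
  expect_equal(unname(eb_means), unname(raw_means), tolerance = 0.05)
  # zero between-variance: full shrinkage to the grand intercept
  x0 <- rnorm(300)
  g0 <- rep(sprintf("S%02d", 1:30), each = 10)
  cp0 <- center_predictor(x0, g0)
  expect_lt(diff(range(cp0$person_mean)), 0.05)
})

test_that("day-level moderation recovers a generated hours-dependent slope", {
  set.seed(12)
  n <- 150; nights <- 7
  id <- rep(sprintf("S%03d", 1:n), each = nights)
  hrs <- pmax(0, pmin(24, round(rnorm(n * nights, 12, 4))))
  hrs_c <- (hrs - mean(hrs)) / sd(hrs)
  w <- rnorm(n * nights, 0, sqrt(0.7))
  x <- rep(rnorm(n, 0, sqrt(0.3)), each = nights) + w
  y <- (0.5 + 0.25 * hrs_c) * w + rep(rnorm(n, 0, 0.4), each = nights) +
    rnorm(n * nights, 0, 0.5)
  d <- data.frame(participant_id = id,
                  anchor_date = as.Date("2020-09-14") + seq_len(nights) - 1,
                  keyboard = x, diary = y, diff_h = x - y,
                  type_of_day = factor(
                    sample(c("weekday", "weekend"), n * nights, TRUE, c(5, 2)),
                    levels = c("weekday", "weekend")),
                  hours_prev_day = hrs, hours_next_day = hrs)
  res <- fit_first_level_moderation(d, hours_side = "prev")
  co <- res$coefficients
  inter <- co[co$term == "kb_cmc:hours_cmc", ]
  expect_gt(inter$estimate, 0)
  expect_lt(inter$p, 0.01)
  # type of day does not moderate in this generator
  tod <- co[co$term == "kb_cmc:type_of_dayweekend", ]
  expect_gt(tod$p, 0.01)
})

test_that("random-slope model detects and bounds slope variation", {
  set.seed(17)
  d <- simulate_paired_assoc(100, 7, beta = 0.7, slope_sd = 0.4)
  rs <- fit_random_slope(d)
  expect_equal(rs$slope_sd, 0.4, tolerance = 0.3)
  expect_lt(rs$lrt_p, 0.001)
  expect_equal(rs$lrt_df, 2L)
  # common slope: near-zero slope SD, LRT not significant
  d0 <- simulate_paired_assoc(60, 7, beta = 0.7, slope_sd = 0)
  rs0 <- fit_random_slope(d0)
  expect_lt(rs0$slope_sd, 0.12)
  expect_gt(rs0$lrt_p, 0.01)
})

test_that("cross-level model recovers trait moderation and screens collinearity", {
  set.seed(22)
  n <- 120; nights <- 7
  id_u <- sprintf("S%03d", 1:n)
  psqi <- pmin(21, pmax(0, round(rnorm(n, 5, 2.3))))
  slope_i <- 0.8 - 0.05 * (psqi - mean(psqi)) + rnorm(n, 0, 0.1)
  id <- rep(id_u, each = nights)
  w <- rnorm(n * nights, 0, sqrt(0.7))
  x <- rep(rnorm(n, 0, sqrt(0.3)), each = nights) + w
  y <- rep(slope_i, each = nights) * w + rep(rnorm(n, 0, 0.4), each = nights) +
    rnorm(n * nights, 0, 0.5)
  d <- data.frame(participant_id = id,
                  anchor_date = as.Date("2020-09-14") + seq_len(nights) - 1,
                  keyboard = x, diary = y, diff_h = x - y,
                  type_of_day = factor("weekday", levels = c("weekday", "weekend")),
                  hours_prev_day = NA_integer_, hours_next_day = NA_integer_)
  traits <- data.frame(participant_id = id_u, msfsc = rnorm(n, 4.8, 1),
                       psqi = psqi, tsc = rnorm(n, 3, 0.5))
  res <- fit_cross_level(d, traits)
  co <- res$coefficients
  px <- co[co$term == "kb_cmc:psqi_c", ]
  expect_lt(px$estimate, 0)
  expect_lt(px$p, 0.01)
  # independent traits stay null
  ms <- co[co$term == "kb_cmc:msfsc_c", ]
  expect_gt(ms$p, 0.01)
  expect_false(res$vif_flag)
  # a duplicated trait column trips the collinearity screen
  traits2 <- traits
  traits2$msfsc <- traits2$psqi
  w <- capture_warnings(res2 <- fit_cross_level(d, traits2))
  expect_true(any(grepl("VIF", w)))
  expect_true(res2$vif_flag)
})
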