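# Motion metrics: parameter-to-affine conventions, the RMS displacement
# metric against closed forms and a Monte-Carlo oracle, file parsing, and
# per-subject summaries with exclusion flags.

test_that("params_to_affine follows the translate-then-rotate convention", {
  expect_equal(params_to_affine(c(0, 0, 0), c(0, 0, 0)), diag(4))
  Tt <- params_to_affine(c(3, 0, 0), c(0, 0, 0))
  expect_equal(Tt[1:3, 1:3], diag(3))
  expect_equal(Tt[1:3, 4], c(3, 0, 0))
  # right-handed z rotation: +90 degrees maps x onto y
  Rz <- params_to_affine(c(0, 0, 0), c(0, 0, pi / 2))
  expect_equal(as.numeric(Rz[1:3, 1:3] %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  # rotation block orthonormal for random angles
  set.seed(1)
  for (i in 1:20) {
    A <- params_to_affine(rnorm(3), runif(3, -0.5, 0.5))[1:3, 1:3]
    expect_equal(crossprod(A), diag(3), tolerance = 1e-12)
  }
  # independent composition oracle: Rx %*% Ry %*% Rz built elementwise
  ang <- c(0.2, -0.3, 0.4)
  rot1 <- params_to_affine(c(0, 0, 0), ang)[1:3, 1:3]
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  expect_equal(rot1, rx %*% ry %*% rz, tolerance = 1e-14)
})

test_that("displacement metric matches closed forms", {
  I4 <- diag(4)
  expect_identical(jenkinson_displacement(I4, I4), 0)
  # pure translation: exactly the Euclidean norm
  T2 <- params_to_affine(c(3, 0, 0), c(0, 0, 0))
  expect_identical(jenkinson_displacement(I4, T2), 3)
  T3 <- params_to_affine(c(1, -2, 2), c(0, 0, 0))
  expect_equal(jenkinson_displacement(I4, T3), 3)
  # 2-degree rotation about z through the centre:
  # sqrt(R^2/5 * 4 (1 - cos 2deg)) with R = 80
  T4 <- params_to_affine(c(0, 0, 0), c(0, 0, 2 * pi / 180))
  expect_equal(jenkinson_displacement(I4, T4),
               sqrt(80^2 / 5 * 4 * (1 - cos(2 * pi / 180))),
               tolerance = 1e-12)
  expect_equal(jenkinson_displacement(I4, T4), 1.766, tolerance = 1e-3)
  expect_error(jenkinson_displacement(matrix(0, 4, 4), T4), "singular")
})

test_that("metric equals Monte-Carlo RMS displacement over the ball", {
  set.seed(42)
  n <- 1e5
  # uniform points in the radius-80 ball
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * 80 * runif(n)^(1 / 3)
  T1 <- params_to_affine(c(0.2, -0.1, 0.3), c(0.004, -0.01, 0.02))
  T2 <- params_to_affine(c(-0.3, 0.4, 0.1), c(-0.01, 0.005, -0.015))
  M <- T2 %*% solve(T1) - diag(4)
  disp <- u %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], n, 3, byrow = TRUE)
  rms <- sqrt(mean(rowSums(disp^2)))
  expect_equal(jenkinson_displacement(T1, T2), rms, tolerance = 0.01)
  # invariance to a consistent world-coordinate shift (the ball centre
  # moves with the coordinates)
  shift <- c(10, -20, 5)
  Sh <- diag(4); Sh[1:3, 4] <- shift
  expect_equal(
    jenkinson_displacement(Sh %*% T1, Sh %*% T2, center = shift),
    jenkinson_displacement(T1, T2, center = c(0, 0, 0)),
    tolerance = 1e-10)
})

test_that("framewise series composes consecutive-frame transforms", {
  expect_equal(framewise_series(zero_series(150)), rep(0, 149))
  # an isolated 3 mm spike enters and leaves: two nonzero entries of 3
  tr <- matrix(0, 20, 3); tr[10, 1] <- 3
  ser <- rigid_motion_series("s", tr, matrix(0, 20, 3))
  fw <- framewise_series(ser)
  expect_equal(which(fw > 0), c(9L, 10L))
  expect_equal(fw[c(9, 10)], c(3, 3))
  # constant drift gives stationary increments
  tr2 <- cbind(seq(0, by = 0.1, length.out = 50), 0, 0)
  ser2 <- rigid_motion_series("d", tr2, matrix(0, 50, 3))
  expect_equal(framewise_series(ser2), rep(0.1, 49))
  # reference mode accumulates the drift instead
  expect_equal(framewise_series(ser2, mode = "reference"),
               seq(0.1, 4.9, by = 0.1))
})

test_that("realignment files parse per dialect and round-trip", {
  spm <- tempfile(fileext = ".txt")
  writeLines(c("0 0 0 0 0 0", "3 0 0 0 0 0"), spm)
  ser <- read_realignment_series(spm, "spm")
  expect_equal(ser$translations[2, ], c(3, 0, 0))
  expect_equal(ser$rotations[2, ], c(0, 0, 0))
  # the same file as fsl puts 3 into the rotations and is implausible
  expect_warning(fsl <- read_realignment_series(spm, "fsl"),
                 "dialect|degrees")
  expect_equal(fsl$rotations[2, ], c(3, 0, 0))

  bad <- tempfile(fileext = ".txt")
  writeLines(c("0 0 0 0 0 0", "1 2 3"), bad)
  expect_error(read_realignment_series(bad, "spm"), "line 2")
  one <- tempfile(fileext = ".txt")
  writeLines("0 0 0 0 0 0", one)
  expect_error(read_realignment_series(one, "spm"), "2 frames")

  # round trip reproduces the summary bit-for-bit
  sim <- simulate_motion_params(seed = 5, subject_id = "rt")
  p1 <- tempfile(fileext = ".txt")
  write_realignment_series(sim, p1, "spm")
  back <- read_realignment_series(p1, "spm", subject_id = "rt")
  expect_identical(summarize_subject_motion(sim),
                   summarize_subject_motion(back))
  # and through the fsl dialect as well
  p2 <- tempfile(fileext = ".par")
  write_realignment_series(sim, p2, "fsl")
  back2 <- read_realignment_series(p2, "fsl", subject_id = "rt")
  expect_identical(summarize_subject_motion(sim),
                   summarize_subject_motion(back2))
})

test_that("gross-motion flag uses strict 3 mm / 2 degree thresholds", {
  tr <- matrix(0, 10, 3); rt <- matrix(0, 10, 3)
  expect_false(gross_motion_flag(rigid_motion_series("a", tr, rt)))
  tr2 <- tr; tr2[5, 2] <- 3.1
  expect_true(gross_motion_flag(rigid_motion_series("b", tr2, rt)))
  tr3 <- tr; tr3[5, 2] <- 3
  expect_false(gross_motion_flag(rigid_motion_series("c", tr3, rt)))
  rt2 <- rt; rt2[4, 1] <- 2 * pi / 180          # exactly 2 degrees
  expect_false(gross_motion_flag(rigid_motion_series("d", tr, rt2)))
  rt3 <- rt; rt3[4, 1] <- 2.05 * pi / 180
  expect_true(gross_motion_flag(rigid_motion_series("e", tr, rt3)))
})

test_that("subject summaries carry means, logs and independent flags", {
  tr <- cbind(seq(0, by = 0.05, length.out = 50), 0, 0)  # peaks below 3 mm
  ser <- rigid_motion_series("s", tr, matrix(0, 50, 3))
  sm <- summarize_subject_motion(ser)
  expect_equal(sm$mean_displacement_mm, 0.05)
  expect_equal(sm$log_displacement, log(0.05), tolerance = 1e-12)
  expect_false(sm$gross_motion)

  # cohort outlier flag: subject at 5.4 cohort sd from the mean
  set.seed(2)
  cohort <- rnorm(800, -2.59, 0.35)
  mu <- mean(cohort); s <- sd(cohort)
  out_val <- exp(mu + 5.4 * s)
  tr2 <- cbind(seq(0, by = out_val, length.out = 50), 0, 0)
  ser2 <- suppressWarnings(rigid_motion_series("o", tr2, matrix(0, 50, 3)))
  sm2 <- summarize_subject_motion(ser2, cohort_log_values = cohort)
  expect_true(sm2$sd_outlier)
  in_val <- exp(mu + 1 * s)
  tr3 <- cbind(seq(0, by = in_val, length.out = 50), 0, 0)
  sm3 <- summarize_subject_motion(rigid_motion_series("i", tr3,
                                                      matrix(0, 50, 3)),
                                  cohort_log_values = cohort)
  expect_false(sm3$sd_outlier)

  # gross motion flags but does not prevent summarisation
  tr4 <- matrix(0, 20, 3); tr4[10, 1] <- 5
  sm4 <- summarize_subject_motion(rigid_motion_series("g", tr4,
                                                      matrix(0, 20, 3)))
  expect_true(sm4$gross_motion)
  expect_gt(sm4$mean_displacement_mm, 0)

  # zero motion floors the log with a warning
  expect_warning(sm5 <- summarize_subject_motion(zero_series(10)), "floor")
  expect_equal(sm5$log_displacement, log(1e-6))
})
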