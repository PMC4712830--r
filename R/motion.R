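# Head-motion metrics from rigid-body realignment parameters.
#
# Conventions (fixed; see the methods vignette):
#   - frame 1 is the reference, its six parameters are all zero;
#   - rotations are radians in files (SPM and FSL both write radians);
#   - a frame's affine is T = Translate(t) %*% Rx(a) %*% Ry(b) %*% Rz(c)
#     with right-handed rotations (SPM order);
#   - displacement metric uses a brain modelled as a ball of radius R = 80 mm
#     centred at x_c (default the origin of the realignment coordinates).

#' Construct a rigid-body motion series
#'
#' Bundles the per-frame realignment parameters of one subject. Frame 1 is
#' the reference frame and must have (near-)zero parameters; all rotations
#' are in radians, translations in millimetres.
#'
#' @param subject_id character scalar.
#' @param translations numeric matrix, n_frames x 3, millimetres.
#' @param rotations numeric matrix, n_frames x 3, radians.
#' @param dialect `"spm"` or `"fsl"` (provenance only; storage is identical).
#' @return An object of class `rigid_motion_series`.
#' @export
rigid_motion_series <- function(subject_id, translations, rotations,
                                dialect = c("spm", "fsl")) {
  dialect <- match.arg(dialect)
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  if (ncol(translations) != 3L || ncol(rotations) != 3L)
    stop("translations and rotations must have 3 columns")
  if (nrow(translations) != nrow(rotations))
    stop("translations and rotations must have the same number of frames")
  n <- nrow(translations)
  if (n < 2L) stop("a motion series needs at least 2 frames")
  if (!all(is.finite(translations)) || !all(is.finite(rotations)))
    stop("non-finite realignment parameters")
  if (max(abs(translations[1L, ]), abs(rotations[1L, ])) > 1e-8)
    warning("first frame is not the zero reference frame; parameters are ",
            "interpreted as relative to frame 1 regardless")
  if (max(abs(rotations)) > 0.5)
    warning("rotation parameter exceeds 0.5 rad; check for degrees-in-file ",
            "or a dialect mix-up (SPM: columns 4-6 are rotations; FSL: 1-3)")
  structure(
    list(subject_id = as.character(subject_id), n_frames = n,
         translations = unname(translations), rotations = unname(rotations),
         dialect = dialect),
    class = "rigid_motion_series")
}

#' @export
print.rigid_motion_series <- function(x, ...) {
  cat(sprintf("<rigid_motion_series> subject %s: %d frames (%s dialect)\n",
              x$subject_id, x$n_frames, x$dialect))
  cat(sprintf("  max |translation| %.3f mm, max |rotation| %.4f rad\n",
              max(abs(x$translations)), max(abs(x$rotations))))
  invisible(x)
}

#' Read an SPM `rp_*.txt` or FSL `.par` realignment file
#'
#' Both dialects are whitespace-delimited with six numeric columns per frame.
#' SPM order is translations (mm) then rotations (rad); FSL (`mcflirt`)
#' writes rotations (rad) first, then translations (mm).
#'
#' @param path file path.
#' @param dialect `"spm"` or `"fsl"`.
#' @param subject_id subject label; defaults to the file name without
#'   extension.
#' @return A [rigid_motion_series()].
#' @export
read_realignment_series <- function(path, dialect = c("spm", "fsl"),
                                    subject_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 2L)
    stop("realignment file ", path, " has fewer than 2 frames")
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 6L || anyNA(vals))
      stop("malformed realignment line ", i, " in ", path,
           ": expected 6 numeric fields")
    vals
  })
  m <- do.call(rbind, rows)
  if (dialect == "spm") {
    rigid_motion_series(subject_id, m[, 1:3], m[, 4:6], dialect = "spm")
  } else {
    rigid_motion_series(subject_id, m[, 4:6], m[, 1:3], dialect = "fsl")
  }
}

#' Write a motion series back to a realignment file
#'
#' Inverse of [read_realignment_series()]; used for round-trip checks and
#' for emitting synthetic fixtures.
#'
#' @param series a [rigid_motion_series()].
#' @param path output path.
#' @param dialect column order to write.
#' @export
write_realignment_series <- function(series, path,
                                     dialect = c("spm", "fsl")) {
  dialect <- match.arg(dialect)
  m <- if (dialect == "spm") cbind(series$translations, series$rotations)
       else cbind(series$rotations, series$translations)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}

#' Rigid-body affine from realignment parameters
#'
#' Builds the 4x4 homogeneous transform
#' `T = Translate(t) %*% Rx(a) %*% Ry(b) %*% Rz(c)` (SPM composition order,
#' right-handed rotations).
#'
#' @param translation length-3 numeric, millimetres.
#' @param rotation length-3 numeric, radians (about x, y, z).
#' @return 4x4 numeric matrix.
#' @export
params_to_affine <- function(translation, rotation) {
  stopifnot(length(translation) == 3L, length(rotation) == 3L,
            all(is.finite(translation)), all(is.finite(rotation)))
  ca <- cos(rotation[1L]); sa <- sin(rotation[1L])
  cb <- cos(rotation[2L]); sb <- sin(rotation[2L])
  cc <- cos(rotation[3L]); sc <- sin(rotation[3L])
  rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  out <- diag(4)
  out[1:3, 1:3] <- rx %*% ry %*% rz
  out[1:3, 4L] <- translation
  out
}

#' RMS displacement between two rigid transforms (Jenkinson metric)
#'
#' The root-mean-square displacement, over a ball of radius `radius` centred
#' at `center`, induced by moving from the pose `T1` to the pose `T2`:
#' with `M = T2 %*% solve(T1) - I`, `A` its 3x3 block and `t` its translation
#' column, the metric is
#' `sqrt(radius^2/5 * tr(A'A) + |t + A %*% center|^2)`.
#' It equals the Euclidean norm of the relative translation exactly when the
#' relative transform is a pure translation.
#'
#' @param T1,T2 4x4 rigid transforms (frame-to-reference).
#' @param radius ball radius in mm (default 80, the conventional adult brain
#'   radius).
#' @param center centre of the ball in the realignment coordinates (mm).
#' @return displacement in millimetres (non-negative scalar).
#' @export
jenkinson_displacement <- function(T1, T2, radius = 80,
                                   center = c(0, 0, 0)) {
  stopifnot(radius > 0, length(center) == 3L)
  d1 <- det(T1[1:3, 1:3])
  if (!is.finite(d1) || abs(d1) < 1e-6)
    stop("T1 is (numerically) singular; not a rigid transform")
  M <- T2 %*% solve(T1) - diag(4)
  A <- M[1:3, 1:3]
  t <- M[1:3, 4L] + A %*% center
  sqrt(max(0, radius^2 / 5 * sum(A * A) + sum(t * t)))
}

#' Framewise displacement series
#'
#' With `mode = "consecutive"` (the default and the path used by the
#' per-subject summary), entry `i` is the Jenkinson metric between the
#' absolute poses of frames `i` and `i + 1` (each expressed relative to the
#' reference frame, then composed pairwise). With `mode = "reference"`,
#' entry `i` is the displacement of frame `i + 1` from the reference frame
#' itself.
#'
#' @param series a [rigid_motion_series()].
#' @param mode `"consecutive"` or `"reference"`.
#' @inheritParams jenkinson_displacement
#' @return numeric vector of length `n_frames - 1`, millimetres.
#' @export
framewise_series <- function(series, radius = 80, center = c(0, 0, 0),
                             mode = c("consecutive", "reference")) {
  mode <- match.arg(mode)
  n <- series$n_frames
  affines <- lapply(seq_len(n), function(i)
    params_to_affine(series$translations[i, ], series$rotations[i, ]))
  if (mode == "reference") {
    ref <- affines[[1L]]
    return(vapply(seq_len(n - 1L), function(i)
      jenkinson_displacement(ref, affines[[i + 1L]],
                             radius = radius, center = center),
      numeric(1)))
  }
  vapply(seq_len(n - 1L), function(i)
    jenkinson_displacement(affines[[i]], affines[[i + 1L]],
                           radius = radius, center = center),
    numeric(1))
}

#' Gross-motion exclusion flag
#'
#' TRUE when any frame's parameters (relative to the reference frame, as
#' realignment outputs are) exceed the exclusion thresholds: translation
#' strictly greater than `trans_thresh` mm on any axis, or rotation strictly
#' greater than `rot_thresh` degrees about any axis.
#'
#' @param series a [rigid_motion_series()].
#' @param trans_thresh translation threshold, mm (default 3).
#' @param rot_thresh rotation threshold, degrees (default 2).
#' @return logical scalar.
#' @export
gross_motion_flag <- function(series, trans_thresh = 3, rot_thresh = 2) {
  rot_rad <- rot_thresh * pi / 180
  max(abs(series$translations)) > trans_thresh ||
    max(abs(series$rotations)) > rot_rad
}

#' Per-subject head-motion summary
#'
#' Summarises a motion series as the mean of the framewise (consecutive)
#' Jenkinson displacements, its natural log, per-axis maxima, the
#' gross-motion flag and, when a vector of cohort log values is supplied, a
#' 4-standard-deviation outlier flag on the log scale (flag only, never an
#' exclusion).
#'
#' @param series a [rigid_motion_series()].
#' @param cohort_log_values optional numeric vector of cohort log
#'   displacements used for the outlier flag.
#' @param radius,center passed to [jenkinson_displacement()].
#' @param trans_thresh,rot_thresh passed to [gross_motion_flag()].
#' @param sd_limit outlier cut in cohort standard deviations (default 4).
#' @return a one-row data.frame (class `motion_summary`).
#' @export
summarize_subject_motion <- function(series, cohort_log_values = NULL,
                                     radius = 80, center = c(0, 0, 0),
                                     trans_thresh = 3, rot_thresh = 2,
                                     sd_limit = 4) {
  fw <- framewise_series(series, radius = radius, center = center)
  mean_disp <- mean(fw)
  if (mean_disp < 1e-6) {
    warning("mean displacement below 1e-6 mm; log floored at log(1e-6)")
    log_disp <- log(1e-6)
  } else {
    log_disp <- log(mean_disp)
  }
  sd_outlier <- NA
  if (!is.null(cohort_log_values) && length(cohort_log_values) >= 3L) {
    mu <- mean(cohort_log_values); s <- sd(cohort_log_values)
    sd_outlier <- is.finite(s) && s > 0 && abs(log_disp - mu) > sd_limit * s
  }
  out <- data.frame(
    subject_id = series$subject_id,
    n_frames = series$n_frames,
    mean_displacement_mm = mean_disp,
    log_displacement = log_disp,
    max_abs_translation_mm = max(abs(series$translations)),
    max_abs_rotation_deg = max(abs(series$rotations)) * 180 / pi,
    gross_motion = gross_motion_flag(series, trans_thresh, rot_thresh),
    sd_outlier = sd_outlier,
    stringsAsFactors = FALSE)
  class(out) <- c("motion_summary", class(out))
  out
}

#' Motion summary table for a set of realignment files
#'
#' Reads every realignment file, summarises each subject, then adds the
#' cohort-level 4-sd outlier flag computed from the log displacements of the
#' subjects themselves.
#'
#' @param paths character vector of realignment file paths.
#' @param dialect `"spm"` or `"fsl"`, applied to all files.
#' @param ... passed to [summarize_subject_motion()].
#' @return data.frame with one row per subject.
#' @export
motion_summary_table <- function(paths, dialect = c("spm", "fsl"), ...) {
  dialect <- match.arg(dialect)
  series <- lapply(paths, read_realignment_series, dialect = dialect)
  rows <- lapply(series, summarize_subject_motion, ...)
  tab <- do.call(rbind, rows)
  if (nrow(tab) >= 3L) {
    mu <- mean(tab$log_displacement); s <- sd(tab$log_displacement)
    tab$sd_outlier <- s > 0 & abs(tab$log_displacement - mu) > 4 * s
  }
  rownames(tab) <- NULL
  tab
}
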