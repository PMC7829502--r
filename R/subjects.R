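## Subject records, cohort I/O, and motion-based quality control.

#' Construct a subject record
#'
#' @param subject_id character scalar.
#' @param group one of \code{"HC"}, \code{"noHE"}, \code{"MHE"},
#'   \code{"unlabeled"}.
#' @param timeseries numeric matrix, nodes x volumes, no missing values.
#' @param age,education years; \code{sex} \code{"M"}/\code{"F"}.
#' @param nct_a number-connection test A time in seconds (higher = worse).
#' @param dst digit-symbol test score (lower = worse).
#' @param blood_ammonia micromol/L, optional.
#' @param motion optional volumes x 6 realignment-parameter matrix
#'   (3 translations in mm, then 3 rotations in radians).
#' @return a \code{subject_record}.
#' @export
subject_record <- function(subject_id, group, timeseries,
                           age = NA_real_, sex = NA_character_,
                           education = NA_real_, nct_a = NA_real_,
                           dst = NA_real_, blood_ammonia = NA_real_,
                           motion = NULL) {
  group <- match.arg(group, c("HC", "noHE", "MHE", "unlabeled"))
  timeseries <- as.matrix(timeseries)
  storage.mode(timeseries) <- "double"
  if (anyNA(timeseries))
    stop(sprintf("subject %s: time series contains missing values",
                 subject_id))
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    storage.mode(motion) <- "double"
    if (ncol(motion) != 6L)
      stop(sprintf("subject %s: motion matrix must have 6 columns",
                   subject_id))
  }
  structure(list(
    subject_id = as.character(subject_id), group = group,
    timeseries = timeseries, age = as.numeric(age),
    sex = as.character(sex), education = as.numeric(education),
    nct_a = as.numeric(nct_a), dst = as.numeric(dst),
    blood_ammonia = as.numeric(blood_ammonia), motion = motion
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject %s> group %s, %d nodes x %d volumes%s\n",
              x$subject_id, x$group, nrow(x$timeseries),
              ncol(x$timeseries),
              if (is.null(x$motion)) ", no motion data" else ""))
  invisible(x)
}

#' Load a cohort from a manifest
#'
#' The manifest is a tab-separated table with columns \code{subject_id},
#' \code{group}, \code{age}, \code{sex}, \code{education}, \code{nct_a},
#' \code{dst}, \code{blood_ammonia}, \code{series_file} and (optionally)
#' \code{motion_file}. Series files are header-less node x volume TSVs;
#' motion files are whitespace-separated volumes x 6 realignment tables.
#' Subjects are returned in manifest order. All series shape mismatches
#' against the atlas are collected and reported in a single error.
#'
#' @param manifest_path path to the manifest TSV.
#' @param series_dir directory that relative file paths resolve against;
#'   defaults to the manifest's directory.
#' @param atlas optional \code{atlas}; when given, every series must have
#'   exactly \code{atlas$n_nodes} rows.
#' @return list of \code{subject_record}s.
#' @export
load_subjects <- function(manifest_path, series_dir = dirname(manifest_path),
                          atlas = NULL) {
  man <- read.delim(manifest_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group", "series_file") %in% names(man)))
    stop("manifest needs at least subject_id, group, series_file columns")
  getcol <- function(nm) if (nm %in% names(man)) man[[nm]] else
    rep(NA_real_, nrow(man))
  resolve <- function(f) ifelse(grepl("^(/|[A-Za-z]:)", f), f,
                                file.path(series_dir, f))
  records <- vector("list", nrow(man))
  shape_errors <- character(0)
  for (i in seq_len(nrow(man))) {
    ts <- as.matrix(read.delim(resolve(man$series_file[i]), header = FALSE,
                               sep = "\t"))
    dimnames(ts) <- NULL
    if (!is.null(atlas) && nrow(ts) != atlas$n_nodes) {
      shape_errors <- c(shape_errors,
        sprintf("subject %s: expected %d node rows, found %d",
                man$subject_id[i], atlas$n_nodes, nrow(ts)))
      next
    }
    motion <- NULL
    if ("motion_file" %in% names(man) && !is.na(man$motion_file[i]) &&
        nzchar(man$motion_file[i])) {
      motion <- as.matrix(read.table(resolve(man$motion_file[i]),
                                     header = FALSE))
      dimnames(motion) <- NULL
    }
    records[[i]] <- subject_record(
      man$subject_id[i], man$group[i], ts,
      age = getcol("age")[i], sex = as.character(getcol("sex")[i]),
      education = getcol("education")[i], nct_a = getcol("nct_a")[i],
      dst = getcol("dst")[i], blood_ammonia = getcol("blood_ammonia")[i],
      motion = motion)
  }
  if (length(shape_errors))
    stop("series shape mismatch:\n  ",
         paste(shape_errors, collapse = "\n  "))
  records
}

#' Write a cohort in the manifest + TSV layout
#'
#' Writes one header-less node x volume series TSV per subject (and a
#' 6-column motion file when present) plus a \code{manifest.tsv}, so
#' synthetic cohorts round-trip through the same reader as real data.
#'
#' @param subjects list of \code{subject_record}s.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(subjects, function(s) {
    sf <- file.path("series", paste0(s$subject_id, ".tsv"))
    write.table(s$timeseries, file.path(dir, sf), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    mf <- ""
    if (!is.null(s$motion)) {
      dir.create(file.path(dir, "motion"), showWarnings = FALSE)
      mf <- file.path("motion", paste0("rp_", s$subject_id, ".txt"))
      write.table(s$motion, file.path(dir, mf), sep = " ",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, education = s$education, nct_a = s$nct_a,
               dst = s$dst, blood_ammonia = s$blood_ammonia,
               series_file = sf, motion_file = mf,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Framewise displacement from realignment parameters
#'
#' Per volume transition, the sum of absolute framewise differences of the
#' six rigid-body parameters, with the three rotations (radians) converted
#' to arc length on a sphere (Power convention).
#'
#' @param motion volumes x 6 matrix: translations (mm) then rotations
#'   (radians).
#' @param radius_mm sphere radius for the rotation arc length; 50 mm by
#'   convention.
#' @return numeric vector of length \code{nrow(motion) - 1}, in mm.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion matrix must have 6 columns")
  if (nrow(motion) < 2L) stop("need at least 2 volumes to compute FD")
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) +
    rowSums(d[, 4:6, drop = FALSE]) * radius_mm
}

#' Motion quality control for one subject
#'
#' A subject is excluded when mean FD exceeds 0.2 mm, any absolute
#' translation exceeds 2 mm, or any absolute rotation exceeds 2 degrees
#' (all strict inequalities). Subjects without motion data are kept, with
#' the reason logged.
#'
#' @param subject a \code{subject_record}.
#' @param fd_limit_mm,translation_limit_mm,rotation_limit_deg exclusion
#'   thresholds.
#' @return one-row data frame: \code{subject_id}, \code{mean_fd},
#'   \code{max_translation}, \code{max_rotation}, \code{excluded},
#'   \code{reason}.
#' @export
qc_motion <- function(subject, fd_limit_mm = 0.2,
                      translation_limit_mm = 2, rotation_limit_deg = 2) {
  if (is.null(subject$motion)) {
    return(data.frame(subject_id = subject$subject_id, mean_fd = NA_real_,
                      max_translation = NA_real_, max_rotation = NA_real_,
                      excluded = FALSE, reason = "no motion data",
                      stringsAsFactors = FALSE))
  }
  fd <- framewise_displacement(subject$motion)
  mean_fd <- mean(fd)
  max_tr <- max(abs(subject$motion[, 1:3]))
  max_rot <- max(abs(subject$motion[, 4:6])) * 180 / pi
  reasons <- c(
    if (mean_fd > fd_limit_mm)
      sprintf("mean FD %.3f mm > %.1f mm", mean_fd, fd_limit_mm),
    if (max_tr > translation_limit_mm)
      sprintf("max translation %.2f mm > %.0f mm", max_tr,
              translation_limit_mm),
    if (max_rot > rotation_limit_deg)
      sprintf("max rotation %.2f deg > %.0f deg", max_rot,
              rotation_limit_deg))
  data.frame(subject_id = subject$subject_id, mean_fd = mean_fd,
             max_translation = max_tr, max_rotation = max_rot,
             excluded = length(reasons) > 0L,
             reason = if (length(reasons)) paste(reasons, collapse = "; ")
                      else "", stringsAsFactors = FALSE)
}

#' Motion QC report for a whole cohort
#'
#' @param subjects list of \code{subject_record}s.
#' @param ... passed to \code{\link{qc_motion}}.
#' @return data frame with one QC row per subject.
#' @export
qc_cohort <- function(subjects, ...) {
  do.call(rbind, lapply(subjects, qc_motion, ...))
}
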