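# Cohort container and flat-CSV persistence.
#
# On-disk layout (one directory per subject):
#   <root>/<subject_id>/traits.csv                 age,height,weight,bmi
#   <root>/<subject_id>/sets.csv                   hand,set_index,reported_rpe,heart_rate,file
#   <root>/<subject_id>/set_<hand>_<set_index>.csv timestamp,ax,ay,az,gx,gy,gz
# All CSV are RFC-4180 with a header row, UTF-8, '.' decimal separator.
# Numbers are written with %.17g so write -> read round-trips bit-exactly.

#' Assemble a cohort object
#'
#' @param subjects List of subject entries, each a list with `subject_id`,
#'   `traits` (a [physical_traits()]) and `recordings` (list of
#'   [set_recording()]).
#' @return Object of class `imu_cohort`.
#' @export
imu_cohort <- function(subjects = list()) {
  ids <- vapply(subjects, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) {
    stop("imu_cohort(): duplicate subject ids", call. = FALSE)
  }
  names(subjects) <- ids
  structure(list(subjects = subjects), class = "imu_cohort")
}

fmt_num <- function(x) sprintf("%.17g", x)

write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a cohort to a directory tree of CSV files
#'
#' @param cohort An [imu_cohort()].
#' @param root_path Output directory (created if absent).
#' @return Invisibly, a manifest data frame (`subject_id`, `type`, `file`).
#' @export
write_cohort <- function(cohort, root_path) {
  stopifnot(inherits(cohort, "imu_cohort"))
  if (!dir.exists(root_path)) {
    ok <- dir.create(root_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("write_cohort(): cannot create '%s'", root_path),
                  call. = FALSE)
  }
  rows <- list()
  for (sub in cohort$subjects) {
    sdir <- file.path(root_path, sub$subject_id)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    tr <- sub$traits
    write_csv_exact(data.frame(age = tr$age, height = tr$height,
                               weight = tr$weight, bmi = tr$bmi),
                    file.path(sdir, "traits.csv"))
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = sub$subject_id, type = "traits",
                 file = file.path(sub$subject_id, "traits.csv"))
    meta <- data.frame(hand = character(), set_index = integer(),
                       reported_rpe = numeric(), heart_rate = numeric(),
                       file = character())
    for (rec in sub$recordings) {
      fname <- sprintf("set_%s_%d.csv", rec$hand, rec$set_index)
      sig <- cbind(data.frame(timestamp = rec$timestamps), rec$channels)
      write_csv_exact(sig, file.path(sdir, fname))
      meta <- rbind(meta, data.frame(
        hand = rec$hand, set_index = rec$set_index,
        reported_rpe = rec$reported_rpe, heart_rate = rec$heart_rate,
        file = fname))
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sub$subject_id, type = "signals",
                   file = file.path(sub$subject_id, fname))
    }
    write_csv_exact(meta, file.path(sdir, "sets.csv"))
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = sub$subject_id, type = "sets",
                 file = file.path(sub$subject_id, "sets.csv"))
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), type = character(),
               file = character())
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param root_path Cohort directory.
#' @param sampling A [sampling_spec()]; timestamps are checked against it
#'   only for monotonicity (units are never auto-converted).
#' @return An [imu_cohort()].
#' @export
read_cohort <- function(root_path, sampling = sampling_spec()) {
  if (!dir.exists(root_path)) {
    stop(sprintf("read_cohort(): no such directory '%s'", root_path),
         call. = FALSE)
  }
  sdirs <- sort(list.dirs(root_path, recursive = FALSE))
  subjects <- list()
  for (sdir in sdirs) {
    sid <- basename(sdir)
    tfile <- file.path(sdir, "traits.csv")
    mfile <- file.path(sdir, "sets.csv")
    if (!file.exists(tfile) || !file.exists(mfile)) {
      stop(sprintf("read_cohort(): subject '%s' lacks traits.csv/sets.csv",
                   sid), call. = FALSE)
    }
    tr <- utils::read.csv(tfile)
    traits <- physical_traits(tr$age[1], tr$height[1], tr$weight[1],
                              bmi = tr$bmi[1])
    meta <- utils::read.csv(mfile, stringsAsFactors = FALSE)
    recs <- vector("list", nrow(meta))
    for (i in seq_len(nrow(meta))) {
      sigfile <- file.path(sdir, meta$file[i])
      sig <- utils::read.csv(sigfile)
      missing <- setdiff(c("timestamp", CHANNEL_NAMES_RAW), names(sig))
      if (length(missing)) {
        stop(sprintf("read_cohort(): %s: missing column(s): %s",
                     sigfile, paste(missing, collapse = ", ")),
             call. = FALSE)
      }
      if (any(diff(sig$timestamp) <= 0)) {
        stop(sprintf("read_cohort(): %s: timestamps not strictly increasing",
                     sigfile), call. = FALSE)
      }
      recs[[i]] <- set_recording(
        subject_id = sid, hand = meta$hand[i], set_index = meta$set_index[i],
        timestamps = sig$timestamp, channels = sig[CHANNEL_NAMES_RAW],
        reported_rpe = meta$reported_rpe[i], heart_rate = meta$heart_rate[i])
    }
    subjects[[length(subjects) + 1L]] <-
      list(subject_id = sid, traits = traits, recordings = recs)
  }
  imu_cohort(subjects)
}
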