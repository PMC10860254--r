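## Submission data model and JSON I/O.
##
## A submission is one student's tracing of one cephalogram, exported by the
## tracing application as a JSON document:
##
##   {
##     "subject":      "042",              pseudonym or plain name
##     "image":        "A",                cephalogram identifier
##     "device":       "tablet",           "tablet" or "desktop"
##     "gender":       "female",           "female", "male" or "unknown"
##     "order":        0,                  0 = student's first analysis
##     "capture":      "dicom",            "dicom" or "screenshot"
##     "first_placed": "2021-03-01T12:00:00.000Z",
##     "last_placed":  "2021-03-01T12:11:48.000Z",
##     "landmarks":    [ {"name": "S", "x": 588.88, "y": 152.56}, ... ]
##   }
##
## The schema is shipped at inst/extdata/submission-schema.json.

TS_FMT <- "%Y-%m-%dT%H:%M:%OS"

parse_time <- function(x) {
  t <- as.POSIXct(x, format = TS_FMT, tz = "UTC")
  if (is.na(t)) stop("unparseable timestamp: ", x, call. = FALSE)
  t
}

format_time <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

invalid_file_error <- function(msg, source = NA_character_) {
  structure(
    class = c("cephmetrics_invalid_file", "error", "condition"),
    list(message = msg, call = NULL, source = source)
  )
}

#' Create a submission object
#'
#' In-memory representation of one student's tracing of one cephalogram.
#' `landmarks` is a tidy tibble with one row per placed landmark; a complete
#' tracing has exactly the 33 names of [landmark_names()].
#'
#' @param subject Subject identifier (pseudonym or name).
#' @param image Cephalogram identifier, e.g. `"A"` or `"B"`.
#' @param device `"tablet"` or `"desktop"`.
#' @param landmarks Data frame with columns `landmark` (or `name`), `x`, `y`.
#' @param gender `"female"`, `"male"` or `"unknown"`.
#' @param order 0 if this is the student's first analysis, 1 otherwise.
#' @param t_first,t_last POSIXct timestamps of the first and last landmark
#'   placement; `t_last` must not precede `t_first`.
#' @param capture `"dicom"` for a regular tracing, `"screenshot"` when the
#'   student traced a screenshot of the image rather than the image itself.
#' @param source Optional file path the submission was read from.
#' @return An object of class `ceph_submission`.
#' @export
new_submission <- function(subject, image, device, landmarks,
                           gender = "unknown", order = 0L,
                           t_first = as.POSIXct("2021-01-01", tz = "UTC"),
                           t_last = t_first,
                           capture = "dicom", source = NA_character_) {
  if (is.null(image) || is.null(device) || !nzchar(image) || !nzchar(device)) {
    stop("submission requires image and device", call. = FALSE)
  }
  device <- match.arg(device, c("tablet", "desktop"))
  gender <- match.arg(gender, c("female", "male", "unknown"))
  capture <- match.arg(capture, c("dicom", "screenshot"))
  lm <- tibble::as_tibble(landmarks)
  if ("name" %in% names(lm) && !"landmark" %in% names(lm)) {
    lm <- dplyr::rename(lm, landmark = "name")
  }
  stopifnot(all(c("landmark", "x", "y") %in% names(lm)))
  lm <- lm[, c("landmark", "x", "y")]
  if (anyDuplicated(lm$landmark)) {
    stop("duplicate landmark names in submission", call. = FALSE)
  }
  if (t_last < t_first) {
    stop("t_last precedes t_first", call. = FALSE)
  }
  structure(
    list(
      subject = as.character(subject), image = as.character(image),
      device = device, gender = gender, order = as.integer(order),
      capture = capture,
      t_first = t_first, t_last = t_last,
      landmarks = lm, source = source
    ),
    class = "ceph_submission"
  )
}

#' @export
print.ceph_submission <- function(x, ...) {
  cat(sprintf(
    "<ceph_submission> subject %s, image %s, %s, %d/33 landmarks\n",
    x$subject, x$image, x$device, nrow(x$landmarks)
  ))
  invisible(x)
}

#' Is a submission's landmark set complete?
#'
#' @param submission A `ceph_submission`.
#' @return TRUE when all 33 landmark names are present.
#' @export
is_complete <- function(submission) {
  all(landmark_names() %in% submission$landmarks$landmark)
}

#' Parse a submission from its JSON export
#'
#' Reads one tracing from the JSON export format of the tracing application.
#' Malformed documents (non-JSON, missing metadata, malformed landmark
#' records) signal an error of class `cephmetrics_invalid_file`; a submission
#' with fewer than the 33 expected landmarks parses fine and is flagged by
#' [is_complete()] (and excluded later as `missing_landmarks`).
#'
#' @param x A file path, a JSON string, or a raw vector.
#' @return A `ceph_submission`.
#' @seealso [write_submission()], [read_submissions()]
#' @export
parse_submission <- function(x) {
  source <- NA_character_
  if (is.raw(x)) x <- rawToChar(x)
  if (length(x) == 1 && !grepl("^[[:space:]]*\\{", x)) {
    source <- x
    x <- tryCatch(
      paste(readLines(x, warn = FALSE), collapse = "\n"),
      error = function(e) stop(invalid_file_error(conditionMessage(e), source))
    )
  }
  doc <- tryCatch(
    jsonlite::fromJSON(x, simplifyDataFrame = TRUE),
    error = function(e) stop(invalid_file_error(
      paste("not valid JSON:", conditionMessage(e)), source))
  )
  need <- c("subject", "image", "device", "first_placed", "last_placed",
            "landmarks")
  missing_keys <- setdiff(need, names(doc))
  if (length(missing_keys)) {
    stop(invalid_file_error(
      paste("missing required keys:", paste(missing_keys, collapse = ", ")),
      source))
  }
  lm <- doc$landmarks
  if (!is.data.frame(lm) || !all(c("name", "x", "y") %in% names(lm)) ||
      !is.numeric(lm$x) || !is.numeric(lm$y)) {
    stop(invalid_file_error("malformed landmark array", source))
  }
  unknown <- setdiff(lm$name, landmark_names())
  if (length(unknown)) {
    stop(invalid_file_error(
      paste("unknown landmark names:", paste(unknown, collapse = ", ")),
      source))
  }
  tryCatch(
    new_submission(
      subject = doc$subject, image = doc$image, device = doc$device,
      gender = doc$gender %||% "unknown",
      order = doc$order %||% 0L,
      capture = doc$capture %||% "dicom",
      t_first = parse_time(doc$first_placed),
      t_last = parse_time(doc$last_placed),
      landmarks = lm, source = source
    ),
    error = function(e) {
      if (inherits(e, "cephmetrics_invalid_file")) stop(e)
      stop(invalid_file_error(conditionMessage(e), source))
    }
  )
}

#' Write a submission to its JSON export format
#'
#' Inverse of [parse_submission()]: `parse_submission(write_submission(s, f))`
#' reproduces `s` on all fields (timestamps to millisecond precision).
#'
#' @param submission A `ceph_submission`.
#' @param path Output file path; created or overwritten.
#' @return `path`, invisibly.
#' @export
write_submission <- function(submission, path) {
  stopifnot(inherits(submission, "ceph_submission"))
  doc <- list(
    subject = submission$subject,
    image = submission$image,
    device = submission$device,
    gender = submission$gender,
    order = submission$order,
    capture = submission$capture,
    first_placed = format_time(submission$t_first),
    last_placed = format_time(submission$t_last),
    landmarks = data.frame(
      name = submission$landmarks$landmark,
      x = submission$landmarks$x,
      y = submission$landmarks$y
    )
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read all submissions in a directory
#'
#' Parses every `*.json` file; files that fail to parse become stubs of class
#' `ceph_invalid` carrying the file name and error message, so that
#' [apply_exclusions()] can account for them as `invalid_file`.
#'
#' @param dir Directory containing submission JSON files.
#' @return A list of `ceph_submission` / `ceph_invalid` objects.
#' @export
read_submissions <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  lapply(files, function(f) {
    tryCatch(parse_submission(f),
             cephmetrics_invalid_file = function(e) {
               structure(list(source = f, message = conditionMessage(e)),
                         class = "ceph_invalid")
             })
  })
}

#' Partition submissions into included and excluded
#'
#' Applies the study's exclusion rules, in this order, to each parsed
#' submission (parse failures enter as `ceph_invalid` stubs):
#' `invalid_file`, `screenshot` (the tracing was made on a screenshot of the
#' cephalogram), `wrong_cephalogram` (image not among `allowed_images`),
#' `wrong_device_assignment` (image traced on a device it was not assigned
#' to, when `assignment` is given), `missing_landmarks`, and `duplicate`.
#' Duplicates share (subject, image, device); by default the earliest
#' `t_first` is kept.
#'
#' @param submissions List of `ceph_submission` / `ceph_invalid` objects.
#' @param allowed_images Character vector of valid cephalogram identifiers.
#' @param assignment Optional data frame with columns `subject`, `device`,
#'   `image` giving each student's intended image-device pairing.
#' @param duplicate_keep `"earliest"` (default) or `"latest"`.
#' @return An object of class `ceph_exclusions`: a list with `included` (list
#'   of submissions), `excluded` (tibble with columns `subject`, `image`,
#'   `device`, `source`, `reason`) and `counts` (tibble `reason`, `n`).
#' @export
apply_exclusions <- function(submissions, allowed_images = c("A", "B"),
                             assignment = NULL,
                             duplicate_keep = c("earliest", "latest")) {
  duplicate_keep <- match.arg(duplicate_keep)
  reasons <- character(length(submissions))

  for (i in seq_along(submissions)) {
    s <- submissions[[i]]
    if (inherits(s, "ceph_invalid")) {
      reasons[i] <- "invalid_file"
    } else if (s$capture == "screenshot") {
      reasons[i] <- "screenshot"
    } else if (!s$image %in% allowed_images) {
      reasons[i] <- "wrong_cephalogram"
    } else if (!is.null(assignment)) {
      ok <- any(assignment$subject == s$subject &
                  assignment$device == s$device &
                  assignment$image == s$image)
      if (!ok) reasons[i] <- "wrong_device_assignment"
    }
    if (reasons[i] == "" && !is_complete(s)) {
      reasons[i] <- "missing_landmarks"
    }
  }

  # duplicate resolution among the so-far-included
  open_idx <- which(reasons == "")
  if (length(open_idx)) {
    key <- vapply(submissions[open_idx], function(s) {
      paste(s$subject, s$image, s$device, sep = "\r")
    }, character(1))
    tfirst <- vapply(submissions[open_idx], function(s) {
      as.numeric(s$t_first)
    }, numeric(1))
    for (k in unique(key[duplicated(key)])) {
      grp <- open_idx[key == k]
      tg <- tfirst[key == k]
      keep <- if (duplicate_keep == "earliest") {
        grp[which.min(tg)]
      } else {
        grp[which.max(tg)]
      }
      reasons[setdiff(grp, keep)] <- "duplicate"
    }
  }

  meta <- function(s, field) {
    if (inherits(s, "ceph_invalid")) NA_character_ else s[[field]]
  }
  excluded_idx <- which(reasons != "")
  excluded <- tibble::tibble(
    subject = vapply(submissions[excluded_idx], meta, character(1), "subject"),
    image = vapply(submissions[excluded_idx], meta, character(1), "image"),
    device = vapply(submissions[excluded_idx], meta, character(1), "device"),
    source = vapply(submissions[excluded_idx], function(s) {
      as.character(s$source %||% NA_character_)
    }, character(1)),
    reason = reasons[excluded_idx]
  )
  reason_levels <- c("wrong_cephalogram", "screenshot",
                     "wrong_device_assignment", "missing_landmarks",
                     "duplicate", "invalid_file")
  counts <- tibble::tibble(
    reason = reason_levels,
    n = vapply(reason_levels, function(r) sum(excluded$reason == r),
               integer(1))
  )
  structure(
    list(
      included = submissions[reasons == ""],
      excluded = excluded,
      counts = counts
    ),
    class = "ceph_exclusions"
  )
}

#' @export
print.ceph_exclusions <- function(x, ...) {
  cat(sprintf("<ceph_exclusions> %d included, %d excluded\n",
              length(x$included), nrow(x$excluded)))
  nonzero <- x$counts[x$counts$n > 0, ]
  if (nrow(nonzero)) {
    for (i in seq_len(nrow(nonzero))) {
      cat(sprintf("  %-24s %d\n", nonzero$reason[i], nonzero$n[i]))
    }
  }
  invisible(x)
}

#' Pseudonymise student names
#'
#' Each name is hashed as SHA3-256(name + salt); pseudonyms are the
#' zero-padded 1-based ranks of the names ordered by hash digest. The mapping
#' is deterministic for a fixed salt, equal names receive equal pseudonyms,
#' and the plain names never appear in any downstream artifact.
#'
#' @param names Character vector of plain names.
#' @param salt Non-empty salt string.
#' @return Named character vector mapping each input name to its pseudonym.
#' @export
#' @examples
#' pseudonymize(c("alice", "bob", "carol"), salt = "s")
pseudonymize <- function(names, salt) {
  if (!is.character(salt) || length(salt) != 1 || !nzchar(salt)) {
    stop("salt must be a non-empty string", call. = FALSE)
  }
  uniq <- unique(names)
  digests <- vapply(uniq, function(n) {
    as.character(openssl::sha3(paste0(n, salt), size = 256))
  }, character(1))
  rk <- rank(digests, ties.method = "first")
  width <- max(1L, nchar(as.character(length(uniq))))
  labels <- sprintf(paste0("%0", width, "d"), rk)
  setNames(labels[match(names, uniq)], names)
}

#' Build a reference landmark set from several raters
#'
#' The reference position of each landmark is the coordinate-wise arithmetic
#' mean of the contributing raters' placements. All rater sets must be
#' complete and belong to the same image.
#'
#' @param rater_sets Either a list of landmark tibbles (columns `landmark`,
#'   `x`, `y`, optionally `image`), or one long tibble with a `rater` column.
#' @return A tibble `landmark`, `x`, `y` with attributes `n_raters` and
#'   (when available) `image`.
#' @export
build_reference <- function(rater_sets) {
  if (is.data.frame(rater_sets)) {
    stopifnot("rater" %in% names(rater_sets))
    rater_sets <- split(
      rater_sets[setdiff(names(rater_sets), "rater")],
      rater_sets$rater
    )
  }
  if (length(rater_sets) < 2) {
    stop("build_reference needs at least two rater sets", call. = FALSE)
  }
  images <- unlist(lapply(rater_sets, function(s) {
    if ("image" %in% names(s)) unique(s$image) else NULL
  }))
  if (length(unique(images)) > 1) {
    stop("rater sets belong to different images", call. = FALSE)
  }
  for (s in rater_sets) {
    if (!all(landmark_names() %in% s$landmark)) {
      stop("incomplete rater set", call. = FALSE)
    }
  }
  long <- dplyr::bind_rows(rater_sets, .id = ".rater")
  ref <- long |>
    dplyr::group_by(.data$landmark) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  ref <- ref[match(landmark_names(), ref$landmark), ]
  attr(ref, "n_raters") <- length(rater_sets)
  if (length(images)) attr(ref, "image") <- images[1]
  ref
}

#' Tracing time of a submission
#'
#' Elapsed time between the first and last landmark placement, in decimal
#' minutes.
#'
#' @param submission A `ceph_submission`.
#' @return Non-negative time in minutes.
#' @export
tracing_time <- function(submission) {
  dt <- as.numeric(difftime(submission$t_last, submission$t_first,
                            units = "mins"))
  if (dt < 0) stop("reversed timestamps", call. = FALSE)
  dt
}
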