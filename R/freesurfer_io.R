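#' Parse volumetric measures from a FreeSurfer-style aseg.stats file
#'
#' Extracts the brain segmentation volume (`BrainSegVol`) and the estimated
#' total intracranial volume (`EstimatedTotalIntraCranialVol` / `eTIV`) from
#' the `# Measure` comment lines of an `aseg.stats`-dialect text file. The
#' parser is tolerant of surrounding whitespace, line order and
#' scientific-notation values, and also captures `BrainSegVolNotVent` when
#' present (stored, unused by default). The subject id is taken from a
#' `# subjectname` line when present, otherwise from the filename stem.
#'
#' @param path Path to a readable stats file.
#' @return A list of class `volumetric_measures` with fields `subject_id`,
#'   `tbv` (mm^3), `etiv` (mm^3), `tbv_notvent` (mm^3 or `NA`), `source_path`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".stats")
#' writeLines(c(
#'   "# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, 929035, mm^3",
#'   "# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, 1327593, mm^3"
#' ), f)
#' m <- parse_aseg_stats(f)
#' compute_brain2icv(m$tbv, m$etiv)
parse_aseg_stats <- function(path) {
  if (!file.exists(path)) stop("stats file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  subject_id <- sub("\\.(aseg\\.)?stats$", "", basename(path))
  name_line <- grep("^\\s*#\\s*subjectname\\s+", lines, value = TRUE)
  if (length(name_line)) {
    subject_id <- trimws(sub("^\\s*#\\s*subjectname\\s+", "", name_line[1]))
  }

  measure_idx <- grep("^\\s*#\\s*Measure\\s", lines)
  # each Measure line is comma-separated: name, short-name, description, value, unit
  get_measure <- function(short_name, long_name) {
    for (i in measure_idx) {
      fields <- trimws(strsplit(sub("^\\s*#\\s*Measure\\s+", "", lines[i]), ",")[[1]])
      if (length(fields) < 4) next
      if (fields[1] == long_name || fields[2] == short_name) {
        value <- suppressWarnings(as.numeric(fields[4]))
        if (is.na(value)) {
          stop("non-numeric value for measure '", short_name, "' at line ", i,
               " of ", path, call. = FALSE)
        }
        return(value)
      }
    }
    NA_real_
  }

  tbv <- get_measure("BrainSegVol", "BrainSeg")
  etiv <- get_measure("eTIV", "EstimatedTotalIntraCranialVol")
  tbv_notvent <- get_measure("BrainSegVolNotVent", "BrainSegNotVent")
  if (is.na(tbv)) {
    stop("missing 'BrainSegVol' Measure line in ", path, call. = FALSE)
  }
  if (is.na(etiv)) {
    stop("missing 'EstimatedTotalIntraCranialVol' (eTIV) Measure line in ",
         path, call. = FALSE)
  }
  if (tbv <= 0 || etiv <= 0) {
    stop("volumes must be positive in ", path, " (tbv = ", tbv,
         ", etiv = ", etiv, ")", call. = FALSE)
  }
  # small tolerance: segmentation noise can push TBV marginally above eTIV
  if (tbv > etiv * 1.05) {
    stop("BrainSegVol exceeds eTIV by more than 5% in ", path,
         "; implausible segmentation", call. = FALSE)
  }
  structure(list(subject_id = subject_id, tbv = tbv, etiv = etiv,
                 tbv_notvent = tbv_notvent, source_path = path),
            class = "volumetric_measures")
}

#' Brain-to-intracranial-volume ratio (Brain2ICV)
#'
#' Computes the atrophy proxy Brain2ICV = TBV / eTIV: the fraction of the
#' intracranial cavity still occupied by brain tissue. Because eTIV bounds
#' the maximal young-adult brain volume, 1 - Brain2ICV approximates the
#' lifetime volume loss from a single scan. The quotient is returned at full
#' precision; rounding (e.g. to 4 decimals for display) is a presentation
#' concern left to report emitters.
#'
#' @param tbv Total brain segmentation volume, mm^3 (> 0). Vectorized.
#' @param etiv Estimated total intracranial volume, mm^3 (> 0). Vectorized.
#' @return `tbv / etiv`, dimensionless.
#' @export
#' @examples
#' compute_brain2icv(929035, 1327593)  # ~0.6998
compute_brain2icv <- function(tbv, etiv) {
  if (!is.numeric(tbv) || !is.numeric(etiv)) {
    stop("tbv and etiv must be numeric", call. = FALSE)
  }
  if (any(!is.finite(tbv)) || any(!is.finite(etiv)) ||
      any(tbv <= 0) || any(etiv <= 0)) {
    stop("tbv and etiv must be positive and finite", call. = FALSE)
  }
  tbv / etiv
}

#' Truncate a ratio for display
#'
#' Presentation rule for worked Brain2ICV values: truncation (not half-up
#' rounding) toward zero at a fixed number of decimals, the convention used
#' when quoting the ratio alongside the raw volumes (e.g. 0.69979 is
#' displayed as 0.6997). Internal computations always keep full precision;
#' this is applied only in reports.
#'
#' @param x Numeric vector.
#' @param digits Decimals kept (default 4).
#' @return `x` truncated toward zero at `digits` decimals.
#' @export
#' @examples
#' truncate_ratio(compute_brain2icv(929035, 1327593))  # 0.6997
truncate_ratio <- function(x, digits = 4) {
  trunc(x * 10^digits) / 10^digits
}

#' Assemble an analysis-ready cohort from stats files and metadata
#'
#' Parses every `*.stats` file under `stats_dir`, computes Brain2ICV per
#' subject, and joins it onto the metadata table by `subject_id`. Metadata
#' rows without a matching stats file are dropped with a warning (an error
#' under `strict = TRUE`); the join report is attached as the `join_report`
#' attribute and lists matched and dropped subjects with reasons.
#'
#' @param stats_dir Directory containing per-subject stats files.
#' @param metadata Path to a metadata CSV (the cohort schema minus
#'   `brain2icv`), or an equivalent `data.frame`.
#' @param strict Error instead of warn on unmatched metadata rows.
#' @return A `cohort_table` with attribute `join_report`
#'   (`n_matched`, `n_dropped`, `dropped`).
#' @export
assemble_cohort <- function(stats_dir, metadata, strict = FALSE) {
  if (!dir.exists(stats_dir)) stop("stats_dir not found: ", stats_dir, call. = FALSE)
  meta <- if (is.character(metadata)) {
    utils::read.csv(metadata, stringsAsFactors = FALSE)
  } else {
    as.data.frame(metadata)
  }
  .check_cohort(meta, require = c("subject_id", "age", "sex", "apoe", "famad",
                                  "education", "cog_score"))
  if (anyDuplicated(meta$subject_id)) {
    stop("duplicate subject_id in metadata: ",
         paste(unique(meta$subject_id[duplicated(meta$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  files <- list.files(stats_dir, pattern = "\\.stats$", full.names = TRUE)
  measures <- lapply(files, parse_aseg_stats)
  ids <- vapply(measures, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id among stats files: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  b2icv <- vapply(measures, function(m) compute_brain2icv(m$tbv, m$etiv),
                  numeric(1))
  names(b2icv) <- ids

  matched <- meta$subject_id %in% ids
  dropped <- meta$subject_id[!matched]
  if (length(dropped)) {
    msg <- paste0(length(dropped), " metadata row(s) without a stats file: ",
                  paste(utils::head(dropped, 5), collapse = ", "),
                  if (length(dropped) > 5) ", ..." else "")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  cohort <- meta[matched, , drop = FALSE]
  cohort$brain2icv <- unname(b2icv[cohort$subject_id])
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  validate_cohort(cohort)
  attr(cohort, "join_report") <- list(
    n_matched = sum(matched),
    n_dropped = length(dropped),
    dropped = if (length(dropped)) {
      data.frame(subject_id = dropped, reason = "no matching stats file",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = character(), reason = character(),
                 stringsAsFactors = FALSE)
    }
  )
  cohort
}
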