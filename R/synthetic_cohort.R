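#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set of the linear-Gaussian structural
#' equation model that the generator samples from. The defaults reproduce the
#' marginal structure of a single-centre cohort of 890 healthy elderly
#' subjects: 303 men and 587 women; age normally distributed per sex
#' (74.64 +/- 3.83 years for men, 74.79 +/- 3.91 for women); Brain2ICV (the
#' total-brain to intracranial volume ratio used as a lifetime atrophy proxy)
#' normally distributed per sex (0.697 +/- 0.026 men, 0.708 +/- 0.028 women);
#' APOE-e4 allele counts 726/157/7 (none/het/hom), family history of dementia
#' 220/890, education levels 170/265/224/231 (none/primary/high school/
#' university), and an aggregate cognitive score of 9.41 +/- 2.66.
#'
#' The generating DAG is: sex -> Brain2ICV, age -> Brain2ICV,
#' education -> cognitive score, Brain2ICV -> cognitive score, with APOE and
#' family history as independent marginals. Age and sex are independent.
#' The age effect on Brain2ICV is a linear slope centred at the sex-specific
#' age mean; the Gaussian residual sd is reduced to
#' \code{sqrt(b2icv_sd^2 - slope^2 * age_sd^2)} so that the *marginal* sd of
#' Brain2ICV equals the configured value and the implied age correlation is
#' \code{slope * age_sd / b2icv_sd} (about -0.33 at the defaults).
#'
#' @param n_male,n_female Number of male and female subjects. Counts are fixed,
#'   not sampled, so class sizes are exactly reproducible.
#' @param age_mean_by_sex,age_sd_by_sex Named numeric vectors
#'   (`male`, `female`) of age means and sds in years.
#' @param b2icv_mean_by_sex,b2icv_sd_by_sex Named numeric vectors of
#'   Brain2ICV group means (in (0,1)) and sds.
#' @param age_effect_on_b2icv Linear change in Brain2ICV per year of age
#'   (negative; default -0.0023, calibrated to corr(age, Brain2ICV) of
#'   approximately -0.33 at the default sds).
#' @param edu_effect_on_b2icv Optional education -> Brain2ICV effect per
#'   ordinal level; 0 by default (the edge is exposed but off).
#' @param apoe_probs Probabilities of 0/1/2 APOE-e4 alleles.
#' @param famad_prob Probability of a positive family history of dementia.
#' @param education_probs Probabilities of education levels 0-3.
#' @param cog_mean,cog_sd Marginal mean and sd of the cognitive score.
#' @param cog_loadings Named vector of standardized effects of the cognitive
#'   score's DAG parents (`brain2icv`, `education`); their squares must sum
#'   to at most 1.
#' @param etiv_mean_by_sex,etiv_sd Intracranial-volume distribution (mm^3)
#'   used only when emitting FreeSurfer-style fixture files.
#' @param age_range Plausible age band; draws outside it are rejected and
#'   redrawn.
#' @param seed Integer seed recorded in the config and used by
#'   [generate_cohort()] unless overridden.
#'
#' @return A list of class `generator_config`.
#' @seealso [generate_cohort()], [write_freesurfer_fixtures()]
#' @export
#' @examples
#' cfg <- generator_config()
#' cfg$n_male
generator_config <- function(n_male = 303L,
                             n_female = 587L,
                             age_mean_by_sex = c(male = 74.64, female = 74.79),
                             age_sd_by_sex = c(male = 3.83, female = 3.91),
                             b2icv_mean_by_sex = c(male = 0.697, female = 0.708),
                             b2icv_sd_by_sex = c(male = 0.026, female = 0.028),
                             age_effect_on_b2icv = -0.0023,
                             edu_effect_on_b2icv = 0,
                             apoe_probs = c(726, 157, 7) / 890,
                             famad_prob = 220 / 890,
                             education_probs = c(170, 265, 224, 231) / 890,
                             cog_mean = 9.41,
                             cog_sd = 2.66,
                             cog_loadings = c(brain2icv = 0.14, education = 0.30),
                             etiv_mean_by_sex = c(male = 1.45e6, female = 1.33e6),
                             etiv_sd = 1e5,
                             age_range = c(60, 95),
                             seed = 1234L) {
  cfg <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
              age_mean_by_sex = age_mean_by_sex, age_sd_by_sex = age_sd_by_sex,
              b2icv_mean_by_sex = b2icv_mean_by_sex,
              b2icv_sd_by_sex = b2icv_sd_by_sex,
              age_effect_on_b2icv = age_effect_on_b2icv,
              edu_effect_on_b2icv = edu_effect_on_b2icv,
              apoe_probs = apoe_probs, famad_prob = famad_prob,
              education_probs = education_probs,
              cog_mean = cog_mean, cog_sd = cog_sd, cog_loadings = cog_loadings,
              etiv_mean_by_sex = etiv_mean_by_sex, etiv_sd = etiv_sd,
              age_range = age_range, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks probability vectors (entries in \[0,1\], sums within 1e-9 of 1),
#' non-negative sds, positive group counts and Brain2ICV means in (0,1).
#' Errors name the offending field.
#'
#' @param cfg A `generator_config`.
#' @return The config, invisibly usable, if valid; otherwise an error.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  bad <- function(field, msg) {
    stop("invalid generator configuration: '", field, "' ", msg, call. = FALSE)
  }
  if (cfg$n_male < 1L) bad("n_male", "must be positive")
  if (cfg$n_female < 1L) bad("n_female", "must be positive")
  for (field in c("apoe_probs", "education_probs")) {
    p <- cfg[[field]]
    if (any(p < 0 | p > 1)) bad(field, "has entries outside [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) bad(field, "does not sum to 1")
  }
  if (length(cfg$apoe_probs) != 3L) bad("apoe_probs", "must have 3 entries")
  if (length(cfg$education_probs) != 4L) bad("education_probs", "must have 4 entries")
  if (cfg$famad_prob < 0 || cfg$famad_prob > 1) bad("famad_prob", "outside [0, 1]")
  for (field in c("age_sd_by_sex", "b2icv_sd_by_sex", "cog_sd", "etiv_sd")) {
    if (any(cfg[[field]] < 0)) bad(field, "must be non-negative")
  }
  if (any(cfg$b2icv_mean_by_sex <= 0 | cfg$b2icv_mean_by_sex >= 1)) {
    bad("b2icv_mean_by_sex", "must lie in (0, 1)")
  }
  for (field in c("age_mean_by_sex", "age_sd_by_sex", "b2icv_mean_by_sex",
                  "b2icv_sd_by_sex", "etiv_mean_by_sex")) {
    if (!all(c("male", "female") %in% names(cfg[[field]]))) {
      bad(field, "must be named with 'male' and 'female'")
    }
  }
  if (sum(cfg$cog_loadings^2) > 1 + 1e-9) {
    bad("cog_loadings", "squared loadings must sum to at most 1")
  }
  # residual sd of Brain2ICV must be real once the age term is subtracted out
  resid_var <- cfg$b2icv_sd_by_sex[c("male", "female")]^2 -
    cfg$age_effect_on_b2icv^2 * cfg$age_sd_by_sex[c("male", "female")]^2
  if (any(resid_var < -1e-12)) {
    bad("age_effect_on_b2icv",
        "is too large for the configured b2icv_sd_by_sex (negative residual variance)")
  }
  cfg
}

# standardize a column; all-zero when degenerate so loadings stay inert
.zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# normal draw truncated to [lo, hi] by rejection; degenerate sd passes through
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic elderly cohort
#'
#' Samples a cohort table from the linear-Gaussian structural equation model
#' described in [generator_config()]. Sex is assigned deterministically by
#' count; age and Brain2ICV are drawn from sex-specific normals with the
#' configured linear age effect; APOE allele count, family history and
#' education are independent multinomial draws; the cognitive score is built
#' from its DAG parents (Brain2ICV, education) plus Gaussian noise. The same
#' seed and config always give an identical table.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `data.frame` (class `cohort_table`) with columns `subject_id`,
#'   `age`, `sex` (`"M"`/`"F"`), `apoe` (e4 allele count 0/1/2), `famad`
#'   (0/1), `education` (0-3), `cog_score`, `brain2icv`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 1))
#' table(cohort$sex)
generate_cohort <- function(config = generator_config(), seed = config$seed) {
  validate_generator_config(config)
  set.seed(seed)
  n <- config$n_male + config$n_female
  sex <- rep(c("M", "F"), times = c(config$n_male, config$n_female))
  key <- ifelse(sex == "M", "male", "female")

  age_mu <- config$age_mean_by_sex[key]
  age_sd <- config$age_sd_by_sex[key]
  age <- .rnorm_trunc(n, age_mu, age_sd, config$age_range[1], config$age_range[2])

  education <- sample(0:3, n, replace = TRUE, prob = config$education_probs)
  apoe <- sample(0:2, n, replace = TRUE, prob = config$apoe_probs)
  famad <- stats::rbinom(n, 1L, config$famad_prob)

  # Brain2ICV: sex-specific mean + centred age slope (+ optional education
  # slope) + residual noise shrunk so the marginal sd matches the config.
  slope <- config$age_effect_on_b2icv
  b_sd <- config$b2icv_sd_by_sex[key]
  resid_sd <- sqrt(pmax(0, b_sd^2 - slope^2 * config$age_sd_by_sex[key]^2))
  b_mu <- config$b2icv_mean_by_sex[key] + slope * (age - age_mu)
  if (config$edu_effect_on_b2icv != 0) {
    edu_mean <- sum(0:3 * config$education_probs)
    b_mu <- b_mu + config$edu_effect_on_b2icv * (education - edu_mean)
  }
  brain2icv <- .rnorm_trunc(n, b_mu, resid_sd, .Machine$double.eps, 1)

  lam <- config$cog_loadings
  lam_b <- if ("brain2icv" %in% names(lam)) lam[["brain2icv"]] else 0
  lam_e <- if ("education" %in% names(lam)) lam[["education"]] else 0
  resid_load <- sqrt(max(0, 1 - lam_b^2 - lam_e^2))
  cog_score <- config$cog_mean + config$cog_sd *
    (lam_b * .zscore(brain2icv) + lam_e * .zscore(education) +
       resid_load * stats::rnorm(n))

  cohort <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = unname(age),
    sex = sex,
    apoe = apoe,
    famad = famad,
    education = education,
    cog_score = unname(cog_score),
    brain2icv = unname(brain2icv),
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "seed") <- as.integer(seed)
  validate_cohort(cohort, age_range = config$age_range)
  cohort
}

#' Validate a cohort table
#'
#' Checks the structural invariants of an analysis-ready cohort: unique
#' subject ids, Brain2ICV in (0, 1], ages inside the plausible band and
#' education levels in 0-3.
#'
#' @param cohort A cohort `data.frame`.
#' @param age_range Allowed age band (default 60-95 years).
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort, age_range = c(60, 95)) {
  .check_cohort(cohort)
  if (anyDuplicated(cohort$subject_id)) {
    stop("duplicate subject_id in cohort", call. = FALSE)
  }
  if (any(cohort$brain2icv <= 0 | cohort$brain2icv > 1)) {
    stop("brain2icv values must lie in (0, 1]", call. = FALSE)
  }
  if (any(cohort$age < age_range[1] | cohort$age > age_range[2])) {
    stop("age values outside the plausible band [", age_range[1], ", ",
         age_range[2], "]", call. = FALSE)
  }
  if (!all(cohort$education %in% 0:3)) {
    stop("education must be an ordinal level in {0, 1, 2, 3}", call. = FALSE)
  }
  invisible(cohort)
}

#' Write FreeSurfer-style aseg.stats fixture files for a cohort
#'
#' Emits one `aseg.stats`-dialect text file per subject, containing `# Measure`
#' comment lines for the brain segmentation volume (BrainSegVol) and the
#' estimated total intracranial volume (eTIV). eTIV is drawn from the
#' configured sex-specific normal; BrainSegVol is set to
#' `brain2icv * eTIV` and written with six decimal places, so parsing the file
#' and forming the ratio recovers the subject's Brain2ICV to well beyond six
#' significant digits.
#'
#' @param cohort A cohort table.
#' @param config A [generator_config()] supplying the eTIV distribution.
#' @param out_dir Output directory (created if missing).
#' @param force Overwrite existing files? Default `FALSE`: colliding with an
#'   existing file is an error.
#' @param seed Seed for the eTIV draws; defaults to `config$seed + 1` so
#'   fixtures are reproducible but not correlated with the cohort draws.
#' @return A manifest `data.frame` with columns `subject_id`, `path`, `etiv`,
#'   `tbv`.
#' @export
write_freesurfer_fixtures <- function(cohort, config = generator_config(),
                                      out_dir, force = FALSE,
                                      seed = config$seed + 1L) {
  if (nrow(cohort) == 0L) {
    return(data.frame(subject_id = character(), path = character(),
                      etiv = numeric(), tbv = numeric(),
                      stringsAsFactors = FALSE))
  }
  .check_cohort(cohort, require = c("subject_id", "sex", "brain2icv"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  key <- ifelse(cohort$sex == "M", "male", "female")
  etiv <- round(.rnorm_trunc(nrow(cohort),
                             config$etiv_mean_by_sex[key], config$etiv_sd,
                             5e5, 2.5e6))
  tbv <- cohort$brain2icv * etiv
  paths <- file.path(out_dir, paste0(cohort$subject_id, ".aseg.stats"))
  existing <- paths[file.exists(paths)]
  if (length(existing) && !force) {
    stop("refusing to overwrite existing fixture file(s): ",
         paste(basename(utils::head(existing, 3)), collapse = ", "),
         if (length(existing) > 3) ", ..." else "",
         " (use force = TRUE)", call. = FALSE)
  }
  for (i in seq_len(nrow(cohort))) {
    lines <- c(
      "# Title Segmentation Statistics",
      paste0("# subjectname ", cohort$subject_id[i]),
      sprintf("# Measure BrainSeg, BrainSegVol, Brain Segmentation Volume, %.6f, mm^3",
              tbv[i]),
      sprintf("# Measure BrainSegNotVent, BrainSegVolNotVent, Brain Segmentation Volume Without Ventricles, %.6f, mm^3",
              tbv[i] * 0.981),
      sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %.6f, mm^3",
              etiv[i]),
      "# ColHeaders Index SegId NVoxels Volume_mm3 StructName"
    )
    writeLines(lines, paths[i])
  }
  data.frame(subject_id = cohort$subject_id, path = paths,
             etiv = unname(etiv), tbv = unname(tbv), stringsAsFactors = FALSE)
}

#' Read and write cohort CSV files
#'
#' The on-disk cohort format is a plain CSV with header
#' `subject_id,age,sex,apoe,famad,education,cog_score,brain2icv`, sex coded
#' `M`/`F`. `read_cohort_csv()` validates the result; missing values are not
#' permitted.
#'
#' @param cohort A cohort table.
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns a `cohort_table`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  .check_cohort(cohort)
  utils::write.csv(as.data.frame(cohort)[, c("subject_id", "age", "sex", "apoe",
                                             "famad", "education", "cog_score",
                                             "brain2icv")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_cohort(cohort)
  if (any(!stats::complete.cases(cohort))) {
    stop("cohort CSV contains missing values", call. = FALSE)
  }
  class(cohort) <- c("cohort_table", "data.frame")
  validate_cohort(cohort)
  cohort
}
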