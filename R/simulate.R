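#' Default synthetic-cohort generator configuration
#'
#' Ground-truth parameters for the synthetic populations the pipeline is
#' exercised on. Stratum segment means are shaped to the qualitative
#' pattern seen in MIBG normal cohorts -- anterior/lateral uptake high,
#' inferior wall lower with a further decrement in males, the Italian
#' stratum with lower anterior uptake and greater heterogeneity than the
#' Japanese stratum -- but are explicitly synthetic values, not
#' measurements. Disease models: coronary-artery disease (CAD) subtracts a
#' focal depth over one randomly chosen coronary territory; dilated
#' cardiomyopathy (DCM) subtracts a diffuse global decrement with inflated
#' per-segment noise. The heart-to-mediastinum ratio (HMR) is drawn per
#' subject around group means of 2.46/2.47 (no disease), 2.07/1.91 (CAD)
#' and 1.81/1.78 (DCM) for early/late phases.
#'
#' @return A nested list of class `generator_config` with elements
#'   `means` (per population x sex x phase, 17 values each, percent),
#'   `sds` (per population, percent), `male_inferior_decrement`,
#'   `it_anterior_decrement`, `cad` (`depth_range`, `hmr_mean`),
#'   `dcm` (`decrement_range`, `noise_inflation`, `hmr_mean`),
#'   `hmr` (`normal_mean`, `noise_sd`), `clip` (percent bounds), and
#'   `planar` (see [simulate_planar()]).
#' @export
default_generator_config <- function() {
  base <- c(84, 78, 74, 76, 82, 86,    # basal 1-6
            85, 79, 76, 77, 84, 87,    # mid 7-12
            83, 78, 76, 84,            # apical 13-16
            79)                        # apex
  inferior_full <- c(4, 10, 15)
  inferior_half <- c(3, 5, 9, 11)
  anterior_full <- c(1, 7, 13)
  anterior_half <- c(2, 8)
  male_dec <- 6; it_dec <- 4; late_shift <- 2
  mk <- function(population, sex, phase) {
    m <- base
    if (sex == "M") {
      m[inferior_full] <- m[inferior_full] - male_dec
      m[inferior_half] <- m[inferior_half] - male_dec / 2
    }
    if (population == "It") {
      m[anterior_full] <- m[anterior_full] - it_dec
      m[anterior_half] <- m[anterior_half] - it_dec / 2
    }
    if (phase == "late") m <- m - late_shift
    m
  }
  means <- list()
  for (pop in c("Jp", "It"))
    for (sex in c("M", "F"))
      for (phase in c("early", "late"))
        means[[paste(pop, sex, phase, sep = ".")]] <- mk(pop, sex, phase)
  structure(list(
    means = means,
    sds = list(Jp = rep(6, 17), It = rep(8, 17)),
    male_inferior_decrement = male_dec,
    it_anterior_decrement = it_dec,
    cad = list(depth_range = c(25, 50),
               hmr_mean = c(early = 2.07, late = 1.91)),
    dcm = list(decrement_range = c(3, 10), noise_inflation = 1.5,
               hmr_mean = c(early = 1.81, late = 1.78)),
    hmr = list(normal_mean = c(early = 2.46, late = 2.47), noise_sd = 0.25),
    clip = c(0, 120),
    planar = list(size = 64L, background = 50, blob_center = c(40, 33),
                  blob_sigma = 7, heart_radius = 9,
                  med_origin = c(4, 29), med_width = 8, med_height = 9)),
    class = "generator_config")
}

stratum_mean <- function(config, population, sex, phase) {
  key <- paste(population, sex, phase, sep = ".")
  m <- config$means[[key]]
  if (is.null(m))
    stop("config error: undefined stratum ", key, call. = FALSE)
  m
}

clip_profiles <- function(m, clip) {
  n_clip <- sum(m < clip[1] | m > clip[2])
  if (n_clip > 0)
    message(n_clip, " segment value(s) clipped to [", clip[1], ", ",
            clip[2], "]%")
  pmin(pmax(m, clip[1]), clip[2])
}

# Draw n subjects (early + late rows each). shift_mat is a 17 x n matrix of
# per-segment mean decrements (the disease effect); noise is N(0, sd_s *
# noise_factor), independent across segments/subjects; HMR is drawn per
# subject and phase around hmr_means, floored at 1.
draw_subjects <- function(config, n, population, sex, label, prefix,
                          shift_mat = NULL, noise_factor = 1,
                          hmr_means = NULL) {
  if (is.null(sex)) sex <- sample(c("M", "F"), n, replace = TRUE)
  else sex <- rep(sex, length.out = n)
  sds <- config$sds[[population]]
  if (is.null(sds))
    stop("config error: undefined population ", population, call. = FALSE)
  if (is.null(hmr_means)) hmr_means <- config$hmr$normal_mean
  if (is.null(shift_mat)) shift_mat <- matrix(0, 17, n)
  out <- vector("list", 2L)
  for (phase in c("early", "late")) {
    mu_by_sex <- vapply(c(M = "M", F = "F"), function(s)
      stratum_mean(config, population, s, phase), numeric(17))
    mu <- mu_by_sex[, sex, drop = FALSE] - shift_mat
    noise <- matrix(stats::rnorm(17L * n, 0, sds * noise_factor), 17L, n)
    u <- clip_profiles(mu + noise, config$clip)
    hmr <- pmax(1, hmr_means[[phase]] +
                   stats::rnorm(n, 0, config$hmr$noise_sd))
    df <- data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
                     population = population, sex = sex, phase = phase,
                     label = label, hmr = hmr)
    df[seg_cols()] <- as.data.frame(t(u))
    out[[if (phase == "early") 1L else 2L]] <- df
  }
  res <- rbind(out[[1L]], out[[2L]])
  res <- res[order(rep(seq_len(n), 2L), rep(1:2, each = n)), ]
  rownames(res) <- NULL
  res
}

#' Simulate a disease-free cohort
#'
#' Draws subjects from a stratum's per-segment normal model:
#' `u_is = clip(m*_s + e_is)` with `e_is ~ N(0, sd*_s)` independent across
#' segments and subjects, population/sex offsets applied to the mean before
#' noise. Each subject gets an early and a late row plus an HMR draw.
#' Results are reproducible: the generator uses R's default
#' Mersenne-Twister stream, seeded once per call when `seed` is given.
#'
#' @param config A [default_generator_config()] (possibly modified).
#' @param n Number of subjects.
#' @param population `"Jp"` or `"It"` (any population defined in the
#'   config).
#' @param sex `"M"`, `"F"`, or `NULL` for a random 1:1 mix.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @param prefix Subject-id prefix.
#' @return Cohort data frame (two rows per subject: early and late) with
#'   columns `subject_id`, `population`, `sex`, `phase`, `label`, `hmr`,
#'   `seg01`..`seg17`.
#' @export
simulate_normal <- function(config = default_generator_config(), n,
                            population = "Jp", sex = NULL, seed = NULL,
                            prefix = paste0(population, "N")) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_subjects(config, n, population, sex, label = "none", prefix = prefix)
}

#' Simulate a focal-denervation (CAD) cohort
#'
#' Starts from the normal model, then subtracts a defect depth, drawn
#' uniformly from `config$cad$depth_range`, from every segment of one
#' randomly chosen coronary territory (LAD, RCA or LCx; standard AHA
#' segment assignment), reflecting the sharply demarcated territorial
#' neuronal loss of coronary disease. The HMR is drawn around the CAD
#' group mean.
#'
#' @inheritParams simulate_normal
#' @return Cohort data frame as in [simulate_normal()], `label = "CAD"`.
#' @export
simulate_cad <- function(config = default_generator_config(), n,
                         population = "Jp", sex = NULL, seed = NULL,
                         prefix = "CAD") {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  territories <- sample(c("LAD", "RCA", "LCx"), n, replace = TRUE)
  depths <- stats::runif(n, config$cad$depth_range[1],
                         config$cad$depth_range[2])
  shift_mat <- vapply(seq_len(n), function(i) {
    s <- rep(0, 17)
    s[territory_segments(territories[i])] <- depths[i]
    s
  }, numeric(17))
  draw_subjects(config, n, population, sex, label = "CAD", prefix = prefix,
                shift_mat = shift_mat, hmr_means = config$cad$hmr_mean)
}

#' Simulate a diffuse-denervation (DCM) cohort
#'
#' Starts from the normal model, then subtracts a global decrement (all 17
#' segments), drawn uniformly from `config$dcm$decrement_range`, and
#' inflates the per-segment noise by `config$dcm$noise_inflation`,
#' reflecting the diffuse, heterogeneous sympathetic dysfunction of
#' dilated cardiomyopathy. The HMR is drawn around the DCM group mean
#' (lower than CAD's).
#'
#' @inheritParams simulate_normal
#' @return Cohort data frame as in [simulate_normal()], `label = "DCM"`.
#' @export
simulate_dcm <- function(config = default_generator_config(), n,
                         population = "Jp", sex = NULL, seed = NULL,
                         prefix = "DCM") {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  decs <- stats::runif(n, config$dcm$decrement_range[1],
                       config$dcm$decrement_range[2])
  shift_mat <- matrix(rep(decs, each = 17L), 17L, n)
  draw_subjects(config, n, population, sex, label = "DCM", prefix = prefix,
                shift_mat = shift_mat,
                noise_factor = config$dcm$noise_inflation,
                hmr_means = config$dcm$hmr_mean)
}

#' Synthesize a planar count image with a target HMR
#'
#' Builds a background level plus a 2D Gaussian cardiac blob whose
#' amplitude is solved exactly so that, before Poisson noise, the
#' heart-ROI mean over the mediastinum-ROI mean equals `target_hmr`.
#' With `poisson = TRUE` each pixel is replaced by a Poisson draw with
#' that intensity.
#'
#' @param target_hmr Desired noise-free HMR (>= 1).
#' @param config Generator config; the `planar` element controls geometry
#'   (image size, background counts, blob center/width, ROI placement).
#' @param poisson Add Poisson counting noise?
#' @return A list with `image` (matrix) and `rois` (the [roi_pair()] the
#'   target was solved for), ready for [compute_hmr()].
#' @export
simulate_planar <- function(target_hmr,
                            config = default_generator_config(),
                            poisson = TRUE) {
  pc <- config$planar
  if (target_hmr < 1)
    stop("config error: target HMR below 1 is not attainable with a ",
         "non-negative blob", call. = FALSE)
  n <- pc$size
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  g <- exp(-((rows - pc$blob_center[1])^2 + (cols - pc$blob_center[2])^2) /
             (2 * pc$blob_sigma^2))
  rois <- roi_pair(heart_center = pc$blob_center,
                   heart_radius = pc$heart_radius,
                   med_origin = pc$med_origin,
                   med_width = pc$med_width, med_height = pc$med_height)
  masks <- roi_masks(matrix(0, n, n), rois)
  gh <- mean(g[masks$heart]); gm <- mean(g[masks$med])
  denom <- gh - target_hmr * gm
  if (denom <= 0)
    stop("config error: target HMR not attainable with this geometry",
         call. = FALSE)
  amp <- pc$background * (target_hmr - 1) / denom
  img <- pc$background + amp * g
  if (poisson)
    img <- matrix(stats::rpois(n * n, img), n, n)
  list(image = img, rois = rois)
}

#' Simulate the full study: normal, validation and disease cohorts
#'
#' Convenience wrapper drawing the study populations in one seeded call:
#' two disease-free database cohorts (Japanese and Italian), plus a
#' validation cohort of CAD and DCM patients and disease-free controls.
#'
#' @inheritParams simulate_normal
#' @param n_jp,n_it Database cohort sizes (defaults 55 and 33).
#' @param n_cad,n_dcm,n_control Validation group sizes (defaults 19, 8,
#'   12).
#' @param seed Integer seed for the whole draw.
#' @return List with cohort data frames `jp_normals`, `it_normals`,
#'   `validation`, and the `config` and `seed` used.
#' @export
simulate_study <- function(config = default_generator_config(),
                           n_jp = 55, n_it = 33, n_cad = 19, n_dcm = 8,
                           n_control = 12, seed = 1) {
  set.seed(seed)
  jp <- simulate_normal(config, n_jp, "Jp", prefix = "JPN")
  it <- simulate_normal(config, n_it, "It", prefix = "ITN")
  val <- rbind(
    simulate_cad(config, n_cad, population = "Jp", prefix = "VCAD"),
    simulate_dcm(config, n_dcm, population = "Jp", prefix = "VDCM"),
    simulate_normal(config, n_control, "It", prefix = "VCTL"))
  list(jp_normals = jp, it_normals = it, validation = val,
       config = config, seed = seed)
}
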