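# Cohorts are plain data frames with one row per subject-phase:
#   subject_id, population, sex, phase, seg01..seg17  (+ optional label, hmr)
# Segment values are percent-of-reference as produced by normalize_profile().

seg_cols <- function() sprintf("seg%02d", 1:17)

profile_matrix <- function(cohort) {
  missing <- setdiff(seg_cols(), names(cohort))
  if (length(missing))
    stop("cohort is missing segment columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- as.matrix(cohort[, seg_cols()])
  if (any(!is.finite(m)) || any(m < 0))
    stop("segment values must be finite and non-negative", call. = FALSE)
  m
}

#' Build a stratified normal database from a cohort of profiles
#'
#' Summarizes a cohort of normalized segmental profiles into the central
#' reference artifact: per-segment mean and sample standard deviation
#' (n - 1 denominator) of percent uptake, with the stratum (population,
#' sex, phase) recorded. Dispersion is always stored as an SD; databases
#' whose source provided a mean deviation are converted on load (see
#' [md_to_sd()]) and flagged via `md_converted`.
#'
#' @param cohort Data frame with columns `subject_id`, `population`, `sex`,
#'   `phase` and `seg01`..`seg17` (percent uptake).
#' @param population,sex,phase Optional stratum filters; `NULL` keeps all
#'   rows. `phase` defaults to requiring a single phase in the data.
#' @param label Population label stored in the database (defaults to the
#'   filtered populations joined without separator, e.g. `"JpIt"`).
#' @return An object of class `normal_database`: list with `segment`
#'   (1..17), `mean`, `sd`, `n`, `population`, `sex`, `phase`,
#'   `md_converted`.
#' @examples
#' cohort <- simulate_normal(default_generator_config(), n = 20,
#'                           population = "Jp", seed = 1)
#' ndb <- build_ndb(cohort, phase = "late")
#' ndb
#' @export
build_ndb <- function(cohort, population = NULL, sex = NULL, phase = NULL,
                      label = NULL) {
  if (!is.null(population))
    cohort <- cohort[cohort$population %in% population, , drop = FALSE]
  if (!is.null(sex))
    cohort <- cohort[cohort$sex %in% sex, , drop = FALSE]
  if (!is.null(phase))
    cohort <- cohort[cohort$phase %in% phase, , drop = FALSE]
  phases <- unique(cohort$phase)
  if (length(phases) != 1L)
    stop("stratum error: cohort must contain exactly one phase after ",
         "filtering (found: ", paste(phases, collapse = ", "), ")",
         call. = FALSE)
  if (nrow(cohort) < 2L)
    stop("insufficient data: a normal database needs at least 2 subjects",
         call. = FALSE)
  m <- profile_matrix(cohort)
  if (is.null(label)) {
    pops <- unique(as.character(cohort$population))
    label <- paste(if (!is.null(population)) population else pops,
                   collapse = "")
  }
  structure(list(segment = 1:17,
                 mean = unname(colMeans(m)),
                 sd = unname(apply(m, 2, stats::sd)),
                 n = nrow(cohort),
                 population = label,
                 sex = if (is.null(sex)) "all" else paste(sex, collapse = ""),
                 phase = phases,
                 md_converted = FALSE),
            class = "normal_database")
}

#' @export
print.normal_database <- function(x, digits = 2, ...) {
  cat(sprintf("normal_database: %s / sex %s / %s phase, n = %d%s\n",
              x$population, x$sex, x$phase, x$n,
              if (x$md_converted) " (dispersion converted from mean deviation)"
              else ""))
  print(data.frame(segment = x$segment, name = segment_names(),
                   mean = round(x$mean, digits), sd = round(x$sd, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Convert a mean deviation to a standard deviation
#'
#' For a normal distribution the mean absolute deviation about the mean is
#' `sigma * sqrt(2 / pi)`; databases that store dispersion as a mean
#' deviation are therefore converted to SD units by multiplying by
#' `sqrt(pi / 2)` (about 1.2533).
#'
#' @param md Non-negative mean deviation(s).
#' @return Standard deviation(s) on the same scale.
#' @export
md_to_sd <- function(md) {
  md <- as.numeric(md)
  if (any(!is.finite(md)) || any(md < 0))
    stop("mean deviation must be finite and non-negative", call. = FALSE)
  md * sqrt(pi / 2)
}

#' Pool two cohorts into a combined normal database
#'
#' Pools at the subject level: the combined database equals [build_ndb()]
#' on the concatenated cohorts, so each cohort contributes in proportion to
#' its size (no reweighting).
#'
#' @param cohort_a,cohort_b Cohort data frames sharing a phase and
#'   normalization policy.
#' @param label Population label of the pooled database (default: the two
#'   cohorts' labels concatenated, e.g. `"JpIt"`).
#' @inheritParams build_ndb
#' @return A `normal_database`.
#' @export
combine_ndbs <- function(cohort_a, cohort_b, phase = NULL, sex = NULL,
                         label = NULL) {
  common <- intersect(names(cohort_a), names(cohort_b))
  need <- c("subject_id", "population", "sex", "phase", seg_cols())
  if (!all(need %in% common))
    stop("cohorts must share the standard profile columns", call. = FALSE)
  pooled <- rbind(cohort_a[, common, drop = FALSE],
                  cohort_b[, common, drop = FALSE])
  if (is.null(label))
    label <- paste(unique(c(as.character(cohort_a$population),
                            as.character(cohort_b$population))),
                   collapse = "")
  build_ndb(pooled, phase = phase, sex = sex, label = label)
}

#' Segment-wise one-way ANOVA across normal databases
#'
#' Compares two or more normal databases segment by segment using a one-way
#' analysis of variance computed from summary statistics only (group means,
#' SDs and ns) -- the raw subject data behind an external database is not
#' available, so between- and within-group sums of squares are reconstructed
#' from the summaries. With two groups the F statistic equals the square of
#' the pooled-variance t statistic.
#'
#' @param ndbs List of two or more `normal_database` objects (all same
#'   phase).
#' @param alpha Significance level for the per-segment flag (default 0.05).
#' @return A data frame of class `segment_comparison`: one row per segment
#'   with the group means/SDs/ns, `F`, `p` and `significant`.
#' @export
compare_ndbs <- function(ndbs, alpha = 0.05) {
  if (!is.list(ndbs) || length(ndbs) < 2L ||
      !all(vapply(ndbs, inherits, logical(1), "normal_database")))
    stop("ndbs must be a list of >= 2 normal_database objects",
         call. = FALSE)
  ns <- vapply(ndbs, `[[`, numeric(1), "n")
  if (any(ns < 2))
    stop("insufficient data: every group needs n >= 2", call. = FALSE)
  phases <- unique(vapply(ndbs, `[[`, character(1), "phase"))
  if (length(phases) != 1L)
    stop("stratum error: databases must share a phase", call. = FALSE)
  labels <- vapply(ndbs, `[[`, character(1), "population")
  k <- length(ndbs)
  out <- data.frame(segment = 1:17)
  for (g in seq_len(k)) {
    out[[paste0("mean_", labels[g])]] <- ndbs[[g]]$mean
    out[[paste0("sd_", labels[g])]] <- ndbs[[g]]$sd
    out[[paste0("n_", labels[g])]] <- ns[g]
  }
  means <- vapply(ndbs, `[[`, numeric(17), "mean")
  sds <- vapply(ndbs, `[[`, numeric(17), "sd")
  if (any(!is.finite(sds)))
    stop("insufficient data: undefined SD in a group", call. = FALSE)
  N <- sum(ns)
  grand <- as.numeric(means %*% ns) / N
  ssb <- rowSums(sweep(sweep(means, 1, grand)^2, 2, ns, `*`))
  ssw <- rowSums(sweep(sds^2, 2, ns - 1, `*`))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  p[f == 0] <- 1
  out$F <- f
  out$p <- p
  out$significant <- p < alpha
  class(out) <- c("segment_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "phase") <- phases
  out
}

#' Write / read a normal database (CSV plus JSON sidecar)
#'
#' The CSV holds one row per segment (`segment`, `mean`, `sd`) with full
#' double precision (17 significant digits) so the round trip is bit-exact;
#' the sidecar `<path>.json` records the stratum metadata (`population`,
#' `sex`, `phase`, `n`, `md_converted`, and optionally `dispersion`).
#' A sidecar declaring `dispersion: "mean_deviation"` is converted to SD on
#' read via [md_to_sd()] and flagged.
#'
#' @param ndb A `normal_database`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_ndb()` returns `path` invisibly; `read_ndb()` returns a
#'   `normal_database`.
#' @export
write_ndb <- function(ndb, path) {
  stopifnot(inherits(ndb, "normal_database"))
  df <- data.frame(segment = ndb$segment,
                   mean = sprintf("%.17g", ndb$mean),
                   sd = sprintf("%.17g", ndb$sd))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(population = ndb$population, sex = ndb$sex, phase = ndb$phase,
               n = ndb$n, md_converted = ndb$md_converted, dispersion = "sd")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ndb
#' @export
read_ndb <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (nrow(df) != 17L)
    stop("normal-database CSV must have 17 segment rows", call. = FALSE)
  df <- df[order(df$segment), ]
  sd <- as.numeric(df$sd)
  md_converted <- isTRUE(meta$md_converted)
  if (identical(meta$dispersion, "mean_deviation")) {
    sd <- md_to_sd(sd)
    md_converted <- TRUE
  }
  structure(list(segment = 1:17, mean = as.numeric(df$mean), sd = sd,
                 n = as.integer(meta$n), population = meta$population,
                 sex = meta$sex, phase = meta$phase,
                 md_converted = md_converted),
            class = "normal_database")
}
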