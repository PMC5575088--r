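#' Analysis configuration
#'
#' Bundles every tunable of the quantification pipeline. Measurement levels
#' follow the ascending-aorta convention: level 1 just above the aortic
#' valve, level 2 caudally and level 3 cranially to the pulmonary artery
#' bifurcation; here each level is an explicit plane (origin + normal).
#'
#' @param levels Named list of planes, each `list(origin =, normal =)`.
#' @param eta Dynamic viscosity, Pa.s (default 3.5e-3).
#' @param hv_threshold_frac High-velocity threshold for eccentricity
#'   grading, fraction of the section peak.
#' @param rotation_none_threshold Upper limit of the `none` rotation grade,
#'   degrees.
#' @param murray_exponent Murray's-law exponent.
#' @param sample_spacing Cross-section lattice pitch, mm.
#' @param probe_depth Wall-probe depth for WSS_SA, mm.
#' @param wss_level Level whose `v_mean`/`r_mean` feed WSS_HP (default
#'   "level2").
#' @param sfd_suspect_range SFD plausibility envelope; values outside are
#'   flagged, not rejected.
#' @param n_endpoints Validation endpoints for the Bonferroni correction.
#' @param seed Integer seed for any stochastic stage.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(levels = NULL, eta = ETA_BLOOD,
                            hv_threshold_frac = 0.70,
                            rotation_none_threshold = 90,
                            murray_exponent = 3,
                            sample_spacing = 0.5,
                            probe_depth = 1,
                            wss_level = "level2",
                            sfd_suspect_range = c(0, 2.5),
                            n_endpoints = 6,
                            seed = 1L) {
  stopifnot(eta > 0, hv_threshold_frac > 0, hv_threshold_frac <= 1,
            rotation_none_threshold >= 0, rotation_none_threshold <= 360,
            sample_spacing > 0, probe_depth > 0, n_endpoints >= 1)
  structure(list(levels = levels, eta = eta,
                 hv_threshold_frac = hv_threshold_frac,
                 rotation_none_threshold = rotation_none_threshold,
                 murray_exponent = murray_exponent,
                 sample_spacing = sample_spacing,
                 probe_depth = probe_depth,
                 wss_level = wss_level,
                 sfd_suspect_range = sfd_suspect_range,
                 n_endpoints = n_endpoints,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Write / read an analysis configuration as YAML
#' @param config An [analysis_config()].
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$levels <- lapply(raw$levels, function(l)
    list(origin = as.numeric(l$origin), normal = as.numeric(l$normal)))
  if (length(raw$levels) == 0) raw$levels <- NULL
  do.call(analysis_config, raw[!vapply(raw, is.null, TRUE)])
}

#' Run the full quantification and validation pipeline
#'
#' Chains field -> cross-sections -> flow metrics -> (optional) anatomical
#' comparison -> (optional) cohort statistics into a single deterministic
#' report: per-level lumen geometry, SFD, WSS_HP, eccentricity grades;
#' field-wide peak velocity; WSS_SA over the wall; helicity/vorticity
#' rotation grades; mean surface and Hausdorff distances when a second
#' surface is given; the paired statistical protocol when cohorts are given.
#'
#' @param field A [velocity_field()].
#' @param surface The vessel wall [tri_surface()].
#' @param config An [analysis_config()] with at least one level.
#' @param cl Optional [centerline()] (needed for rotation grading).
#' @param surface2 Optional second surface for the anatomical block.
#' @param align Rigidly align `surface2` onto `surface` before measuring
#'   distances.
#' @param cohorts Optional named list of [paired_cohort()] objects.
#' @param grade_tables Optional named list of grade tables for
#'   [friedman_grades()].
#' @return An object of class `run_report`.
#' @export
run_pipeline <- function(field, surface, config, cl = NULL,
                         surface2 = NULL, align = TRUE,
                         cohorts = NULL, grade_tables = NULL) {
  if (is.null(config$levels) || !length(config$levels))
    stop_af("config carries no measurement levels")
  warnings_log <- character(0)
  lev <- purrr::imap(config$levels, function(pl, nm) {
    sec <- tryCatch(
      extract_cross_section(surface, pl$origin, pl$normal, field = field,
                            sample_spacing = config$sample_spacing),
      error = function(e) stop_af("stage 'section %s' failed: %s", nm,
                                  conditionMessage(e)))
    sfd <- secondary_flow_degree(sec)
    if (sfd < config$sfd_suspect_range[1] || sfd > config$sfd_suspect_range[2])
      warnings_log <<- c(warnings_log,
                         sprintf("level %s: SFD %.3g outside plausibility envelope [%g, %g]",
                                 nm, sfd, config$sfd_suspect_range[1], config$sfd_suspect_range[2]))
    ecc <- grade_eccentricity(sec, config$hv_threshold_frac)
    v_mean <- mean_through_velocity(sec)
    tibble(level = nm,
           area_mm2 = sec$area, r_mean_mm = sec$r_mean,
           v_mean = v_mean,
           peak_velocity = max(sqrt(sec$samples$v_through[sec$samples$lumen]^2 +
                                    sec$samples$v_in1[sec$samples$lumen]^2 +
                                    sec$samples$v_in2[sec$samples$lumen]^2)),
           sfd = sfd,
           wss_hp = wss_hagen_poiseuille(v_mean, sec$r_mean / 1000, config$eta),
           eccentricity = as.character(ecc$grade),
           hv_area_fraction = ecc$hv_area_fraction,
           hv_centroid_offset = ecc$hv_centroid_offset)
  })
  levels_tbl <- dplyr::bind_rows(lev)
  wss <- wss_surface_averaged(field, surface, eta = config$eta,
                              probe_depth = config$probe_depth)
  wl <- if (config$wss_level %in% levels_tbl$level) config$wss_level else levels_tbl$level[1]
  wrow <- levels_tbl[levels_tbl$level == wl, ]
  rotation <- NULL
  if (!is.null(cl)) {
    helic <- rotation_angle(field, cl, seed_radius = wrow$r_mean_mm / 2)
    rotation <- tibble(pattern = "helicity", rotation_deg = helic,
                       grade = as.character(grade_rotation(helic, config$rotation_none_threshold)))
  }
  anatomy <- NULL
  if (!is.null(surface2)) {
    tr <- NULL
    s2 <- surface2
    if (align) {
      tr <- rigid_align(s2, surface)
      s2 <- transform_surface(s2, tr$rotation, tr$translation)
    }
    anatomy <- list(distance = surface_distance(surface, s2), transform = tr)
  }
  stats_tbl <- NULL
  if (!is.null(cohorts)) {
    stats_tbl <- dplyr::bind_rows(purrr::imap(cohorts, function(co, nm) {
      # zero-variance differences admit no normality screen; the t-test
      # branch handles them explicitly downstream
      ks <- tryCatch(suppressWarnings(ks_normality(co$predicted - co$observed)),
                     error = function(e) list(statistic = NA_real_, p = NA_real_))
      tt <- paired_ttest(co)
      rg <- regression_through_origin(co)
      ba <- bland_altman(co)
      tibble(metric = nm, n = tt$n,
             ks_p = ks$p, t = tt$t, df = tt$df, p = tt$p_two_sided,
             slope = rg$slope, r_squared = rg$r_squared,
             bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high)
    }))
  }
  grades_tbl <- NULL
  if (!is.null(grade_tables)) {
    grades_tbl <- dplyr::bind_rows(purrr::imap(grade_tables, function(g, nm) {
      fr <- friedman_grades(g)
      tibble(pattern = nm, statistic = fr$statistic, df = fr$df, p = fr$p)
    }))
  }
  structure(list(
    levels = levels_tbl,
    peak_velocity = peak_velocity(field),
    wss = wss,
    wss_hp = wrow$wss_hp, wss_level = wl,
    rotation = rotation,
    anatomy = anatomy,
    cohort_stats = stats_tbl,
    grade_stats = grades_tbl,
    alpha_adjusted = as.numeric(bonferroni_alpha(0.05, config$n_endpoints)),
    warnings = warnings_log,
    provenance = list(field_hash = object_hash_(field),
                      surface_hash = object_hash_(surface),
                      config = unclass(config),
                      tool_version = as.character(utils::packageVersion("aortaflow")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== aortaflow run report ==\n")
  cat(sprintf("peak velocity: %.3g m/s | WSS_SA: %.3g Pa | WSS_HP(%s): %.3g Pa\n",
              x$peak_velocity, x$wss$wss_sa, x$wss_level, x$wss_hp))
  print(x$levels)
  if (!is.null(x$rotation)) print(x$rotation)
  if (!is.null(x$anatomy)) print(x$anatomy$distance)
  if (!is.null(x$cohort_stats)) {
    cat(sprintf("paired validation (significance at p < %.4f):\n", x$alpha_adjusted))
    print(x$cohort_stats)
  }
  if (!is.null(x$grade_stats)) print(x$grade_stats)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Serialise a run report to JSON
#' @param report A `run_report`.
#' @param path Output path.
#' @param strip_timestamp Drop the timestamp (for byte-stable reports).
#' @export
write_report_json <- function(report, path, strip_timestamp = FALSE) {
  r <- unclass(report)
  r$wss <- tidy(r$wss)
  if (!is.null(r$anatomy)) {
    r$anatomy <- list(distance = tidy(r$anatomy$distance),
                      rotation_deg = if (!is.null(r$anatomy$transform))
                        rotation_angle_of(r$anatomy$transform$rotation))
  }
  if (strip_timestamp) r$provenance$timestamp <- NULL
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
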