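#' Cross-section area of a spherical vesicle
#'
#' `pi * (d/2)^2` with the diameter in nm and the area in square
#' micrometers; an 80 nm vesicle has a cross-section of ~0.005 um^2, the
#' bulk-endosome area threshold.
#'
#' @param diameter_nm Vesicle diameter(s) in nm.
#' @return Area(s) in um^2.
#' @export
vesicle_area_um2 <- function(diameter_nm) {
  pi * (diameter_nm / 2000)^2
}

# The 80 nm-vesicle cross-section threshold (um^2).
bulk_area_threshold_um2 <- function() vesicle_area_um2(80)

#' Is a vesicle a bulk endosome?
#'
#' The size rule for endocytic bulk endosomes: diameter of 80 nm or more,
#' or cross-section area exceeding that of an 80 nm vesicle
#' (pi * 0.04^2 ~ 0.005 um^2). Either criterion suffices when both
#' measurements are present; the diameter boundary (exactly 80 nm) is
#' assigned to bulk. Vectorized; a row with neither measurement is an
#' error.
#'
#' @param diameter_nm Diameter(s) in nm (NA when unmeasured).
#' @param area_um2 Cross-section area(s) in um^2 (NA when unmeasured).
#' @return Logical vector.
#' @examples
#' is_bulk_endosome(diameter_nm = c(80, 79), area_um2 = c(NA, 0.0049))
#' @export
is_bulk_endosome <- function(diameter_nm = NULL, area_um2 = NULL) {
  n <- max(length(diameter_nm), length(area_um2))
  d <- rep_len(diameter_nm %||% NA_real_, n)
  a <- rep_len(area_um2 %||% NA_real_, n)
  if (any(is.na(d) & is.na(a))) {
    stop_invalid("Each vesicle needs a diameter or an area.")
  }
  by_d <- !is.na(d) & d >= 80
  by_a <- !is.na(a) & a > bulk_area_threshold_um2()
  by_d | by_a
}

#' Per-profile HRP(+) vesicle density and bulk-endosome area
#'
#' For each synaptic cross-section profile: the number of HRP-labeled
#' regular vesicles per square micrometer and the summed bulk-endosome
#' cross-section area per square micrometer. Bulk endosomes (size rule of
#' [is_bulk_endosome()]) are excluded from the regular-vesicle count, and
#' by default only HRP(+) bulk endosomes enter the area sum (they mark
#' endocytosis during the labeling epoch).
#'
#' @param vesicles A tibble with `profile_id`, `diameter_nm` and/or
#'   `area_um2`, `hrp` (logical), and optionally `condition`, `timepoint`.
#' @param profiles A tibble with `profile_id`, `profile_area_um2`, and
#'   optionally `condition`, `timepoint`; profiles without vesicles get
#'   zero densities.
#' @param bulk_hrp_only Count only HRP(+) bulk endosomes in the area sum.
#' @return A tibble with one row per profile: `profile_id`,
#'   `hrp_density_per_um2`, `bulk_area_per_um2`, plus any grouping columns
#'   present in `profiles`.
#' @export
em_profile_densities <- function(vesicles, profiles, bulk_hrp_only = TRUE) {
  if (any(profiles$profile_area_um2 <= 0)) {
    stop_invalid("Every `profile_area_um2` must be > 0.")
  }
  if (nrow(vesicles) > 0) {
    if (!"area_um2" %in% names(vesicles)) vesicles$area_um2 <- NA_real_
    if (!"diameter_nm" %in% names(vesicles)) vesicles$diameter_nm <- NA_real_
    area <- ifelse(is.na(vesicles$area_um2),
                   vesicle_area_um2(vesicles$diameter_nm), vesicles$area_um2)
    bulk <- is_bulk_endosome(vesicles$diameter_nm, area)
    per_profile <- tibble(profile_id = vesicles$profile_id,
                          hrp = vesicles$hrp, bulk = bulk, area = area) |>
      dplyr::group_by(.data$profile_id) |>
      dplyr::summarise(
        n_hrp_regular = sum(.data$hrp & !.data$bulk),
        bulk_area_um2 = sum(.data$area[.data$bulk &
                                         (.data$hrp | !bulk_hrp_only)]),
        .groups = "drop"
      )
  } else {
    per_profile <- tibble(profile_id = character(), n_hrp_regular = integer(),
                          bulk_area_um2 = numeric())
  }
  profiles |>
    dplyr::left_join(per_profile, by = "profile_id") |>
    dplyr::mutate(
      n_hrp_regular = dplyr::coalesce(.data$n_hrp_regular, 0L),
      bulk_area_um2 = dplyr::coalesce(.data$bulk_area_um2, 0),
      hrp_density_per_um2 = .data$n_hrp_regular / .data$profile_area_um2,
      bulk_area_per_um2 = .data$bulk_area_um2 / .data$profile_area_um2
    ) |>
    dplyr::select(-dplyr::any_of(c("n_hrp_regular", "bulk_area_um2")))
}

#' Condition/timepoint means of the EM densities
#'
#' Aggregates [em_profile_densities()] output over profiles: mean and
#' s.e.m. per condition and timepoint (the unit of analysis is the
#' synaptic profile).
#'
#' @param densities Output of [em_profile_densities()].
#' @param group_by Grouping columns present in `densities`.
#' @return A tibble of per-group means and s.e.m. values.
#' @export
em_group_densities <- function(densities,
                               group_by = c("condition", "timepoint")) {
  group_by <- intersect(group_by, names(densities))
  densities |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_profiles = dplyr::n(),
      hrp_density_mean = mean(.data$hrp_density_per_um2),
      hrp_density_sem = sd(.data$hrp_density_per_um2) / sqrt(dplyr::n()),
      bulk_area_mean = mean(.data$bulk_area_per_um2),
      bulk_area_sem = sd(.data$bulk_area_per_um2) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Simulate EM vesicle tables for one or more condition/timepoint groups
#'
#' Generates per-profile vesicle records emulating an HRP-uptake EM
#' experiment: per profile, a cross-section area, Poisson counts of
#' HRP(+) and HRP(-) regular vesicles (normal diameters well below the
#' 80 nm bulk threshold) and of HRP(+) bulk endosomes (log-normal
#' diameters at or above 80 nm), with `area_um2 = pi (d/2)^2` for every
#' vesicle.
#'
#' @param groups A tibble with one row per group and columns `condition`,
#'   `timepoint`, and optionally `n_profiles` (default 120),
#'   `hrp_pos_rate_per_um2` (HRP(+) regular vesicles per um^2, default 2),
#'   `hrp_neg_rate_per_um2` (default 20), `bulk_rate_per_um2` (default
#'   0.5), `profile_area_mean_um2` (default 0.35).
#' @param vesicle_diam_mean_nm,vesicle_diam_sd_nm Regular-vesicle diameter
#'   distribution (nm).
#' @param bulk_diam_meanlog,bulk_diam_sdlog Log-normal parameters of the
#'   bulk-endosome diameter above the 80 nm threshold.
#' @param seed Optional integer seed.
#' @return A list of two tibbles: `vesicles` (`profile_id`, `vesicle_id`,
#'   `diameter_nm`, `area_um2`, `hrp`, `condition`, `timepoint`) and
#'   `profiles` (`profile_id`, `profile_area_um2`, `condition`,
#'   `timepoint`).
#' @export
simulate_em_tables <- function(groups,
                               vesicle_diam_mean_nm = 42,
                               vesicle_diam_sd_nm = 5,
                               bulk_diam_meanlog = log(60),
                               bulk_diam_sdlog = 0.6,
                               seed = NULL) {
  defaults <- tibble(n_profiles = 120L, hrp_pos_rate_per_um2 = 2,
                     hrp_neg_rate_per_um2 = 20, bulk_rate_per_um2 = 0.5,
                     profile_area_mean_um2 = 0.35)
  for (nm in names(defaults)) {
    if (!nm %in% names(groups)) groups[[nm]] <- defaults[[nm]]
  }
  if (any(groups$n_profiles < 1)) stop_invalid("`n_profiles` must be >= 1.")
  rate_cols <- c("hrp_pos_rate_per_um2", "hrp_neg_rate_per_um2",
                 "bulk_rate_per_um2")
  if (any(unlist(groups[rate_cols]) < 0)) stop_invalid("Rates must be >= 0.")

  with_seed_if(seed, {
    ves_rows <- list()
    prof_rows <- list()
    for (g in seq_len(nrow(groups))) {
      gr <- groups[g, ]
      for (p in seq_len(gr$n_profiles)) {
        pid <- sprintf("%s_%s_p%03d", gr$condition, gr$timepoint, p)
        # Profile areas: gamma with CV ~0.4, typical bouton cross-sections.
        area_p <- stats::rgamma(1, shape = 6,
                                scale = gr$profile_area_mean_um2 / 6)
        prof_rows[[length(prof_rows) + 1L]] <- tibble(
          profile_id = pid, profile_area_um2 = area_p,
          condition = gr$condition, timepoint = gr$timepoint
        )
        n_pos <- rpois(1, gr$hrp_pos_rate_per_um2 * area_p)
        n_neg <- rpois(1, gr$hrp_neg_rate_per_um2 * area_p)
        n_bulk <- rpois(1, gr$bulk_rate_per_um2 * area_p)
        n_reg <- n_pos + n_neg
        if (n_reg + n_bulk == 0L) next
        d_reg <- if (n_reg > 0) {
          pmin(pmax(rnorm(n_reg, vesicle_diam_mean_nm, vesicle_diam_sd_nm),
                    20), 79.9)
        } else {
          numeric(0)
        }
        d_bulk <- if (n_bulk > 0) {
          80 + rlnorm(n_bulk, bulk_diam_meanlog, bulk_diam_sdlog)
        } else {
          numeric(0)
        }
        d <- c(d_reg, d_bulk)
        ves_rows[[length(ves_rows) + 1L]] <- tibble(
          profile_id = pid,
          vesicle_id = sprintf("%s_v%03d", pid, seq_along(d)),
          diameter_nm = d,
          area_um2 = vesicle_area_um2(d),
          hrp = c(rep(TRUE, n_pos), rep(FALSE, n_neg), rep(TRUE, n_bulk)),
          condition = gr$condition, timepoint = gr$timepoint
        )
      }
    }
    list(
      vesicles = if (length(ves_rows)) dplyr::bind_rows(ves_rows) else
        tibble(profile_id = character(), vesicle_id = character(),
               diameter_nm = numeric(), area_um2 = numeric(),
               hrp = logical(), condition = character(),
               timepoint = character()),
      profiles = dplyr::bind_rows(prof_rows)
    )
  })
}
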