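#' Consumer profile for dietary exposure
#'
#' Body weight and weekly seafood intake of one consumer group under one
#' consumption regime — either the NHS recommendation for seafood
#' consumption or the NDNS survey of actual consumption.
#'
#' @param label consumer group label (`"men"`, `"women"`, `"children"`,
#'   `"pregnant women"` or custom).
#' @param body_weight_kg body weight `W`, kg.
#' @param weekly_intake_kg named numeric vector of weekly seafood intake per
#'   food group (kg week^-1), names drawn from `"oily_fish"`, `"white_fish"`,
#'   `"shellfish"`.
#' @param regime `"NHS"` (recommended) or `"NDNS"` (reported actual).
#' @return object of class `consumer_profile`.
#' @export
consumer_profile <- function(label, body_weight_kg, weekly_intake_kg,
                             regime = c("NHS", "NDNS")) {
  regime <- match.arg(regime)
  if (body_weight_kg <= 0) stop("body weight must be positive")
  if (any(weekly_intake_kg < 0)) stop("intakes must be nonnegative")
  if (is.null(names(weekly_intake_kg))) {
    stop("weekly_intake_kg must be named by seafood group")
  }
  structure(list(label = label, body_weight_kg = body_weight_kg,
                 weekly_intake_kg = weekly_intake_kg, regime = regime),
            class = "consumer_profile")
}

#' @export
print.consumer_profile <- function(x, ...) {
  cat(sprintf("Consumer profile: %s (%s regime), %g kg\n",
              x$label, x$regime, x$body_weight_kg))
  for (nm in names(x$weekly_intake_kg)) {
    cat(sprintf("  %-12s %.3g kg week^-1\n", nm, x$weekly_intake_kg[[nm]]))
  }
  invisible(x)
}

#' Convert a daily reference concentration to its weekly form
#'
#' The EPA methylmercury reference concentration of 0.0001 mg kg^-1 d^-1
#' corresponds to 0.0007 mg kg^-1 week^-1.
#'
#' @param rfc_daily mg kg^-1 d^-1.
#' @return mg kg^-1 week^-1.
#' @export
rfc_daily_to_weekly <- function(rfc_daily) rfc_daily * 7

#' Risk-assessment parameters
#'
#' @param absorption methylmercury stomach epithelial cell absorption rate
#'   `AB` (default 0.79).
#' @param bioaccessibility default bioaccessible fraction `F` applied when no
#'   species-specific value is supplied (default 1, the conservative
#'   worst case).
#' @param mehg_fraction fraction of muscle total mercury that is
#'   methylmercury, by organism class: about 95 percent in fish and higher
#'   trophic level organisms, 30 percent in zooplankton, 15 percent in
#'   phytoplankton.
#' @param north_sea_fraction fraction of UK-consumed seafood landed in the
#'   North Sea, per commodity: 0.21 for fish and 0.23 for shellfish (79 and
#'   77 percent originate elsewhere).
#' @param twi tolerable weekly intake of methylmercury,
#'   ug kg^-1 bw week^-1 (default 1.3).
#' @param rfc_daily EPA reference concentration, mg kg^-1 d^-1
#'   (default 0.0001); its weekly form is derived with
#'   [rfc_daily_to_weekly()].
#' @return object of class `risk_params`.
#' @export
risk_params <- function(absorption = 0.79,
                        bioaccessibility = 1,
                        mehg_fraction = c(fish = 0.95, zooplankton = 0.30,
                                          phytoplankton = 0.15),
                        north_sea_fraction = c(fish = 0.21, shellfish = 0.23),
                        twi = 1.3,
                        rfc_daily = 0.0001) {
  stopifnot(absorption >= 0, absorption <= 1,
            bioaccessibility >= 0, bioaccessibility <= 1,
            all(mehg_fraction >= 0), all(mehg_fraction <= 1),
            all(north_sea_fraction >= 0), all(north_sea_fraction <= 1),
            twi > 0, rfc_daily > 0)
  structure(list(absorption = absorption,
                 bioaccessibility = bioaccessibility,
                 mehg_fraction = mehg_fraction,
                 north_sea_fraction = north_sea_fraction,
                 twi = twi,
                 rfc_daily = rfc_daily,
                 rfc_weekly = rfc_daily_to_weekly(rfc_daily)),
            class = "risk_params")
}

#' Estimated weekly methylmercury intake from one species
#'
#' `EWI = AC * F * WI * AB * Frac / W`: muscle methylmercury concentration
#' `AC` (ug kg^-1), bioaccessible fraction `F`, weekly intake of that species
#' `WI` (kg week^-1), absorption rate `AB`, sourcing fraction `Frac`, body
#' weight `W` (kg). The grouping is the only dimensionally consistent reading
#' of the intake equation: it yields ug per kg body weight per week.
#'
#' @param ac muscle methylmercury concentration, ug kg^-1.
#' @param f bioaccessible fraction.
#' @param wi weekly intake of the species, kg week^-1.
#' @param ab absorption rate.
#' @param w body weight, kg.
#' @param frac fraction of the consumed amount carrying concentration `ac`.
#' @return EWI, ug kg^-1 bw week^-1.
#' @export
ewi_species <- function(ac, f, wi, ab, w, frac = 1) {
  if (w <= 0) stop("body weight must be positive")
  if (any(c(ac, f, wi, ab, frac) < 0)) stop("inputs must be nonnegative")
  ac * f * wi * ab * frac / w
}

#' Estimated weekly intake from one seafood food group
#'
#' The food group's weekly intake is split evenly across its species. Each
#' species contributes a mixture of sources: the North Sea share (`frac_ns`)
#' carries the scenario's modelled muscle concentration, while the imported
#' share carries the baseline (scenario A) concentration, since no
#' concentration data exist for imported seafood.
#'
#' @param ac_scenario named vector of muscle methylmercury concentrations for
#'   the group's species under the scenario being assessed, ug kg^-1.
#' @param ac_background same species, baseline (scenario A) concentrations.
#' @param wi_group weekly intake of the whole food group, kg week^-1.
#' @param w body weight, kg.
#' @param frac_ns North Sea sourcing fraction for this commodity.
#' @param ab absorption rate (default 0.79).
#' @param f bioaccessible fraction, single value or per species.
#' @return total EWI of the food group, ug kg^-1 bw week^-1.
#' @export
ewi_food_group <- function(ac_scenario, ac_background, wi_group, w,
                           frac_ns, ab = 0.79, f = 1) {
  n_sp <- length(ac_scenario)
  if (n_sp == 0) stop("food group has no species")
  if (length(ac_background) != n_sp) {
    stop("scenario and background concentrations must cover the same species")
  }
  f <- rep_len(f, n_sp)
  share <- wi_group / n_sp
  per_species <- ewi_species(ac_scenario, f, share, ab, w, frac_ns) +
    ewi_species(ac_background, f, share, ab, w, 1 - frac_ns)
  sum(per_species)
}

#' Combine food-group intakes into a total weekly exposure
#'
#' Sums the per-food-group EWIs (all three seafood groups must be present),
#' flags exceedance of the tolerable weekly intake, and derives the hazard
#' quotient from the weekly exposure dose.
#'
#' @param profile a [consumer_profile()].
#' @param group_ewis named vector of per-food-group EWIs
#'   (ug kg^-1 bw week^-1) covering `"oily_fish"`, `"white_fish"`,
#'   `"shellfish"`.
#' @param params a [risk_params()].
#' @return object of class `ewi_result` with fields `label`, `regime`,
#'   `group_ewis`, `total_ewi`, `twi_exceeded`, `hq`.
#' @export
ewi_total <- function(profile, group_ewis, params = risk_params()) {
  need <- c("oily_fish", "white_fish", "shellfish")
  missing_g <- setdiff(need, names(group_ewis))
  if (length(missing_g)) {
    stop("missing seafood group(s): ", paste(missing_g, collapse = ", "))
  }
  if (any(group_ewis < 0)) stop("EWIs must be nonnegative")
  total <- sum(group_ewis[need])
  structure(list(label = profile$label,
                 regime = profile$regime,
                 group_ewis = group_ewis[need],
                 total_ewi = total,
                 twi_exceeded = total > params$twi,
                 hq = hazard_quotient(total / 1000, params$rfc_weekly)),
            class = "ewi_result")
}

#' @export
print.ewi_result <- function(x, ...) {
  cat(sprintf("EWI for %s (%s): %.4g ug kg^-1 bw week^-1 (TWI %s), HQ %.3g\n",
              x$label, x$regime, x$total_ewi,
              if (x$twi_exceeded) "exceeded" else "met", x$hq))
  invisible(x)
}

#' Hazard quotient
#'
#' Ratio of the weekly exposure dose to the reference concentration. HQ <= 1:
#' adverse effects are not likely; HQ > 1 quantifies by how much the exposure
#' dose exceeds the reference.
#'
#' @param ed_mg weekly exposure dose, mg kg^-1 week^-1 (an EWI in
#'   ug kg^-1 bw week^-1 divided by 1000).
#' @param rfc_weekly weekly reference concentration, mg kg^-1 week^-1
#'   (EPA default 0.0007).
#' @return dimensionless hazard quotient.
#' @export
hazard_quotient <- function(ed_mg, rfc_weekly = 0.0007) {
  if (rfc_weekly <= 0) stop("RfC must be positive")
  if (any(ed_mg < 0)) stop("exposure dose must be nonnegative")
  ed_mg / rfc_weekly
}

#' Read / write consumer profiles as CSV
#'
#' Columns: `label`, `regime`, `body_weight_kg`, `wi_oily_kg`, `wi_white_kg`,
#' `wi_shellfish_kg`.
#'
#' @param path CSV path.
#' @return `read_consumer_profiles` returns a list of [consumer_profile()].
#' @export
read_consumer_profiles <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(k) {
    consumer_profile(
      label = d$label[k],
      body_weight_kg = d$body_weight_kg[k],
      weekly_intake_kg = c(oily_fish = d$wi_oily_kg[k],
                           white_fish = d$wi_white_kg[k],
                           shellfish = d$wi_shellfish_kg[k]),
      regime = d$regime[k])
  })
}

#' @rdname read_consumer_profiles
#' @param profiles list of [consumer_profile()].
#' @export
write_consumer_profiles <- function(profiles, path) {
  d <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(label = p$label, regime = p$regime,
               body_weight_kg = p$body_weight_kg,
               wi_oily_kg = p$weekly_intake_kg[["oily_fish"]],
               wi_white_kg = p$weekly_intake_kg[["white_fish"]],
               wi_shellfish_kg = p$weekly_intake_kg[["shellfish"]],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(profiles)
}
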