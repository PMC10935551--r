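#' Convert a whole-body concentration to a muscle-tissue concentration
#'
#' Observed seafood mercury data are muscle based, while the tracer yields
#' whole-body burdens. The conversion multiplies by the muscle allocation
#' fraction: about 50 percent of total mercury sits in muscle for most fish,
#' 15 percent for shrimp, and effectively 100 percent is counted for benthos,
#' plankton and detritus. The multiplier convention (`muscle = body * f_m`)
#' is the default; a divisor convention (`body / f_m`, reading `f_m` as the
#' muscle share of body mass with all mercury in muscle) is available.
#'
#' @param body_concentration whole-body concentration, ug kg^-1 wet weight.
#' @param muscle_fraction `f_m` in (0, 1].
#' @param convention `"multiplier"` (default) or `"divisor"`.
#' @return muscle concentration, ug kg^-1 muscle wet weight.
#' @export
muscle_concentration <- function(body_concentration, muscle_fraction,
                                 convention = c("multiplier", "divisor")) {
  convention <- match.arg(convention)
  if (any(muscle_fraction <= 0 | muscle_fraction > 1)) {
    stop("muscle_fraction must lie in (0, 1]")
  }
  if (convention == "multiplier") body_concentration * muscle_fraction
  else body_concentration / muscle_fraction
}

#' Paired modelled/observed record for one group
#'
#' @param group group name.
#' @param modelled modelled mean muscle concentration `M`, ug kg^-1.
#' @param observed vector of observed muscle concentrations (one per
#'   empirical study), ug kg^-1.
#' @return object of class `validation_record` with fields `group`,
#'   `modelled`, `observed`, `n`.
#' @export
validation_record <- function(group, modelled, observed) {
  observed <- as.numeric(observed)
  if (length(observed) < 1) stop("at least one observed value is required")
  if (modelled < 0 || any(observed < 0)) {
    stop("concentrations must be nonnegative")
  }
  structure(list(group = group, modelled = modelled, observed = observed,
                 n = length(observed)),
            class = "validation_record")
}

#' Model/observed ratio
#'
#' `M / mean(O)`: 1 means the model reproduces the observed mean exactly,
#' above 1 overprediction, below 1 underprediction.
#'
#' @param record a [validation_record()].
#' @return dimensionless ratio.
#' @export
mo_ratio <- function(record) {
  m_obs <- mean(record$observed)
  if (m_obs <= 0) stop("mean observed concentration must be positive")
  record$modelled / m_obs
}

#' Normalized mean bias
#'
#' `sum(M - O) / sum(O)` over the paired modelled/observed values. Zero is an
#' unbiased model; positive values signal overprediction.
#'
#' @param modelled vector of modelled values `M`.
#' @param observed vector of observed values `O`, same length.
#' @return dimensionless NMB.
#' @export
nmb <- function(modelled, observed) {
  if (length(modelled) == 0) stop("no pairs supplied")
  if (length(modelled) != length(observed)) {
    stop("modelled and observed must have equal length")
  }
  denom <- sum(observed)
  if (denom <= 0) stop("sum of observed values must be positive")
  sum(modelled - observed) / denom
}

#' Interpret a normalized mean bias as an over/under-prediction factor
#'
#' For `NMB >= 0` the model overpredicts by a factor `NMB + 1` (an NMB of 1.2
#' is an overestimation by a factor of 2.2). For negative values the
#' convention reports an underprediction by a factor `|NMB| + 1` (an NMB of
#' -0.2 is an underprediction by a factor of 1.2).
#'
#' @param nmb_value an NMB, must exceed -1.
#' @return list with elements `direction` (`"over"` or `"under"`) and
#'   `factor`.
#' @export
nmb_factor <- function(nmb_value) {
  if (nmb_value <= -1) stop("NMB must exceed -1")
  if (nmb_value >= 0) {
    list(direction = "over", factor = nmb_value + 1)
  } else {
    list(direction = "under", factor = abs(nmb_value) + 1)
  }
}

#' Food standard for mercury in seafood muscle
#'
#' Guideline limits deciding whether landed seafood is eligible for
#' commercial sale: 0.5 mg kg^-1 muscle for low trophic level species and
#' 1.0 mg kg^-1 for high trophic level species.
#'
#' @param low_trophic_limit mg kg^-1 (default 0.5).
#' @param high_trophic_limit mg kg^-1 (default 1.0).
#' @return object of class `food_standard`.
#' @export
food_standard <- function(low_trophic_limit = 0.5, high_trophic_limit = 1.0) {
  if (low_trophic_limit <= 0 || high_trophic_limit <= 0) {
    stop("limits must be positive")
  }
  structure(list(low_trophic_limit = low_trophic_limit,
                 high_trophic_limit = high_trophic_limit),
            class = "food_standard")
}

#' Food-standard exceedance check
#'
#' @param muscle_conc_mg muscle concentration, mg kg^-1 wet weight.
#' @param trophic_class `"low"` or `"high"` (selects the applicable limit).
#' @param standard a [food_standard()].
#' @return list with `exceeded` (logical) and `margin` (limit minus value,
#'   mg kg^-1; negative when exceeded).
#' @export
fs_exceedance <- function(muscle_conc_mg, trophic_class,
                          standard = food_standard()) {
  if (any(muscle_conc_mg < 0)) stop("concentration must be nonnegative")
  if (!all(trophic_class %in% c("low", "high"))) {
    stop("unknown trophic class: ",
         paste(setdiff(trophic_class, c("low", "high")), collapse = ", "))
  }
  limit <- ifelse(trophic_class == "high",
                  standard$high_trophic_limit, standard$low_trophic_limit)
  list(exceeded = muscle_conc_mg > limit, margin = limit - muscle_conc_mg)
}

#' Read an observations table
#'
#' Plain CSV with columns `group`, `study_id`, `observed_ug_per_kg`, `basis`
#' (`"wet"` or `"dry"`) and `moisture_fraction`. Dry-weight values are
#' converted to wet weight at the boundary:
#' `wet = dry * (1 - moisture_fraction)`.
#'
#' @param path CSV path.
#' @return data.frame with `group`, `study_id` and wet-weight
#'   `observed_ug_per_kg`.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "study_id", "observed_ug_per_kg", "basis")
  if (!all(need %in% names(d))) {
    stop("observations CSV needs columns: ", paste(need, collapse = ", "))
  }
  dry <- d$basis == "dry"
  if (any(dry)) {
    if (!"moisture_fraction" %in% names(d) ||
        any(is.na(d$moisture_fraction[dry]))) {
      stop("dry-basis rows need a moisture_fraction")
    }
    d$observed_ug_per_kg[dry] <-
      d$observed_ug_per_kg[dry] * (1 - d$moisture_fraction[dry])
  }
  d[, c("group", "study_id", "observed_ug_per_kg")]
}

#' Validation report: M/O ratios and normalized mean bias per group
#'
#' Matches modelled muscle concentrations against an observations table and
#' computes, per group, the mean observed value, the M/O ratio, the NMB over
#' that group's studies, and its interpretive factor.
#'
#' @param modelled named vector of modelled muscle concentrations,
#'   ug kg^-1 (names are group names).
#' @param observations data.frame as returned by [read_observations()] or
#'   [generate_observations()].
#' @return data.frame with columns `group`, `M_ug_per_kg`, `mean_O_ug_per_kg`,
#'   `n`, `mo_ratio`, `nmb`, `nmb_factor`, `direction`.
#' @export
validation_report <- function(modelled, observations) {
  groups <- intersect(names(modelled), unique(observations$group))
  if (!length(groups)) stop("no observed group matches a modelled group")
  rows <- lapply(groups, function(g) {
    o <- observations$observed_ug_per_kg[observations$group == g]
    rec <- validation_record(g, modelled[[g]], o)
    b <- nmb(rep(rec$modelled, rec$n), o)
    fac <- nmb_factor(b)
    data.frame(group = g,
               M_ug_per_kg = rec$modelled,
               mean_O_ug_per_kg = mean(o),
               n = rec$n,
               mo_ratio = mo_ratio(rec),
               nmb = b,
               nmb_factor = fac$factor,
               direction = fac$direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
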