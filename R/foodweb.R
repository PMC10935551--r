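#' Construct a mass-balanced trophic food-web model
#'
#' A `food_web` holds the static (Ecopath-style) description of a trophic
#' network: one row per functional group with its biomass and rate parameters,
#' plus a diet-composition matrix, plus the geometry of the model environment
#' (area and mean depth) used to convert between masses and water
#' concentrations.
#'
#' @param groups data.frame with one row per functional group and columns
#'   `name` (unique label), `group_class` (`"producer"`, `"consumer"` or
#'   `"detritus"`), `B` (biomass, t km^-2 wet weight), `PB` (production /
#'   biomass, yr^-1), `QB` (consumption / biomass, yr^-1; 0 for producers and
#'   detritus), `EE` (ecotrophic efficiency, fraction in [0, 1]),
#'   `direct_uptake` (logical: does the group take mercury up from the water
#'   column directly? true only for photosynthetic plankton and the
#'   copepod/euphausiid grazers in the shipped template), `muscle_fraction`
#'   (fraction of whole-body mercury allocated to muscle: 0.5 for fish,
#'   0.15 for shrimp, 1 for benthos/plankton/detritus), `trophic_class`
#'   (`"low"` or `"high"`, selects the applicable food standard) and
#'   `commercial` (logical: landed commercially).
#' @param diet square numeric matrix `DC` with `DC[i, j]` the fraction of
#'   predator `i`'s diet taken from prey `j`. Consumer rows must sum to 1;
#'   producer and detritus rows must be all zero.
#' @param area model area in km^2 (North Sea default 570 000).
#' @param depth mean depth in m (North Sea default 95).
#'
#' @return An object of class `food_web`: a list with elements `groups`,
#'   `diet`, `area`, `depth`.
#'
#' @details Group order is the row order of `groups`; every matrix in the
#'   package is indexed in that order. Biomasses must be strictly positive for
#'   all groups (contaminant body concentrations divide by biomass).
#'
#' @examples
#' web <- generate_foodweb(web_gen_spec(n_groups = 5, seed = 1))
#' web
#' trophic_levels(web)
#' @export
food_web <- function(groups, diet, area = 570000, depth = 95) {
  required <- c("name", "group_class", "B", "PB", "QB", "EE",
                "direct_uptake", "muscle_fraction", "trophic_class",
                "commercial")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols)) {
    stop("groups table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  diet <- as.matrix(diet)
  n <- nrow(groups)
  if (!all(dim(diet) == c(n, n))) {
    stop("diet matrix must be ", n, " x ", n, " to match the group table")
  }
  if (anyDuplicated(groups$name)) stop("group names must be unique")
  rownames(diet) <- colnames(diet) <- groups$name

  web <- structure(list(groups = groups, diet = diet,
                        area = area, depth = depth),
                   class = "food_web")
  validate_food_web(web)
  web
}

# Invariant checks shared by the constructor and the CSV reader.
validate_food_web <- function(web) {
  g <- web$groups
  dc <- web$diet
  cls <- g$group_class
  if (!all(cls %in% c("producer", "consumer", "detritus"))) {
    stop("group_class must be producer, consumer or detritus")
  }
  bad <- g$name[!is.finite(g$B) | g$B <= 0]
  if (length(bad)) {
    stop("biomass must be positive for every group (contaminant body ",
         "concentrations divide by B); offending: ",
         paste(bad, collapse = ", "))
  }
  bad <- g$name[g$PB < 0 | g$QB < 0]
  if (length(bad)) {
    stop("negative rates for group(s): ", paste(bad, collapse = ", "))
  }
  cons <- cls == "consumer"
  bad <- g$name[cons & g$QB < g$PB]
  if (length(bad)) {
    stop("consumers must satisfy QB >= PB: ", paste(bad, collapse = ", "))
  }
  bad <- g$name[!cons & g$QB != 0]
  if (length(bad)) {
    stop("producers and detritus must have QB = 0: ",
         paste(bad, collapse = ", "))
  }
  if (any(g$EE < 0 | g$EE > 1)) stop("EE must lie in [0, 1]")
  if (any(g$muscle_fraction <= 0 | g$muscle_fraction > 1)) {
    stop("muscle_fraction must lie in (0, 1]")
  }
  if (!all(g$trophic_class %in% c("low", "high"))) {
    stop("trophic_class must be 'low' or 'high'")
  }
  if (any(dc < 0)) stop("diet fractions must be nonnegative")
  rs <- rowSums(dc)
  bad <- g$name[cons & abs(rs - 1) > 1e-9]
  if (length(bad)) {
    stop("consumer diet rows must sum to 1: ", paste(bad, collapse = ", "))
  }
  bad <- g$name[!cons & rs != 0]
  if (length(bad)) {
    stop("producer/detritus diet rows must be zero: ",
         paste(bad, collapse = ", "))
  }
  if (!(web$area > 0 && web$depth > 0)) stop("area and depth must be positive")
  invisible(web)
}

#' @export
print.food_web <- function(x, ...) {
  g <- x$groups
  cat("Mass-balanced food web:", nrow(g), "functional groups\n")
  cat("  ", sum(g$group_class == "producer"), " producers, ",
      sum(g$group_class == "consumer"), " consumers, ",
      sum(g$group_class == "detritus"), " detritus\n", sep = "")
  cat(sprintf("  area %g km^2, mean depth %g m (volume %.3g l)\n",
              x$area, x$depth, water_volume_l(x)))
  cat("  direct water uptake flagged for:",
      paste(g$name[g$direct_uptake], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.food_web <- function(object, ...) {
  g <- object$groups
  out <- data.frame(
    name = g$name,
    class = g$group_class,
    B_t_km2 = g$B,
    PB_per_yr = g$PB,
    QB_per_yr = g$QB,
    EE = g$EE,
    TL = trophic_levels(object),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Water volume of the model environment in litres: area km^2 * depth m.
water_volume_l <- function(web) web$area * 1e6 * web$depth * 1e3

#' Consumption flow matrix
#'
#' Standard Ecopath flow bookkeeping: `Q[i, j] = B_i * QB_i * DC[i, j]` is the
#' biomass flow (t km^-2 yr^-1) from prey `j` into predator `i`. Rows of
#' consumers sum to the group's total consumption `B_i * QB_i`; producer and
#' detritus rows are zero.
#'
#' @param web a [food_web()].
#' @return numeric matrix (predator rows x prey columns), t km^-2 yr^-1.
#' @export
consumption_matrix <- function(web) {
  g <- web$groups
  bad <- g$name[g$B < 0 | g$QB < 0]
  if (length(bad)) stop("negative rates for group(s): ",
                        paste(bad, collapse = ", "))
  sweep(web$diet, 1, g$B * g$QB, "*")
}

#' Ecopath mass-balance residuals
#'
#' For each group the master-equation residual
#' `B_i * PB_i * EE_i - sum_j B_j * QB_j * DC[j, i] - Y_i`
#' (production used within the system minus predation losses minus landings).
#' A balanced web has all residuals at zero. Biomass accumulation and net
#' migration are fixed at zero (closed model environment, no migration of
#' biota). Flows into detritus are not part of the static balance, so the
#' detritus residual is reported as 0.
#'
#' @param web a [food_web()].
#' @param landings per-group fishery removals `Y` in t km^-2 yr^-1; a single 0
#'   recycles to all groups.
#' @return named numeric vector of residuals, t km^-2 yr^-1.
#' @export
mass_balance_residuals <- function(web, landings = 0) {
  g <- web$groups
  n <- nrow(g)
  if (length(landings) == 1) landings <- rep(landings, n)
  if (length(landings) != n) {
    stop("landings has length ", length(landings), " but the web has ", n,
         " groups")
  }
  if (any(landings < 0)) stop("landings must be nonnegative")
  predation <- colSums(consumption_matrix(web))
  res <- g$B * g$PB * g$EE - predation - landings
  res[g$group_class == "detritus"] <- 0
  stats::setNames(res, g$name)
}

#' Fractional trophic levels
#'
#' Solves the linear system `TL_i = 1 + sum_j DC[i, j] * TL_j`. Producers and
#' detritus (empty diet rows) sit at trophic level 1; a consumer feeding only
#' on producers sits at 2.
#'
#' @param web a [food_web()].
#' @return named numeric vector of trophic levels.
#' @export
trophic_levels <- function(web) {
  dc <- web$diet
  n <- nrow(dc)
  a <- diag(n) - dc
  tl <- tryCatch(solve(a, rep(1, n)),
                 error = function(e) {
                   stop("trophic-level system is singular (degenerate ",
                        "cannibalism loop): ", conditionMessage(e))
                 })
  stats::setNames(tl, web$groups$name)
}

#' Read / write a food web as CSV tables
#'
#' The on-disk form is two plain CSV files: a group table (columns `name`,
#' `class`, `B`, `PB`, `QB`, `EE`, `direct_uptake`, `muscle_fraction`,
#' `trophic_class`, `commercial`) and a square diet matrix whose header row and
#' first column carry the group names (predator rows x prey columns).
#'
#' @param groups_csv path to the group table CSV.
#' @param diet_csv path to the diet matrix CSV.
#' @param area,depth model geometry (km^2, m).
#' @return `read_food_web` returns a [food_web()]; `write_food_web` returns
#'   the input web invisibly.
#' @export
read_food_web <- function(groups_csv, diet_csv, area = 570000, depth = 95) {
  g <- utils::read.csv(groups_csv, stringsAsFactors = FALSE)
  names(g)[names(g) == "class"] <- "group_class"
  g$direct_uptake <- as.logical(g$direct_uptake)
  g$commercial <- as.logical(g$commercial)
  d <- utils::read.csv(diet_csv, row.names = 1, check.names = FALSE)
  d <- as.matrix(d)
  if (!identical(rownames(d), g$name) || !identical(colnames(d), g$name)) {
    stop("diet matrix names do not match the group table")
  }
  food_web(g, d, area = area, depth = depth)
}

#' @rdname read_food_web
#' @param web a [food_web()] to serialize.
#' @export
write_food_web <- function(web, groups_csv, diet_csv) {
  g <- web$groups
  names(g)[names(g) == "group_class"] <- "class"
  utils::write.csv(g, groups_csv, row.names = FALSE)
  utils::write.csv(as.data.frame(web$diet), diet_csv, row.names = TRUE)
  invisible(web)
}
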