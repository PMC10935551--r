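# Run code under a local, explicit seed without disturbing the caller's
# random state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for the synthetic food-web generator
#'
#' @param n_groups total number of functional groups (default 29, the size of
#'   the North Sea model the package emulates).
#' @param n_producers number of producer groups (>= 1).
#' @param n_detritus 0 or 1 detritus groups.
#' @param connectance probability that an allowed predator-prey link is
#'   realized, in (0, 1].
#' @param biomass_range log-uniform biomass range, t km^-2.
#' @param ge_range gross food-conversion efficiency range (PB/QB) for
#'   consumers.
#' @param seed integer seed; every random draw in the generator flows from
#'   it.
#' @return object of class `web_gen_spec`.
#' @export
web_gen_spec <- function(n_groups = 29, n_producers = 3, n_detritus = 1,
                         connectance = 0.3,
                         biomass_range = c(0.01, 50),
                         ge_range = c(0.15, 0.3),
                         seed = 1) {
  stopifnot(n_producers >= 1, n_detritus %in% c(0, 1),
            connectance > 0, connectance <= 1,
            n_groups >= n_producers + n_detritus + 1,
            biomass_range[1] > 0, biomass_range[2] >= biomass_range[1],
            ge_range[1] > 0, ge_range[2] <= 1)
  structure(list(n_groups = n_groups, n_producers = n_producers,
                 n_detritus = n_detritus, connectance = connectance,
                 biomass_range = biomass_range, ge_range = ge_range,
                 seed = as.integer(seed)),
            class = "web_gen_spec")
}

# Named guild template for the default 29-group North Sea style web:
# 3 phytoplankton producers, grazing and carnivorous zooplankton, a benthic
# community, the main commercial fish guilds, top predators and detritus.
# The composition (names, which groups take mercury up directly, muscle
# fractions, commercial status) mirrors the real model's guild structure;
# all parameter values are synthetic.
north_sea_guilds <- function() {
  data.frame(
    name = c("phytoplankton_diatoms", "phytoplankton_flagellates",
             "phytoplankton_picoplankton",
             "copepods", "euphausiids",
             "gelatinous_zooplankton", "carnivorous_zooplankton",
             "polychaetes", "bivalves", "echinoderms", "infaunal_benthos",
             "epifaunal_benthos", "shrimp", "crabs",
             "sandeel", "sprat", "herring", "plaice", "sole", "gurnards",
             "whiting", "haddock", "mackerel", "saithe", "cod",
             "seabirds", "seals", "harbour_porpoise",
             "detritus"),
    guild = c(rep("phytoplankton", 3), rep("zooplankton", 4),
              rep("benthos", 7), rep("fish", 11), rep("top_predator", 3),
              "detritus"),
    stringsAsFactors = FALSE
  )
}

#' Generate a mass-balanced synthetic food web
#'
#' Draws a random trophic network of the shape the analysis assumes and
#' back-solves the ecotrophic efficiencies so the static mass balance holds
#' exactly. Groups are ordered producers first, consumers by rising trophic
#' position, detritus last; each consumer feeds only on lower-ordered groups
#' (plus detritus), so the web is acyclic apart from the detritus loop.
#' Production rates fall and biomasses shrink with trophic position;
#' consumption follows `QB = PB / GE` with a drawn gross efficiency. Where a
#' predator's demand would exceed a prey's production, the prey's production
#' rate is raised (working from top predators downwards) so every `EE` lands
#' in [0, 0.95].
#'
#' With the default 29-group spec the groups carry the named North Sea style
#' guilds (phytoplankton, copepods, euphausiids, benthos, shrimp, named fish,
#' top predators, detritus): direct water uptake is flagged only for the
#' phytoplankton groups, copepods and euphausiids; muscle fractions are 0.5
#' for fish (and warm-blooded top predators), 0.15 for shrimp and 1 for
#' everything else; the commercial flag marks the landed guilds. Other sizes
#' get generic labels with the same conventions.
#'
#' @param spec a [web_gen_spec()].
#' @return a [food_web()] that passes all model invariants, with
#'   `mass_balance_residuals()` identically zero; identical for identical
#'   seeds.
#' @export
generate_foodweb <- function(spec = web_gen_spec()) {
  stopifnot(inherits(spec, "web_gen_spec"))
  with_seed(spec$seed, generate_foodweb_impl(spec))
}

generate_foodweb_impl <- function(spec) {
  n <- spec$n_groups
  np <- spec$n_producers
  nd <- spec$n_detritus
  nc <- n - np - nd
  has_det <- nd == 1
  det <- if (has_det) n else integer(0)
  cons <- seq(np + 1, np + nc)

  template <- NULL
  if (n == 29 && np == 3 && has_det) {
    template <- north_sea_guilds()
    nm <- template$name
  } else {
    nm <- c(paste0("producer_", seq_len(np)),
            paste0("consumer_", seq_len(nc)),
            if (has_det) "detritus")
  }

  # trophic position rank in [0, 1] driving rate and biomass scaling
  r <- numeric(n)
  r[cons] <- seq_len(nc) / nc

  lb <- log10(spec$biomass_range[1])
  ub <- log10(spec$biomass_range[2])
  b <- 10^stats::runif(n, lb, ub - (ub - lb) * 0.6 * r)
  # the detrital pool is far larger than any living compartment
  if (has_det) b[det] <- 10^stats::runif(1, 2, 2.7)

  pb <- numeric(n)
  pb[seq_len(np)] <- 10^stats::runif(np, 1, 2)          # 10..100 yr^-1
  pb[cons] <- 10^stats::runif(nc, 0.6 - 2.2 * r[cons], 1.2 - 2.2 * r[cons])
  ge <- stats::runif(n, spec$ge_range[1], spec$ge_range[2])

  # diet links: each consumer may feed on any lower-ordered group, and on
  # detritus if it sits in the lower half of the consumer ladder
  dc <- matrix(0, n, n)
  herbivore <- !is.null(template) & nm %in% c("copepods", "euphausiids")
  for (i in cons) {
    # the grazing crustaceans are strict herbivores; everyone else may feed
    # on any lower-ordered group
    allowed <- if (herbivore[i]) seq_len(np) else seq_len(i - 1)
    picked <- allowed[stats::runif(length(allowed)) < spec$connectance]
    if (has_det && !herbivore[i] && r[i] <= 0.5 &&
        stats::runif(1) < spec$connectance) {
      picked <- c(picked, det)
    }
    if (!length(picked)) picked <- max(allowed)   # guarantee one prey
    # availability-weighted diets: abundant prey dominate, which keeps the
    # web omnivorous rather than chain-like
    w <- sqrt(b[picked])
    if (has_det) w[picked == det] <- 0.5 * max(w)
    frac <- stats::rgamma(length(picked), shape = 1) * w
    dc[i, picked] <- frac / sum(frac)
  }

  # balance top-down: predators have higher order than their prey, so their
  # consumption is fixed before the prey's production is set
  qb <- numeric(n)
  ee <- numeric(n)
  for (i in rev(seq_len(n - as.integer(has_det)))) {
    demand <- sum(b[cons] * qb[cons] * dc[cons, i])
    if (demand > 0) {
      ee_target <- stats::runif(1, 0.5, 0.95)
      pb[i] <- max(pb[i], demand / (b[i] * ee_target))
      ee[i] <- demand / (b[i] * pb[i])
    }
    if (i %in% cons) qb[i] <- pb[i] / ge[i]
  }
  if (has_det) {
    pb[det] <- 0
    qb[det] <- 0
    ee[det] <- 0
  }

  cls <- c(rep("producer", np), rep("consumer", nc),
           if (has_det) "detritus")

  if (!is.null(template)) {
    guild <- template$guild
    direct <- guild == "phytoplankton" | nm %in% c("copepods", "euphausiids")
    fm <- ifelse(guild %in% c("fish", "top_predator"), 0.5,
                 ifelse(nm == "shrimp", 0.15, 1))
    commercial <- guild == "fish" | nm %in% c("shrimp", "crabs", "bivalves")
  } else {
    direct <- cls == "producer"
    direct[cons[seq_len(min(2, nc))]] <- TRUE
    fm <- rep(1, n)
    commercial <- rep(FALSE, n)
  }

  groups <- data.frame(name = nm, group_class = cls, B = b, PB = pb,
                       QB = qb, EE = ee, direct_uptake = direct,
                       muscle_fraction = fm, trophic_class = "low",
                       commercial = commercial, stringsAsFactors = FALSE)
  web <- food_web(groups, dc)
  tl <- trophic_levels(web)
  web$groups$trophic_class <- ifelse(tl >= 4, "high", "low")
  web
}

#' Calibrate direct uptake rates to target body concentrations
#'
#' Mirrors the calibration step in which per-group uptake rates are derived
#' so that, at the fixed background water concentration, the flagged groups
#' equilibrate at literature-style body burdens. Because the tracer system is
#' linear, the map from uptake rates to equilibrium concentrations is a
#' matrix; the calibration solves it directly for the flagged groups.
#'
#' @param web a [food_web()].
#' @param targets named vector of target equilibrium whole-body
#'   concentrations (ug kg^-1 wet weight) for the direct-uptake groups. A
#'   single unnamed value recycles over all flagged groups.
#' @param excretion excretion rate passed to [tracer_params()].
#' @param water_concentration fixed calibration concentration, ug l^-1.
#' @param ... further arguments to [tracer_params()].
#' @return a [tracer_params()] whose equilibrium run reproduces the targets.
#'   Errors, naming the groups, if a target is unreachable because dietary
#'   inflow alone already exceeds it (the solve would need a negative uptake
#'   rate).
#' @export
calibrate_uptake <- function(web, targets, excretion = 0.10,
                             water_concentration = 0.57, ...) {
  g <- web$groups
  flagged <- which(g$direct_uptake)
  if (!length(flagged)) stop("no group carries the direct_uptake flag")
  tvec <- rep(NA_real_, length(flagged))
  if (is.null(names(targets))) {
    tvec <- rep_len(as.numeric(targets), length(flagged))
  } else {
    unknown <- setdiff(names(targets), g$name[flagged])
    if (length(unknown)) {
      stop("targets given for non-flagged group(s): ",
           paste(unknown, collapse = ", "))
    }
    tvec <- targets[match(g$name[flagged], names(targets))]
    if (anyNA(tvec)) {
      stop("missing target for flagged group(s): ",
           paste(g$name[flagged][is.na(tvec)], collapse = ", "))
    }
  }
  if (any(tvec < 0)) stop("targets must be nonnegative")

  base <- tracer_params(web, uptake = 0, excretion = excretion, ...)
  tm <- tracer_matrix(web, base)
  m_b <- tm$F[-1, -1, drop = FALSE]
  kg <- tm$kg
  # equilibrium body concentration response to a unit uptake rate on group j:
  # pools A = -M^-1 (C_w * kg * e_j), concentration = A / kg
  resp <- sapply(flagged, function(j) {
    s <- numeric(nrow(m_b))
    s[j] <- water_concentration * kg[j]
    (-solve(m_b, s) / kg)[flagged]
  })
  resp <- matrix(resp, nrow = length(flagged))
  u_f <- solve(resp, as.numeric(tvec))
  scale <- max(abs(u_f), 1e-300)
  u_f[u_f < 0 & u_f > -1e-10 * scale] <- 0
  if (any(u_f < 0)) {
    stop("target unreachable (dietary inflow alone exceeds the target) for: ",
         paste(g$name[flagged][u_f < 0], collapse = ", "))
  }
  tracer_params(web, uptake = stats::setNames(u_f, g$name[flagged]),
                excretion = excretion, ...)
}

#' Default calibration targets for a generated web
#'
#' Literature-style background whole-body burdens for the direct-uptake
#' groups: a few ug kg^-1 wet weight in phytoplankton and somewhat more in
#' the grazing crustaceans, so that (after trophic magnification) fish sit
#' well below the food standards at the background concentration.
#'
#' @param web a [food_web()].
#' @param producer_target ug kg^-1 for flagged producers (default 0.5).
#' @param grazer_target ug kg^-1 for flagged consumers (default 4).
#' @return named target vector for [calibrate_uptake()].
#' @export
default_uptake_targets <- function(web, producer_target = 0.5,
                                   grazer_target = 4) {
  g <- web$groups
  flagged <- g$direct_uptake
  stats::setNames(ifelse(g$group_class[flagged] == "producer",
                         producer_target, grazer_target),
                  g$name[flagged])
}

#' Generate a synthetic observation set around modelled concentrations
#'
#' Constructs per-group observed muscle concentrations with a controlled
#' model bias and multiplicative noise: each observation is
#' `modelled / (1 + bias)` times a lognormal factor with unit mean and the
#' stated coefficient of variation. With `n_studies` large and noise absent,
#' the NMB of the modelled values against these observations recovers `bias`
#' exactly.
#'
#' @param modelled named vector of modelled muscle concentrations,
#'   ug kg^-1.
#' @param bias constructed model bias `b` (NMB scale; > -1).
#' @param noise_cv coefficient of variation of the lognormal noise (>= 0).
#' @param n_studies observations per group.
#' @param seed integer seed.
#' @return data.frame with columns `group`, `study_id`,
#'   `observed_ug_per_kg`.
#' @export
generate_observations <- function(modelled, bias = 0, noise_cv = 0,
                                  n_studies = 3, seed = 1) {
  if (bias <= -1) stop("bias must exceed -1")
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (is.null(names(modelled))) stop("modelled must be named by group")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rows <- lapply(names(modelled), function(g) {
      noise <- if (noise_cv > 0) {
        stats::rlnorm(n_studies, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, n_studies)
      data.frame(group = g,
                 study_id = paste0(g, "_s", seq_len(n_studies)),
                 observed_ug_per_kg = modelled[[g]] / (1 + bias) * noise,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate the four consumer profiles under both consumption regimes
#'
#' Stand-in profiles for the UK consumer groups assessed in the exposure
#' layer: men, women, children and pregnant women, each under the NHS
#' recommended seafood intake and the (lower) NDNS reported actual intake.
#' The NHS intake of every food group is at least the NDNS intake by
#' construction. Body weights and the NHS portion arithmetic (two 140 g
#' portions a week, at least one oily) are typical reference values; the
#' NDNS fractions are drawn per profile from the seed. These tables are
#' synthetic stand-ins, not survey extracts.
#'
#' @param seed integer seed.
#' @return list of eight [consumer_profile()] objects (4 labels x 2
#'   regimes).
#' @export
generate_consumer_profiles <- function(seed = 1) {
  labels <- c("men", "women", "children", "pregnant women")
  weights <- c(men = 85, women = 70, children = 30, `pregnant women` = 75)
  # NHS-style weekly portions in kg: one oily portion, one white portion,
  # modest shellfish; children at 60% portion size
  nhs <- list(
    men = c(oily_fish = 0.140, white_fish = 0.140, shellfish = 0.090),
    women = c(oily_fish = 0.140, white_fish = 0.140, shellfish = 0.090),
    children = c(oily_fish = 0.084, white_fish = 0.084, shellfish = 0.054),
    `pregnant women` = c(oily_fish = 0.140, white_fish = 0.140,
                         shellfish = 0.090)
  )
  with_seed(seed, {
    out <- list()
    for (lab in labels) {
      frac <- stats::runif(3, 0.3, 0.9)    # reported below recommended
      out[[length(out) + 1]] <- consumer_profile(
        lab, weights[[lab]], nhs[[lab]], regime = "NHS")
      out[[length(out) + 1]] <- consumer_profile(
        lab, weights[[lab]], nhs[[lab]] * frac, regime = "NDNS")
    }
    out
  })
}
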