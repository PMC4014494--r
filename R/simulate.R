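#' Life-history and resource parameters of the simulated population
#'
#' Parameters of the individual-based, food-limited Daphnia-like population
#' model.  Individuals are characterised by age, body length and a fixed
#' randomly assigned maximum lifetime; all other vital rates are
#' deterministic functions of body length and the realised food ration.
#' The shared food pool creates crowding/competition and the strongly
#' overcompensating boom-bust dynamics the analysis layer characterises.
#'
#' Defaults were calibrated (grid search on the control ensemble) so that
#' the undisturbed population persists over a year, remains bounded, and
#' exhibits chaotic fluctuations with an ensemble-mean maximal Lyapunov
#' exponent in the 0.3-0.7 per-day range.
#'
#' @param asymptotic_length Asymptotic (von Bertalanffy) body length, mm.
#' @param neonate_length Body length at birth, mm.
#' @param growth_rate Von Bertalanffy growth coefficient per day at full
#'   ration; realised growth is scaled by the ration fraction.
#' @param neonate_max Upper length bound of the neonate class, mm
#'   (neonates are `< neonate_max`).
#' @param adult_min Lower length bound of the adult class, mm (adults are
#'   `>= adult_min`); doubles as the maturity threshold for reproduction.
#' @param brood_interval Days between successive broods of an adult.
#' @param brood_max Maximum brood size (neonates per brood) at full ration
#'   and zero toxicant.
#' @param lifetime_range Integer range (days) from which each individual's
#'   fixed maximum lifetime is drawn uniformly at birth.
#' @param food_input Constant daily food input to the shared pool,
#'   mg C per litre per day.
#' @param food_decay Fraction of the standing food pool lost per day
#'   (settling/degradation); bounds food accumulation when the population
#'   crashes.
#' @param half_saturation Food density at which the ingestion rate is half
#'   its maximum, mg C/l.
#' @param ingestion_coef Maximum ingestion per day of a 1-mm individual,
#'   mg C; ingestion scales with body length squared (filtering area).
#' @param starve_coef Starvation threshold coefficient: an individual of
#'   length L starves on days when its ration fraction falls below
#'   `starve_coef * L` (maintenance scales with body volume, intake with
#'   area, so large animals starve first).
#' @param starve_days Consecutive starvation days an individual survives;
#'   on the next it is removed.
#' @param provision_spread Maternal provisioning range: neonate birth
#'   length spans `neonate_length * (1 +/- provision_spread/2)` as the
#'   mother's ration fraction runs from 0 to 1.  Staggers cohort
#'   development without any extra stochasticity.
#' @param init_adult_length Body length of the adults seeded at day 0, mm.
#' @param init_food Initial food pool, mg C/l.
#' @param carrying_ceiling Upper abundance bound used by calibration
#'   checks; the dynamics themselves are bounded by food, not by this.
#' @return An object of class `life_history`.
#' @export
life_history_params <- function(asymptotic_length = 4.0,
                                neonate_length = 0.8,
                                growth_rate = 0.12,
                                neonate_max = 1.4,
                                adult_min = 2.6,
                                brood_interval = 3L,
                                brood_max = 6,
                                lifetime_range = c(30L, 60L),
                                food_input = 20,
                                food_decay = 0.05,
                                half_saturation = 0.3,
                                ingestion_coef = 0.01,
                                starve_coef = 0.05,
                                provision_spread = 0.3,
                                starve_days = 4L,
                                init_adult_length = 3.0,
                                init_food = 10,
                                carrying_ceiling = 30000) {
  stopifnot(asymptotic_length > 0, neonate_length > 0,
            neonate_length < asymptotic_length,
            growth_rate > 0, neonate_max > neonate_length,
            adult_min > neonate_max, adult_min < asymptotic_length,
            brood_interval >= 1, brood_max >= 0,
            length(lifetime_range) == 2L, lifetime_range[1] >= 1,
            lifetime_range[2] >= lifetime_range[1],
            food_input >= 0, food_decay >= 0, food_decay < 1,
            half_saturation > 0, ingestion_coef > 0,
            starve_coef >= 0, provision_spread >= 0, provision_spread < 1,
            starve_days >= 1,
            init_adult_length >= adult_min, init_food >= 0,
            carrying_ceiling > 0)
  structure(list(asymptotic_length = asymptotic_length,
                 neonate_length = neonate_length,
                 growth_rate = growth_rate,
                 neonate_max = neonate_max,
                 adult_min = adult_min,
                 brood_interval = as.integer(brood_interval),
                 brood_max = brood_max,
                 lifetime_range = as.integer(lifetime_range),
                 food_input = food_input,
                 food_decay = food_decay,
                 half_saturation = half_saturation,
                 ingestion_coef = ingestion_coef,
                 starve_coef = starve_coef,
                 provision_spread = provision_spread,
                 starve_days = as.integer(starve_days),
                 init_adult_length = init_adult_length,
                 init_food = init_food,
                 carrying_ceiling = carrying_ceiling),
            class = "life_history")
}

#' Treatment configuration: one toxicant concentration, one ensemble
#'
#' @param concentration Constant (press) toxicant concentration, ug/l.
#' @param n_days Number of simulated days; the returned series has
#'   `n_days + 1` censuses (day 0 is recorded before any update).
#' @param n_runs Ensemble size (Monte-Carlo runs); must be at least 2.
#' @param base_seed Base RNG seed; run `i` uses seed `base_seed + i`, so
#'   ensembles at different concentrations that share `base_seed` are
#'   paired run-by-run through identical initial lifetime draws.
#' @param dose_response A [dose_response()] object.
#' @param life_history A [life_history_params()] object.
#' @return An object of class `treatment_config`.
#' @export
treatment_config <- function(concentration = 0, n_days = 365L,
                             n_runs = 100L, base_seed = 1L,
                             dose_response = popchaos::dose_response(),
                             life_history = life_history_params()) {
  stopifnot(is.numeric(concentration), length(concentration) == 1L,
            concentration >= 0, n_days >= 1, n_runs >= 2,
            inherits(dose_response, "dose_response"),
            inherits(life_history, "life_history"))
  structure(list(concentration = concentration,
                 n_days = as.integer(n_days),
                 n_runs = as.integer(n_runs),
                 base_seed = as.integer(base_seed),
                 dose_response = dose_response,
                 life_history = life_history),
            class = "treatment_config")
}

#' Classify individuals into age (size) classes by body length
#'
#' Neonates are shorter than `neonate_max` (default 1.4 mm), juveniles at
#' least `neonate_max` but shorter than `adult_min` (default 2.6 mm),
#' adults at least `adult_min`.  Boundaries are left-closed on the upper
#' class: an individual of exactly 1.4 mm is a juvenile, 2.6 mm an adult.
#'
#' @param lengths Numeric vector of body lengths, mm, all `> 0`.
#' @param neonate_max,adult_min Class boundaries, mm.
#' @return Named integer vector `c(neonates, juveniles, adults)`.
#' @examples
#' classify_by_length(c(1.0, 1.4, 2.6))  # one of each
#' @export
classify_by_length <- function(lengths, neonate_max = 1.4, adult_min = 2.6) {
  stopifnot(is.numeric(lengths))
  if (any(lengths <= 0)) stop("body lengths must be positive", call. = FALSE)
  c(neonates  = sum(lengths < neonate_max),
    juveniles = sum(lengths >= neonate_max & lengths < adult_min),
    adults    = sum(lengths >= adult_min))
}

## Internal: empty individual table
empty_individuals <- function() {
  data.frame(age = integer(0), length = numeric(0),
             max_lifetime = integer(0), days_since_brood = integer(0),
             starve = integer(0), eggs = numeric(0))
}

#' Initial population state
#'
#' Seeds the system with 5 neonates and 3 adults, each assigned a random
#' but thereafter fixed maximum lifetime (the model's only source of
#' stochasticity).  Draws are taken from the current RNG stream in a fixed
#' order (neonates first), so a seeded stream makes the state reproducible.
#'
#' @param lh A [life_history_params()] object.
#' @return An object of class `population_state` with elements `day`,
#'   `individuals` (data frame) and `food`.
#' @export
initial_state <- function(lh = life_history_params()) {
  stopifnot(inherits(lh, "life_history"))
  n0 <- 5L
  a0 <- 3L
  lt <- draw_lifetimes(n0 + a0, lh)
  ind <- data.frame(
    age = rep(0L, n0 + a0),
    length = c(rep(lh$neonate_length, n0), rep(lh$init_adult_length, a0)),
    max_lifetime = lt,
    days_since_brood = rep(0L, n0 + a0),
    starve = rep(0L, n0 + a0),
    eggs = rep(0, n0 + a0))
  structure(list(day = 0L, individuals = ind, food = lh$init_food),
            class = "population_state")
}

## Internal: uniform integer lifetime draws from the run's RNG stream.
draw_lifetimes <- function(n, lh) {
  if (n == 0L) return(integer(0))
  r <- lh$lifetime_range
  r[1] + sample.int(r[2] - r[1] + 1L, n, replace = TRUE) - 1L
}

#' Advance the population by one day
#'
#' Applies, in fixed order: (1) food decay and replenishment by the
#' constant daily input; (2) ingestion, proportional to body length
#' squared and a saturating function of food density, with proportional
#' down-scaling when total demand exceeds the pool (competition);
#' (3) somatic growth toward the asymptotic length, scaled by the realised
#' ration fraction; (4) reproduction, where adults whose days-since-brood
#' counter has reached the brood interval release
#' `round(brood_max * ration * (1 - inhibition))` neonates, each receiving
#' a fresh maximum-lifetime draw; (5) survival, removing individuals that
#' have completed their maximum lifetime or starved for `starve_days`
#' consecutive days; (6) age and day counters advance.  The RNG is
#' consulted only for the lifetime draws of newborns; everything else is
#' deterministic given the state.
#'
#' An extinct population is a legal absorbing state: the step returns an
#' empty population with the food pool still updating.
#'
#' @param state A `population_state`.
#' @param cfg A [treatment_config()].
#' @return The `population_state` one day later.
#' @export
step_day <- function(state, cfg) {
  stopifnot(inherits(state, "population_state"),
            inherits(cfg, "treatment_config"))
  lh <- cfg$life_history
  ind <- state$individuals
  food <- state$food * (1 - lh$food_decay) + lh$food_input

  if (nrow(ind) > 0L) {
    ## work on plain vectors; the data frame is rebuilt once at the end
    age <- ind$age; len <- ind$length; mlt <- ind$max_lifetime
    dsb <- ind$days_since_brood; stv <- ind$starve; eggs <- ind$eggs

    ## (2) ingestion under competition for the shared pool
    sat <- food / (food + lh$half_saturation)
    cap <- lh$ingestion_coef * len^2                # max ingestion, mg C/day
    demand <- cap * sat
    total_demand <- sum(demand)
    comp <- if (total_demand > food && total_demand > 0) food / total_demand
            else 1
    food <- max(0, food - total_demand * comp)
    ration <- sat * comp                            # realised fraction in [0,1]

    ## (3) growth stalls under food shortage
    len <- pmin(lh$asymptotic_length,
                len + lh$growth_rate * (lh$asymptotic_length - len) * ration)

    ## (4) reproduction: adults accrue fecundity continuously at
    ## (brood_max / brood_interval) * ration * (1 - inhibition) eggs/day;
    ## at each brood date the integer part is released and the fractional
    ## remainder carries over, so small sub-lethal inhibition shifts the
    ## realised birth rate smoothly instead of being lost to rounding
    adult <- len >= lh$adult_min
    inh <- reproduction_inhibition(cfg$concentration, cfg$dose_response)
    eggs[adult] <- eggs[adult] +
      lh$brood_max / lh$brood_interval * ration * (1 - inh)
    brooding <- adult & dsb >= lh$brood_interval
    n_new <- 0L
    born_len <- numeric(0)
    if (any(brooding)) {
      broods <- as.integer(floor(eggs[brooding]))
      eggs[brooding] <- eggs[brooding] - broods
      ## maternal provisioning: better-fed mothers release larger
      ## neonates, staggering cohort development (deterministic)
      neo_len <- lh$neonate_length *
        (1 - lh$provision_spread / 2 + lh$provision_spread * ration)
      dsb[brooding] <- 0L
      n_new <- sum(broods)
      born_len <- rep(neo_len, n_new)
    }

    ## (5) survival: lifetime completion, starvation, optional acute kill
    stv <- ifelse(ration < lh$starve_coef * len, stv + 1L, 0L)
    keep <- (age < mlt) & (stv < lh$starve_days)
    haz <- acute_hazard(cfg$concentration, cfg$dose_response)
    if (haz > 0 && any(keep)) {
      ## deterministic cull of the oldest fraction (no extra RNG use)
      alive <- which(keep)
      n_kill <- floor(haz * length(alive))
      if (n_kill > 0) {
        keep[alive[order(-age[alive])][seq_len(n_kill)]] <- FALSE
      }
    }

    ## (6) ageing, brood counters, newborns
    age <- age[keep] + 1L
    len <- len[keep]
    mlt <- mlt[keep]
    dsb <- dsb[keep] + ifelse(len >= lh$adult_min, 1L, 0L)
    stv <- stv[keep]
    eggs <- eggs[keep]
    if (n_new > 0L) {
      age <- c(age, rep(0L, n_new))
      len <- c(len, born_len)
      mlt <- c(mlt, draw_lifetimes(n_new, lh))
      dsb <- c(dsb, rep(0L, n_new))
      stv <- c(stv, rep(0L, n_new))
      eggs <- c(eggs, rep(0, n_new))
    }
    ind <- data.frame(age = age, length = len, max_lifetime = mlt,
                      days_since_brood = dsb, starve = stv, eggs = eggs)
  }

  structure(list(day = state$day + 1L, individuals = ind, food = food),
            class = "population_state")
}

#' Simulate one population run
#'
#' Seeds the RNG, builds the initial state (5 neonates + 3 adults with
#' random fixed lifetimes), iterates [step_day()] for `cfg$n_days` days and
#' records a census after every update; the day-0 census is taken before
#' any update, so the series has `n_days + 1` rows.
#'
#' @param cfg A [treatment_config()].
#' @param seed Integer RNG seed for this run.
#' @return An `abundance_series`: a data frame with columns `day`,
#'   `neonates`, `juveniles`, `adults`, `total` and attributes
#'   `concentration`, `run`, `seed`.
#' @export
run_simulation <- function(cfg, seed) {
  stopifnot(inherits(cfg, "treatment_config"))
  set.seed(as.integer(seed))
  lh <- cfg$life_history
  state <- initial_state(lh)
  nd <- cfg$n_days
  counts <- matrix(0L, nrow = nd + 1L, ncol = 3L,
                   dimnames = list(NULL, c("neonates", "juveniles", "adults")))
  counts[1L, ] <- classify_by_length(state$individuals$length,
                                     lh$neonate_max, lh$adult_min)
  for (t in seq_len(nd)) {
    state <- step_day(state, cfg)
    counts[t + 1L, ] <- if (nrow(state$individuals) > 0L) {
      classify_by_length(state$individuals$length, lh$neonate_max, lh$adult_min)
    } else c(0L, 0L, 0L)
  }
  abundance_series(data.frame(day = 0:nd,
                              neonates = counts[, 1L],
                              juveniles = counts[, 2L],
                              adults = counts[, 3L],
                              total = as.integer(rowSums(counts))),
                   concentration = cfg$concentration,
                   run = NA_integer_, seed = as.integer(seed))
}

#' Construct / validate an abundance series
#'
#' @param df Data frame with integer columns `day`, `neonates`,
#'   `juveniles`, `adults`, `total`; days must be contiguous from 0 and
#'   the class counts must sum to `total` on every day.
#' @param concentration,run,seed Metadata stored as attributes.
#' @return The validated data frame with class `abundance_series`.
#' @export
abundance_series <- function(df, concentration = NA_real_,
                             run = NA_integer_, seed = NA_integer_) {
  need <- c("day", "neonates", "juveniles", "adults", "total")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("abundance series is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  if (!identical(as.integer(df$day), seq.int(0L, nrow(df) - 1L))) {
    gap <- which(as.integer(df$day) != seq.int(0L, nrow(df) - 1L))[1]
    stop("days must be contiguous from 0; first irregular row: ", gap,
         call. = FALSE)
  }
  if (any(df[-1] < 0)) stop("abundance counts must be non-negative",
                            call. = FALSE)
  if (any(df$neonates + df$juveniles + df$adults != df$total)) {
    stop("class counts do not sum to total", call. = FALSE)
  }
  structure(df, class = c("abundance_series", "data.frame"),
            concentration = concentration, run = run, seed = seed)
}

#' Simulate a Monte-Carlo ensemble at one concentration
#'
#' Run `i` (1-based) uses seed `base_seed + i`.  Because the seed does not
#' depend on the concentration, ensembles generated at different
#' concentrations with the same `base_seed` share their initial lifetime
#' draws run-by-run, which makes run-index pairing across treatments
#' meaningful for the paired signed-rank tests downstream.
#'
#' @param cfg A [treatment_config()] (`n_runs >= 2`).
#' @return List of `n_runs` [abundance_series()] objects.
#' @export
run_ensemble <- function(cfg) {
  stopifnot(inherits(cfg, "treatment_config"))
  if (cfg$n_runs < 2L) stop("n_runs must be at least 2", call. = FALSE)
  lapply(seq_len(cfg$n_runs), function(i) {
    s <- run_simulation(cfg, seed = cfg$base_seed + i)
    attr(s, "run") <- i
    s
  })
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("Abundance series:", nrow(x) - 1L, "days, concentration",
      attr(x, "concentration"), "ug/l, run", attr(x, "run"),
      ", seed", attr(x, "seed"), "\n")
  cat("Final census:", x$neonates[nrow(x)], "neonates,",
      x$juveniles[nrow(x)], "juveniles,", x$adults[nrow(x)], "adults\n")
  invisible(x)
}
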