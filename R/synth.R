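#' Specification of one synthetic cohort case
#'
#' Encodes the immunophenotype structure the detection method assumes.
#' A healthy case carries three lymphocyte populations — kappa-expressing
#' B cells (x > 0), lambda-expressing B cells (x < 0), both CD19-high, and
#' CD19-negative T cells — in nearly even kappa/lambda proportions. A CLL
#' case carries one light-chain-restricted CD5+ B clone (z > 0) plus
#' T cells; an FL case one CD10+ clone (z < 0) plus T cells. Scatter and
#' CD45 channels carry a lymphocyte and a granulocyte population for the
#' gating stages, and doublets are injected by doubling FSC-A.
#'
#' @param cohort `"Normal"`, `"CLL"`, or `"FL"`.
#' @param n_events Total events in the case (lymphocytes plus other
#'   leukocytes, before doublet injection).
#' @param dominance Light chain of the malignant clone (patient cohorts),
#'   `"kappa"` or `"lambda"`.
#' @param global_shift Length-3 rigid shift of the case in the 3-D model
#'   space (applied to the kappa, CD19, and CD5 channels), emulating
#'   instrument/batch variation.
#' @param doublet_rate Fraction of events turned into doublets.
#' @param non_lymph_frac Fraction of events that are non-lymphocyte
#'   leukocytes (removed by the CD45/SSC gate).
#' @param separation Difficulty knob scaling the distances between cluster
#'   means; 1 is the default easy regime (>= 6 pooled-sd separations),
#'   smaller values shrink the separations to probe failure modes.
#' @param proportions Optional named vector of lymphocyte population
#'   proportions (must sum to 1); defaults per cohort.
#' @param seed Integer seed; the same spec always generates the same case.
#' @return A `cohort_spec` object for [generate_case()].
#' @export
cohort_spec <- function(cohort, n_events = 1500L, dominance = "kappa",
                        global_shift = c(0, 0, 0), doublet_rate = 0.02,
                        non_lymph_frac = 0.35, separation = 1,
                        proportions = NULL, seed = 1L) {
  cohort <- match.arg(cohort, COHORTS)
  dominance <- match.arg(dominance, c("kappa", "lambda"))
  stopifnot(n_events >= 1L, length(global_shift) == 3L,
            doublet_rate >= 0, doublet_rate <= 0.5,
            non_lymph_frac >= 0, non_lymph_frac < 1, separation > 0)
  default_props <- switch(cohort,
    Normal = c(kappa_B = 0.25, lambda_B = 0.25, T = 0.50),
    CLL = c(clone_B = 0.6, T = 0.4),
    FL = c(clone_B = 0.6, T = 0.4))
  proportions <- proportions %||% default_props
  if (abs(sum(proportions) - 1) > 1e-8 || any(proportions < 0)) {
    stop("population proportions must be non-negative and sum to 1")
  }
  if (!identical(sort(names(proportions)), sort(names(default_props)))) {
    stop("proportions must name the populations: ",
         paste(names(default_props), collapse = ", "))
  }
  structure(list(cohort = cohort, n_events = as.integer(n_events),
                 dominance = dominance,
                 global_shift = as.numeric(global_shift),
                 doublet_rate = doublet_rate,
                 non_lymph_frac = non_lymph_frac,
                 separation = separation, proportions = proportions,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-population 9-channel means and standard deviations. Fluorescence is
# on an arbitrary transformed scale: "low" (unstained background) ~ 1,
# "high" separated by >= 6 pooled sd at separation = 1.
population_panel <- function(spec) {
  s <- spec$separation
  lo <- 1
  hi <- 1 + 5 * s       # kappa/lambda/CD5/CD10 positive level
  cd19_hi <- 1 + 7 * s  # pan-B marker
  fluor_sd <- 0.6
  base <- c("FSC-A" = 50000, "FSC-H" = 50000, "SSC-A" = 1500,
            "CD45" = 9, "CD5" = lo, "CD10" = lo, "CD19" = lo,
            "kappa" = lo, "lambda" = lo)
  base_sd <- c("FSC-A" = 4000, "FSC-H" = 0, "SSC-A" = 300,
               "CD45" = 0.5, "CD5" = fluor_sd, "CD10" = fluor_sd,
               "CD19" = 0.8, "kappa" = fluor_sd, "lambda" = fluor_sd)
  pop <- list()
  add <- function(name, ...) {
    mu <- base
    tweaks <- c(...)
    mu[names(tweaks)] <- tweaks
    pop[[name]] <<- list(mean = mu, sd = base_sd)
  }
  light_hi <- if (spec$dominance == "kappa") "kappa" else "lambda"
  switch(spec$cohort,
    Normal = {
      add("kappa_B", kappa = hi, CD19 = cd19_hi)
      add("lambda_B", lambda = hi, CD19 = cd19_hi)
      add("T", CD19 = lo)
    },
    CLL = {
      add("clone_B", CD19 = cd19_hi, CD5 = hi)
      pop$clone_B$mean[light_hi] <- hi
      add("T", CD19 = lo)
    },
    FL = {
      add("clone_B", CD19 = cd19_hi, CD10 = hi)
      pop$clone_B$mean[light_hi] <- hi
      add("T", CD19 = lo)
    })
  # non-lymphocyte leukocytes: CD45 dimmer, high side scatter
  pop$other <- list(
    mean = replace(base, c("FSC-A", "SSC-A", "CD45"), c(70000, 6000, 6.5)),
    sd = replace(base_sd, c("FSC-A", "SSC-A", "CD45"), c(8000, 800, 0.6)))
  pop
}

#' Generate one synthetic flow cytometry case
#'
#' Draws events from the Gaussian populations encoded in a
#' [cohort_spec()], emits all nine channels (five fluorescence markers for
#' the 3-D projection; FSC/SSC/CD45 for doublet removal and lymphocyte
#' gating), injects doublets by doubling FSC-A, and applies the case's
#' rigid global shift. Per-event ground-truth labels (population,
#' lymphocyte flag, doublet flag) are kept in the table's `truth` field.
#'
#' @param spec A [cohort_spec()].
#' @param case_id Case identifier.
#' @return An [event_table()] with ground-truth annotations.
#' @export
generate_case <- function(spec, case_id = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  case_id <- case_id %||% paste0(tolower(spec$cohort), "-", spec$seed)
  with_seed(spec$seed, {
    panel <- population_panel(spec)
    probs <- c(spec$proportions * (1 - spec$non_lymph_frac),
               other = spec$non_lymph_frac)
    counts <- as.vector(stats::rmultinom(1L, spec$n_events, probs))
    names(counts) <- names(probs)
    n <- spec$n_events
    exprs <- matrix(0, n, length(SEMANTIC_CHANNELS),
                    dimnames = list(NULL, SEMANTIC_CHANNELS))
    population <- rep(names(counts), counts)
    row <- 1L
    for (p in names(counts)) {
      np <- counts[[p]]
      if (np == 0L) next
      mu <- panel[[p]]$mean
      sd <- panel[[p]]$sd
      for (ch in SEMANTIC_CHANNELS) {
        exprs[row:(row + np - 1L), ch] <-
          stats::rnorm(np, mu[[ch]], sd[[ch]])
      }
      row <- row + np
    }
    # FSC-H tracks FSC-A with ~4% ratio noise, so singlets sit at
    # FSC-A/FSC-H ~ 1
    exprs[, "FSC-H"] <- exprs[, "FSC-A"] /
      stats::rnorm(n, 1, 0.04)
    is_doublet <- rep(FALSE, n)
    n_doub <- round(spec$doublet_rate * n)
    if (n_doub > 0L) {
      idx <- sample.int(n, n_doub)
      exprs[idx, "FSC-A"] <- 2 * exprs[idx, "FSC-A"]
      is_doublet[idx] <- TRUE
    }
    # rigid shift of the 3-D projection via one channel per axis
    exprs[, "kappa"] <- exprs[, "kappa"] + spec$global_shift[1L]
    exprs[, "CD19"] <- exprs[, "CD19"] + spec$global_shift[2L]
    exprs[, "CD5"] <- exprs[, "CD5"] + spec$global_shift[3L]
    perm <- sample.int(n)
    truth <- data.frame(population = population,
                        is_lymphocyte = population != "other",
                        is_doublet = is_doublet,
                        stringsAsFactors = FALSE)[perm, , drop = FALSE]
    rownames(truth) <- NULL
    event_table(exprs[perm, , drop = FALSE], case_id = case_id,
                cohort = spec$cohort, truth = truth)
  })
}

#' Generate full synthetic cohorts
#'
#' Draws whole cohorts of cases with per-case random global shifts, event
#' counts, and (for patients) light-chain dominance. Per-case seeds are
#' derived from `master_seed`, so a cohort set is fully reproducible. Event
#' counts per case are drawn uniformly from per-cohort ranges centered on
#' the typical per-case lymphocyte yields of a clinical panel (healthy
#' cases largest, FL smallest).
#'
#' @param n_normal,n_cll,n_fl Cases per cohort.
#' @param master_seed Master seed for the whole collection.
#' @param events_range Named list of `c(min, max)` event-count ranges.
#' @param shift_range Per-axis global shifts are drawn uniformly from
#'   `[-shift_range, shift_range]`.
#' @param doublet_rate Doublet fraction for every case.
#' @param separation Difficulty knob, see [cohort_spec()].
#' @return List of [event_table()] cases (normals, then CLL, then FL).
#' @export
generate_cohorts <- function(n_normal = 44L, n_cll = 21L, n_fl = 15L,
                             master_seed = 1L,
                             events_range = list(Normal = c(1100, 1700),
                                                 CLL = c(650, 1000),
                                                 FL = c(450, 700)),
                             shift_range = 2, doublet_rate = 0.02,
                             separation = 1) {
  counts <- c(Normal = n_normal, CLL = n_cll, FL = n_fl)
  with_seed(master_seed, {
    total <- sum(counts)
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    i <- 0L
    out <- list()
    for (cohort in COHORTS) {
      for (j in seq_len(counts[[cohort]])) {
        i <- i + 1L
        rng <- events_range[[cohort]]
        spec <- cohort_spec(
          cohort = cohort,
          n_events = sample(seq(rng[1L], rng[2L]), 1L),
          dominance = sample(c("kappa", "lambda"), 1L),
          global_shift = stats::runif(3L, -shift_range, shift_range),
          doublet_rate = doublet_rate,
          separation = separation,
          seed = seeds[i])
        out[[i]] <- generate_case(
          spec, case_id = sprintf("%s-%02d", tolower(cohort), j))
      }
    }
    out
  })
}
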