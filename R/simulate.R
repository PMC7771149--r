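#' True parameter sets used by the synthetic-data generator
#'
#' Documented coefficient sets, on the logit scale for the defense traits and
#' in mm for the morphometrics, whose signs and magnitudes reproduce the
#' qualitative effect structure of the study system:
#' * instar-1 neckteeth are canalized (mostly 1-3 teeth regardless of
#'   kairomone or UVR);
#' * instar-2 neckteeth appear only under kairomone exposure (2-3 teeth for
#'   clone UNI without UVR) and are suppressed by UVR;
#' * pedestals are induced by kairomone and strongly suppressed by UVR in
#'   instar 1, more weakly in instar 2;
#' * UVR decreases body length, body width and spina length; kairomone does
#'   not affect size.
#'
#' Coefficients are indexed by the default design-matrix columns
#' ([defense_design_spec] for the defense traits, [morpho_design_spec] for
#' the morphometrics; the latter is shared between instars via its instar
#' factor, so `default_true_params(1)` and `default_true_params(2)` return
#' the same morphometric parameter set).
#'
#' @param instar 1 or 2.
#' @return List with elements `defense` (betas, thresholds, random-effect
#'   scales) and `morpho` (B, sigma_u, Sigma).
#' @export
default_true_params <- function(instar) {
  instar <- as.integer(instar)
  if (!instar %in% c(1L, 2L)) stop("instar must be 1 or 2", call. = FALSE)
  cols <- c("(Intercept)", "cloneUNI", "kairomone1", "uvr1",
            "cloneUNI:kairomone1", "cloneUNI:uvr1", "kairomone1:uvr1")
  if (instar == 1L) {
    beta_N <- c(-0.4, 0, 0.2, -0.2, 0, 0, 0)
    beta_P <- c(0, 0, 3, -2, 0, 0, 0)
  } else {
    beta_N <- c(-3, 0, 2.4, -0.5, 0.6, 0, -1.5)
    beta_P <- c(-1, 0, 2.5, -1.5, 0, 0, 0)
  }
  names(beta_N) <- names(beta_P) <- cols
  defense <- list(beta_N = beta_N, beta_P = beta_P, tau = c(0, 3),
                  sigma_N = 0.5, sigma_P = 0.5)

  mcols <- colnames(build_design_matrix(
    data.frame(clone = "P5", instar = "1", kairomone = "0", uvr = "0"),
    morpho_design_spec()))
  B <- matrix(0, length(mcols), 3,
              dimnames = list(mcols, MORPHO_TRAITS))
  B["(Intercept)", ] <- c(0.67, 0.40, 0.30)
  B["instar2", ] <- c(0.20, 0.10, 0.02)
  B["uvr1", ] <- c(-0.05, -0.025, -0.06)
  B["cloneUNI", ] <- c(0.01, 0.005, 0)
  sds <- c(0.035, 0.025, 0.05)
  R <- matrix(c(1, 0.8, 0.3,
                0.8, 1, 0.25,
                0.3, 0.25, 1), 3, 3)
  morpho <- list(B = B, sigma_u = c(0.015, 0.010, 0.015),
                 Sigma = tcrossprod(sds) * R)
  list(defense = defense, morpho = morpho)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the two experiments: a 2-clone x kairomone x UVR full
#' factorial with 6 mothers per clone-by-treatment cell (study range 5-7)
#' and 5-10 offspring per mother, at least 50% UVR mortality before instar 2
#' (default per-juvenile probability 0.55), per-instar body-length ranges of
#' 0.55-0.8 mm (instar 1) and 0.75-1.0 mm (instar 2) enforced by rejection,
#' and one empty design cell (no instar-1 data for clone P5 under
#' +kairomone/+UVR); plus a kairomone-effectivity trial with 3 treatments x
#' 4 exposure durations, 2 mothers and 10 juveniles per cell.
#'
#' @param clones Clone labels.
#' @param mothers_per_treatment Mothers per clone-by-treatment cell.
#' @param offspring_per_mother Integer range (length 2) of clutch sizes.
#' @param uvr_instar2_mortality Per-juvenile probability of failing to reach
#'   instar 2 under UVR.
#' @param include_missing_cell Drop instar-1 records of clone P5 under
#'   +kairomone/+UVR?
#' @param true_params_instar1,true_params_instar2 Output of
#'   [default_true_params].
#' @param body_length_ranges List with elements `"1"` and `"2"`: mm
#'   intervals enforced on simulated body lengths per instar.
#' @param effectivity_mothers_per_cell,effectivity_offspring_per_mother
#'   Design of the effectivity trial (2 mothers x 5 offspring = 10
#'   juveniles per treatment-by-duration cell).
#' @param seed Integer master seed; per-cell substreams are derived from it
#'   so adding a treatment cell does not shuffle the draws of other cells.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(clones = c("UNI", "P5"),
                             mothers_per_treatment = 6L,
                             offspring_per_mother = c(5L, 10L),
                             uvr_instar2_mortality = 0.55,
                             include_missing_cell = TRUE,
                             true_params_instar1 = default_true_params(1),
                             true_params_instar2 = default_true_params(2),
                             body_length_ranges = list(`1` = c(0.55, 0.80),
                                                       `2` = c(0.75, 1.00)),
                             effectivity_mothers_per_cell = 2L,
                             effectivity_offspring_per_mother = 5L,
                             seed = 1L) {
  stopifnot(length(clones) >= 1, mothers_per_treatment >= 1,
            length(offspring_per_mother) == 2,
            offspring_per_mother[1] >= 1,
            offspring_per_mother[2] >= offspring_per_mother[1],
            uvr_instar2_mortality >= 0, uvr_instar2_mortality <= 1)
  for (r in body_length_ranges) {
    if (length(r) != 2 || diff(r) <= 0) {
      stop("body_length_ranges must be intervals of positive width",
           call. = FALSE)
    }
  }
  structure(list(clones = clones,
                 mothers_per_treatment = as.integer(mothers_per_treatment),
                 offspring_per_mother = as.integer(offspring_per_mother),
                 uvr_instar2_mortality = uvr_instar2_mortality,
                 include_missing_cell = isTRUE(include_missing_cell),
                 true_params_instar1 = true_params_instar1,
                 true_params_instar2 = true_params_instar2,
                 body_length_ranges = body_length_ranges,
                 effectivity_mothers_per_cell =
                   as.integer(effectivity_mothers_per_cell),
                 effectivity_offspring_per_mother =
                   as.integer(effectivity_offspring_per_mother),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Load a generator configuration from a YAML file
#'
#' Accepts a flat YAML mapping of the [generator_config] arguments (scalar
#' and vector fields only; true parameter sets always come from
#' [default_true_params]).
#' @param path Path to a YAML file.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(generator_config)),
                     c("true_params_instar1", "true_params_instar2"))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    stop("unknown generator-config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(generator_config, vals)
}

# Deterministic substream seed for a labelled cell: polynomial string hash
# folded into [0, 2^31). Cells are seeded independently, so adding or
# removing a cell leaves every other cell's draws unchanged.
substream_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

draw_categorical <- function(p) {
  # one draw from probabilities p (row vector)
  findInterval(stats::runif(1), cumsum(p)) + 1L
}

# One truncated-MVN morphometric draw: rejection into {length in range,
# all components positive}.
draw_morpho <- function(mu, L_chol, range, max_tries = 10000L) {
  for (i in seq_len(max_tries)) {
    y <- mu + drop(crossprod(L_chol, stats::rnorm(3)))
    if (y[1] >= range[1] && y[1] <= range[2] && all(y > 0)) return(y)
  }
  stop("morphometric rejection sampling failed; check ranges vs parameters",
       call. = FALSE)
}

defense_eta <- function(x, defense) {
  c(N = sum(x * defense$beta_N), P = sum(x * defense$beta_P))
}

#' Simulate the main 2-clone kairomone-by-UVR experiment
#'
#' For every clone-by-treatment cell, mothers receive independent per-instar
#' random intercepts for both defense traits and a shared trivariate
#' morphometric intercept; each of her juveniles then gets an instar-1
#' record (neckteeth ~ Binomial(5, logit), pedestal ~ cumulative-logit,
#' morphometrics ~ truncated trivariate Gaussian) and, if it survives --
#' under UVR each juvenile independently fails to reach instar 2 with the
#' configured mortality -- an instar-2 record drawn with the instar-2
#' parameters. A fixed seed yields an identical table.
#'
#' @param config A [generator_config].
#' @return A validated juvenile-record data frame (see
#'   [read_juvenile_table]).
#' @export
simulate_main_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  dspec <- defense_design_spec()
  mspec <- morpho_design_spec()
  tp <- list(`1` = config$true_params_instar1, `2` = config$true_params_instar2)
  rows <- list()
  for (clone in config$clones) {
    for (kairo in c(FALSE, TRUE)) {
      for (uvr in c(FALSE, TRUE)) {
        key <- sprintf("main|%s|K%d|U%d", clone, kairo, uvr)
        set.seed(substream_seed(config$seed, key))
        xdef <- drop(build_design_matrix(
          data.frame(clone = clone, kairomone = kairo, uvr = uvr), dspec))
        xmor <- lapply(c("1", "2"), function(ins) drop(build_design_matrix(
          data.frame(clone = clone, instar = ins, kairomone = kairo,
                     uvr = uvr), mspec)))
        names(xmor) <- c("1", "2")
        L_chol <- chol(tp[["1"]]$morpho$Sigma)
        for (m in seq_len(config$mothers_per_treatment)) {
          uid <- make_mother_uid(clone, kairo, uvr, m)
          u_def <- lapply(tp, function(p) c(
            N = stats::rnorm(1, 0, p$defense$sigma_N),
            P = stats::rnorm(1, 0, p$defense$sigma_P)))
          u_mor <- stats::rnorm(3, 0, tp[["1"]]$morpho$sigma_u)
          n_off <- sample(seq(config$offspring_per_mother[1],
                              config$offspring_per_mother[2]), 1)
          for (j in seq_len(n_off)) {
            survived <- if (uvr) {
              stats::runif(1) >= config$uvr_instar2_mortality
            } else TRUE
            for (ins in c("1", "2")) {
              if (ins == "2" && !survived) next
              p <- tp[[ins]]
              eta <- defense_eta(xdef, p$defense)
              eta <- eta + u_def[[ins]]
              k <- stats::rbinom(1, NECKTEETH_TRIALS, stats::plogis(eta["N"]))
              ped <- PEDESTAL_LEVELS[draw_categorical(
                ordinal_category_probs(eta["P"], p$defense$tau)[1, ])]
              mu <- drop(xmor[[ins]] %*% p$morpho$B) + u_mor
              y <- draw_morpho(mu, L_chol, config$body_length_ranges[[ins]])
              rows[[length(rows) + 1L]] <- list(
                clone = clone, kairomone = kairo, uvr = uvr,
                instar = as.integer(ins), mother_uid = uid,
                neckteeth = k, pedestal = ped,
                body_length_mm = y[1], body_width_mm = y[2],
                spina_length_mm = y[3], survived_to_instar2 = survived)
            }
          }
        }
      }
    }
  }
  df <- data.frame(
    clone = vapply(rows, `[[`, "", "clone"),
    kairomone = vapply(rows, `[[`, NA, "kairomone"),
    uvr = vapply(rows, `[[`, NA, "uvr"),
    instar = vapply(rows, `[[`, 0L, "instar"),
    mother_uid = vapply(rows, `[[`, "", "mother_uid"),
    neckteeth = vapply(rows, `[[`, 0L, "neckteeth"),
    pedestal = vapply(rows, `[[`, "", "pedestal"),
    body_length_mm = vapply(rows, `[[`, 0, "body_length_mm"),
    body_width_mm = vapply(rows, `[[`, 0, "body_width_mm"),
    spina_length_mm = vapply(rows, `[[`, 0, "spina_length_mm"),
    survived_to_instar2 = vapply(rows, `[[`, NA, "survived_to_instar2"),
    stringsAsFactors = FALSE)
  if (config$include_missing_cell) {
    drop_idx <- df$clone == "P5" & df$instar == 1L & df$kairomone & df$uvr
    df <- df[!drop_idx, , drop = FALSE]
  }
  rownames(df) <- NULL
  validate_juvenile_table(df)
}

#' Simulate the kairomone-effectivity trial
#'
#' Three treatments (control without kairomone; kairomone suspensions
#' exposed to PAR or to UVR) crossed with four exposure durations (2/4/6/8
#' h), two clone-UNI mothers and five offspring per cell -- 10 juveniles per
#' cell, 120 records in total, scored at instar 2. The PAR and UVR cells
#' share identical trait-generating parameters (UVR exposure of the
#' suspension does not degrade the kairomone), while the control generates
#' near-zero induction; exposure duration has no effect by construction.
#'
#' @param config A [generator_config].
#' @return A validated effectivity-record data frame.
#' @export
simulate_effectivity_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  dspec <- defense_design_spec()
  p2 <- config$true_params_instar2$defense
  rows <- list()
  for (treatment in EFFECTIVITY_TREATMENTS) {
    kairo <- treatment != "control"
    xdef <- drop(build_design_matrix(
      data.frame(clone = "UNI", kairomone = kairo, uvr = FALSE), dspec))
    eta0 <- defense_eta(xdef, p2)
    for (hours in EXPOSURE_HOURS) {
      key <- sprintf("eff|%s|T%d", treatment, hours)
      set.seed(substream_seed(config$seed, key))
      for (m in seq_len(config$effectivity_mothers_per_cell)) {
        uid <- make_effectivity_mother_uid(treatment, hours, m)
        u <- c(N = stats::rnorm(1, 0, p2$sigma_N),
               P = stats::rnorm(1, 0, p2$sigma_P))
        for (j in seq_len(config$effectivity_offspring_per_mother)) {
          eta <- eta0 + u
          k <- stats::rbinom(1, NECKTEETH_TRIALS, stats::plogis(eta["N"]))
          ped <- PEDESTAL_LEVELS[draw_categorical(
            ordinal_category_probs(eta["P"], p2$tau)[1, ])]
          rows[[length(rows) + 1L]] <- list(
            treatment = treatment, exposure_hours = hours, mother_uid = uid,
            neckteeth = k, pedestal = ped)
        }
      }
    }
  }
  df <- data.frame(
    treatment = vapply(rows, `[[`, "", "treatment"),
    exposure_hours = vapply(rows, `[[`, 0L, "exposure_hours"),
    mother_uid = vapply(rows, `[[`, "", "mother_uid"),
    neckteeth = vapply(rows, `[[`, 0L, "neckteeth"),
    pedestal = vapply(rows, `[[`, "", "pedestal"))
  rownames(df) <- NULL
  validate_effectivity_table(df)
}
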