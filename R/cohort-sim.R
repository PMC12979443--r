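# Seeded synthetic knee-osteoarthritis (KOA) cohort generator. Group-wise
# marginals (mean/SD for continuous, category proportions for discrete)
# follow the published baseline tables of a 541-patient cohort split by
# concern about falling (CAF: FES-I >= 28, n = 360; no CAF, n = 181).
# Features with no printed group difference are generated group-independent.

feature_spec <- function(name, kind, clamp = NULL, mean = NULL, sd = NULL,
                         prob = NULL, levels = NULL) {
  if (kind == "continuous") {
    stopifnot(length(mean) == 2, length(sd) == 2, all(sd > 0))
    if (!is.null(clamp)) {
      if (any(mean < clamp[1]) || any(mean > clamp[2]))
        stop("infeasible clamp range for feature '", name,
             "': excludes a group mean")
    }
  } else {
    stopifnot(is.matrix(prob), nrow(prob) == 2,
              all(abs(rowSums(prob) - 1) < 1e-9))
  }
  list(name = name, kind = kind, clamp = clamp, mean = mean, sd = sd,
       prob = prob, levels = levels)
}

#' Default synthetic KOA cohort schema
#'
#' Encodes, per outcome group (CAF = concern about falling, FES-I >= 28),
#' the published moments for age, BMI, sex, knee extensor moment, TUG time,
#' Kellgren-Lawrence grade, WOMAC pain and HADS anxiety, and whole-cohort
#' parameters (no published group split) for disease duration, gait speed,
#' WOMAC stiffness and function, employment, occupation, education, living
#' mode, and MRI bone-marrow-edema / joint-effusion findings. Continuous
#' features carry plausible clamp ranges (e.g. TUG time > 0).
#'
#' @return Named list of feature specifications.
#' @export
default_schema <- function() {
  both <- function(x) c(caf = x, nocaf = x)
  pm <- function(p1, p0) matrix(c(p1, p0), 2, byrow = TRUE,
                                dimnames = list(c("caf", "nocaf"), NULL))
  specs <- list(
    feature_spec("age", "continuous", clamp = c(18, 100),
                 mean = c(caf = 67.35, nocaf = 61.85),
                 sd = c(caf = 14.23, nocaf = 13.77)),
    feature_spec("bmi", "continuous", clamp = c(12, 50),
                 mean = c(caf = 24.97, nocaf = 23.12),
                 sd = c(caf = 3.78, nocaf = 3.15)),
    feature_spec("sex_female", "binary",
                 prob = pm(c(1 - 282 / 360, 282 / 360),
                           c(1 - 95 / 181, 95 / 181)),
                 levels = c("0", "1")),
    feature_spec("knee_extensor_moment", "continuous", clamp = c(0.1, 3),
                 mean = c(caf = 1.05, nocaf = 1.45),
                 sd = c(caf = 0.32, nocaf = 0.41)),
    feature_spec("tug_time", "continuous", clamp = c(3, 40),
                 mean = c(caf = 14.52, nocaf = 10.11),
                 sd = c(caf = 3.85, nocaf = 2.46)),
    feature_spec("kl_grade", "categorical",
                 prob = pm(c(202 / 360, 158 / 360), c(130 / 181, 51 / 181)),
                 levels = c("grade2", "grade3")),
    feature_spec("womac_pain", "continuous", clamp = c(0, 20),
                 mean = c(caf = 6.45, nocaf = 4.73),
                 sd = c(caf = 2.01, nocaf = 1.24)),
    feature_spec("hads_anxiety", "continuous", clamp = c(0, 21),
                 mean = c(caf = 10.83, nocaf = 9.11),
                 sd = c(caf = 3.31, nocaf = 2.59)),
    feature_spec("duration", "continuous", clamp = c(0.5, 60),
                 mean = both(15.82), sd = both(4.62)),
    feature_spec("gait_speed", "continuous", clamp = c(0.2, 2.5),
                 mean = both(0.92), sd = both(0.21)),
    feature_spec("womac_stiffness", "continuous", clamp = c(0, 8),
                 mean = both(2.15), sd = both(0.49)),
    feature_spec("womac_function", "continuous", clamp = c(0, 68),
                 mean = both(22.53), sd = both(9.25)),
    feature_spec("employment", "categorical",
                 prob = pm(c(0.1871, 0.2794, 0.5335),
                           c(0.1871, 0.2794, 0.5335)),
                 levels = c("employed", "unemployed", "retired")),
    feature_spec("occupation", "categorical",
                 prob = pm(c(0.5242, 0.4249, 0.0509),
                           c(0.5242, 0.4249, 0.0509)),
                 levels = c("farmer", "white_collar", "freelance")),
    feature_spec("education", "categorical",
                 prob = pm(c(0.3580, 0.5404, 0.1016),
                           c(0.3580, 0.5404, 0.1016)),
                 levels = c("primary", "middle", "college")),
    feature_spec("living_mode", "categorical",
                 prob = pm(c(0.0947, 0.5358, 0.1409, 0.2286),
                           c(0.0947, 0.5358, 0.1409, 0.2286)),
                 levels = c("alone", "spouse", "children", "family")),
    feature_spec("mri_edema", "binary",
                 prob = pm(c(1 - 0.4365, 0.4365), c(1 - 0.4365, 0.4365)),
                 levels = c("0", "1")),
    feature_spec("mri_effusion", "binary",
                 prob = pm(c(1 - 0.3603, 0.3603), c(1 - 0.3603, 0.3603)),
                 levels = c("0", "1"))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# Clamped Gaussian draw by rejection resampling (keeps moments close to the
# targets, unlike clipping).
rnorm_clamped <- function(n, mean, sd, clamp) {
  x <- rnorm(n, mean, sd)
  if (!is.null(clamp)) {
    for (it in 1:100) {
      bad <- x < clamp[1] | x > clamp[2]
      if (!any(bad)) break
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    x <- pmin(pmax(x, clamp[1]), clamp[2])
  }
  x
}

#' Generate a synthetic KOA cohort
#'
#' Draws `n_caf + n_nocaf` patient rows with the stated outcome split;
#' continuous features are per-group Gaussian with rejection resampling
#' into their clamp range, discrete features per-group categorical draws.
#' Fully seeded: the same seed reproduces the table bit for bit. No missing
#' values are generated.
#'
#' @param schema Feature schema, see [default_schema()].
#' @param n_caf,n_nocaf Group sizes (defaults 360 / 181, the published
#'   cohort).
#' @param seed Integer seed.
#' @return Data frame with one row per patient, feature columns per the
#'   schema, and a binary outcome column `caf`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort)      # 541
#' sum(cohort$caf)   # 360
#' @export
generate_cohort <- function(schema = default_schema(), n_caf = 360,
                            n_nocaf = 181, seed = 1L) {
  stopifnot(n_caf >= 1, n_nocaf >= 1)
  with_seed(derive_seed(seed, "cohort"), {
    n <- n_caf + n_nocaf
    grp <- rep(c("caf", "nocaf"), c(n_caf, n_nocaf))
    out <- list()
    for (sp in schema) {
      if (sp$kind == "continuous") {
        x <- numeric(n)
        for (g in c("caf", "nocaf")) {
          i <- grp == g
          x[i] <- rnorm_clamped(sum(i), sp$mean[g], sp$sd[g], sp$clamp)
        }
        out[[sp$name]] <- x
      } else {
        x <- character(n)
        for (g in c("caf", "nocaf")) {
          i <- grp == g
          x[i] <- sample(sp$levels, sum(i), replace = TRUE,
                         prob = sp$prob[g, ])
        }
        out[[sp$name]] <- if (sp$kind == "binary") as.integer(x) else
          factor(x, levels = sp$levels)
      }
    }
    out$caf <- as.integer(grp == "caf")
    data.frame(out, stringsAsFactors = FALSE)
  })
}

#' Dichotomize a FES-I total score into the CAF label
#'
#' The Falls Efficacy Scale-International total (16 items, range 16-64) is
#' dichotomized at the clinical cut-off of 28: scores >= 28 denote concern
#' about falling (CAF = 1).
#'
#' @param fesi_total Integer score(s) in 16..64.
#' @return Integer 0/1 label(s).
#' @examples
#' label_from_fesi(c(27, 28))  # 0 1
#' @export
label_from_fesi <- function(fesi_total) {
  if (any(fesi_total < 16 | fesi_total > 64))
    stop("FES-I total must lie in [16, 64]")
  as.integer(fesi_total >= 28)
}

#' Planted-signal dataset for feature-recovery experiments
#'
#' Two-class tabular data with a 2:1 class balance (mimicking the cohort's
#' outcome split): informative features shift their class-1 mean by
#' `effect_size` standard deviations; noise features are identically
#' distributed in both classes.
#'
#' @param n Total rows.
#' @param n_informative,n_noise Numbers of informative / noise columns.
#' @param effect_size Standardized mean shift of informative features.
#' @param seed Integer seed.
#' @return Data frame with columns `inf1..`, `noise1..` and outcome `caf`;
#'   attribute `informative` names the informative columns.
#' @export
planted_signal_dataset <- function(n = 400, n_informative = 5, n_noise = 10,
                                   effect_size = 1, seed = 1L) {
  stopifnot(n_informative >= 1, n_noise >= 0, n >= 4)
  with_seed(derive_seed(seed, "planted"), {
    n1 <- round(2 * n / 3)
    y <- rep(c(1L, 0L), c(n1, n - n1))
    X <- matrix(rnorm(n * (n_informative + n_noise)), n)
    X[y == 1, seq_len(n_informative)] <-
      X[y == 1, seq_len(n_informative)] + effect_size
    colnames(X) <- c(paste0("inf", seq_len(n_informative)),
                     if (n_noise > 0) paste0("noise", seq_len(n_noise)))
    d <- data.frame(X, caf = y)
    attr(d, "informative") <- paste0("inf", seq_len(n_informative))
    d
  })
}
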