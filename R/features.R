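# Feature inventory: 52 longitudinal features in four domains
# (12 psychological, 18 nutritional, 15 immunological, 7 performance).

PSYCH_FEATURES <- c(
  "fatigue", "stress", "sleep_quality", "resilience", "mood", "motivation",
  "anxiety", "depression", "vigor", "concentration", "wellbeing",
  "irritability"
)

NUTRITION_FEATURES <- c(
  "energy_intake", "carb_pct_energy", "protein_g_kg", "fat_pct_energy",
  "vitamin_d", "vitamin_b6", "vitamin_b12", "folate", "iron", "zinc",
  "omega3", "fiber", "magnesium", "calcium", "vitamin_c", "hydration",
  "caffeine", "antioxidant_index"
)

IMMUNE_FEATURES <- c(
  "il6", "tnf_alpha", "crp", "iga", "cortisol", "wbc", "lymphocytes",
  "neutrophils", "monocytes", "nk_cells", "igg", "igm", "il10", "il1b",
  "ifn_gamma"
)

PERFORMANCE_FEATURES <- c(
  "vo2max", "training_volume", "training_load", "resting_hr", "hrv",
  "competition_score", "recovery_index"
)

ALL_FEATURES <- c(PSYCH_FEATURES, NUTRITION_FEATURES, IMMUNE_FEATURES,
                  PERFORMANCE_FEATURES)

DIET_GROUPS <- c("high_carb", "high_protein", "balanced")
RESILIENCE_TERTILES <- c("low", "moderate", "high")

#' Feature domain lookup
#'
#' @param features Character vector of feature names (default: all 52).
#' @return Named character vector mapping feature name to its domain
#'   (`psychological`, `nutritional`, `immunological`, `performance`).
#' @export
feature_domains <- function(features = ALL_FEATURES) {
  dom <- rep(NA_character_, length(features))
  dom[features %in% PSYCH_FEATURES] <- "psychological"
  dom[features %in% NUTRITION_FEATURES] <- "nutritional"
  dom[features %in% IMMUNE_FEATURES] <- "immunological"
  dom[features %in% PERFORMANCE_FEATURES] <- "performance"
  stats::setNames(dom, features)
}

# Features where larger values indicate more physiological/psychological
# strain (+1) or better status (-1); used for the shared latent factor and
# for improvement directions. 0 = neutral filler.
FEATURE_DIRECTION <- c(
  fatigue = +1, stress = +1, sleep_quality = -1, resilience = -1,
  anxiety = +1, depression = +1, mood = -1, vigor = -1,
  il6 = +1, tnf_alpha = +1, crp = +1, iga = -1, cortisol = +1,
  vo2max = -1
)

feature_direction <- function(feature) {
  d <- FEATURE_DIRECTION[feature]
  d[is.na(d)] <- 0
  unname(d)
}

#' Default baseline calibration per dietary group
#'
#' Mean and SD for each named feature (psychological 0-10 scales; IL-6 /
#' TNF-a ng/L; CRP mg/L; IgA mg/dL; cortisol nmol/L; VO2max mL/kg/min;
#' training volume h/week), per dietary-pattern group.
#'
#' @return Named list: per feature, a list with `mean` and `sd` vectors
#'   named by group.
#' @export
default_baseline_profiles <- function() {
  p <- function(hc, hp, bal, sd_hc, sd_hp = sd_hc, sd_bal = sd_hc) {
    list(mean = c(high_carb = hc, high_protein = hp, balanced = bal),
         sd   = c(high_carb = sd_hc, high_protein = sd_hp, balanced = sd_bal))
  }
  list(
    fatigue        = p(5.8, 5.2, 4.6, 1.0),
    stress         = p(6.2, 5.6, 5.0, 0.9),
    sleep_quality  = p(6.2, 6.8, 7.4, 0.8),
    resilience     = p(4.8, 5.4, 6.0, 0.9),
    il6            = p(3.24, 2.76, 2.31, 0.82, 0.75, 0.68),
    tnf_alpha      = p(9.56, 8.84, 7.92, 1.23, 1.15, 1.08),
    crp            = p(3.85, 3.42, 2.98, 0.96, 0.88, 0.81),
    iga            = p(176.3, 185.7, 198.5, 19.2, 17.8, 18.6),
    cortisol       = p(458.3, 441.2, 436.8, 82.1, 79.5, 77.3),
    vo2max         = p(58.2, 60.1, 62.4, 6.3, 5.8, 6.1),
    training_volume = p(12.5, 12.8, 12.3, 3.1, 2.9, 3.3),
    # Macronutrient intake consistent with the dietary-pattern labelling
    # rules (values truncated to the rule windows at generation time).
    carb_pct_energy = p(64.0, 50.0, 55.0, 2.0, 2.2, 2.2),
    protein_g_kg    = p(1.00, 1.85, 1.40, 0.10, 0.12, 0.09)
  )
}

#' Default 12-month endpoint calibration (trajectory targets)
#'
#' Psychological and cortisol endpoints follow the study-change
#' calibration; immune and performance endpoints are the package's own
#' calibration with the same group ordering as the cortisol reductions.
#' Features absent here stay flat.
#'
#' @return Named list in the same shape as [default_baseline_profiles()].
#' @export
default_trajectory_targets <- function() {
  p <- function(hc, hp, bal, sd_hc, sd_hp = sd_hc, sd_bal = sd_hc) {
    list(mean = c(high_carb = hc, high_protein = hp, balanced = bal),
         sd   = c(high_carb = sd_hc, high_protein = sd_hp, balanced = sd_bal))
  }
  list(
    fatigue       = p(5.0, 4.0, 2.8, 0.9, 0.9, 0.8),
    stress        = p(5.3, 4.3, 3.3, 0.9, 0.8, 0.8),
    resilience    = p(5.5, 6.5, 7.5, 0.9, 0.8, 0.8),
    sleep_quality = p(6.6, 7.3, 8.1, 0.8),
    cortisol      = p(398.7, 342.5, 298.4, 71.4, 68.2, 62.1),
    il6           = p(3.02, 2.42, 1.85, 0.78, 0.70, 0.62),
    tnf_alpha     = p(9.10, 8.10, 6.85, 1.15, 1.08, 1.00),
    crp           = p(3.62, 3.05, 2.42, 0.90, 0.82, 0.75),
    iga           = p(183.0, 197.5, 216.0, 19.0, 18.0, 18.0),
    vo2max        = p(59.4, 62.0, 65.5, 6.0, 5.6, 5.9)
  )
}

# Generic filler features (identical across groups); means/SDs on plausible
# scales so the 52-dimensional input tensor is fully populated.
default_filler_profiles <- function() {
  f <- function(m, s) list(mean = m, sd = s)
  list(
    mood = f(6.0, 1.0), motivation = f(6.5, 1.0), anxiety = f(4.0, 1.0),
    depression = f(3.0, 1.0), vigor = f(6.0, 1.0), concentration = f(6.5, 0.9),
    wellbeing = f(6.2, 1.0), irritability = f(3.5, 1.0),
    energy_intake = f(3200, 350), fat_pct_energy = f(28, 4),
    vitamin_d = f(18, 5), vitamin_b6 = f(2.0, 0.5), vitamin_b12 = f(4.5, 1.2),
    folate = f(420, 80), iron = f(16, 4), zinc = f(12, 3),
    omega3 = f(1.6, 0.5), fiber = f(30, 7), magnesium = f(380, 70),
    calcium = f(1100, 220), vitamin_c = f(110, 30), hydration = f(3.1, 0.5),
    caffeine = f(180, 70), antioxidant_index = f(5.5, 1.2),
    wbc = f(6.1, 1.2), lymphocytes = f(2.1, 0.5), neutrophils = f(3.4, 0.9),
    monocytes = f(0.5, 0.13), nk_cells = f(0.35, 0.1), igg = f(1100, 190),
    igm = f(130, 35), il10 = f(4.8, 1.1), il1b = f(2.2, 0.6),
    ifn_gamma = f(11, 3),
    training_load = f(850, 180), resting_hr = f(52, 6), hrv = f(78, 18),
    competition_score = f(72, 9), recovery_index = f(6.5, 1.1)
  )
}

# Loading of the shared latent "strain" factor. Set from the
# equicorrelated-block canonical-correlation identity
# r1 = p*a / (1 + (p-1)*a), a = lambda^2, adjusted for the between-group
# mean separation (which also correlates the blocks when groups are
# pooled), so the pooled first canonical correlation between the
# 4-variable psychological and immune blocks is ~0.85 at baseline.
STRAIN_LOADING <- 0.66

strain_loadings <- function() {
  l <- STRAIN_LOADING
  c(
    fatigue = +l, stress = +l, sleep_quality = -l, resilience = -l,
    il6 = +l, tnf_alpha = +l, crp = +l, iga = -l,
    cortisol = +0.40, vo2max = -0.30,
    anxiety = +0.30, depression = +0.30, mood = -0.30, vigor = -0.30,
    wellbeing = -0.30, recovery_index = -0.25, hrv = -0.25
  )
}
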