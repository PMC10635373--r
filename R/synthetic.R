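#' Default feature descriptors for the synthetic cohort
#'
#' The six-family feature taxonomy the generator emits: demographics (age,
#' sex), eight binary concept indicators named by CUI-style identifiers,
#' eight radiology indicators, six cardiac features (including continuous
#' ejection fraction), six clinical-history features (including continuous
#' NIHSS and vitals) and thirteen continuous laboratory values covering every
#' shipped discretization rule.
#'
#' @return Descriptor data frame (`name`, `group`, `kind`, `sex_specific`).
#' @export
default_descriptors <- function() {
  d <- function(name, group, kind) {
    data.frame(name = name, group = group, kind = kind,
               sex_specific = name == "hemoglobin", stringsAsFactors = FALSE)
  }
  rbind(
    d("age", "DEMO", "continuous"),
    d("sex", "DEMO", "binary"),
    d(c("C0004238", "C0020538", "C0004153", "C0398623",
        "C0011849", "C0020473", "C0027051", "C0149931"), "CUI", "binary"),
    d(c("rad_frontal", "rad_basal_ganglia", "rad_thalamus",
        "rad_mca_occlusion", "rad_ica_occlusion", "rad_carotid_stenosis",
        "rad_hemorrhage", "rad_cerebellar"), "RAD", "binary"),
    d("ejection_fraction", "HRT", "continuous"),
    d(c("hrt_left_atrial_enlargement", "hrt_vegetation", "hrt_thrombus",
        "hrt_pfo", "hrt_sinus_rhythm"), "HRT", "binary"),
    d(c("nihss", "systolic_bp", "respiratory_rate"), "HEX", "continuous"),
    d(c("hex_tobacco", "hex_ethanol", "hex_drug_use"), "HEX", "binary"),
    d(c("sodium", "bun", "alt", "ast", "wbc", "hematocrit", "hemoglobin",
        "triglycerides", "hdl", "ldl", "tsh", "ptt", "a1c"), "LAB", "continuous")
  )
}

#' Class-conditional effect specification
#'
#' Per-class Bernoulli rates for binary features and per-class mean shifts for
#' continuous features. The default plants the etiology-typical associations:
#' carotid stenosis/occlusion and atherosclerosis elevated in large-artery
#' atherosclerosis (class 1); atrial fibrillation, left-atrial enlargement and
#' intracardiac thrombus elevated in cardioembolism (class 2); basal-ganglia
#' and thalamus infarct locations elevated in small-vessel disease (class 3);
#' hypercoagulability elevated and age markedly lower in other-determined
#' strokes (class 4). Features without an override keep their base rate in
#' every class, so [zero_effect_spec()] makes the classes exchangeable.
#'
#' @param strength Multiplier in `[0, 1]` scaling every class effect toward
#'   the base rate (1 = full printed effects, 0 = no effects).
#' @return A list with elements `binary` (data frame: `feature`, `base`,
#'   `r1`..`r4`) and `continuous` (data frame: `feature`, `mean`, `sd`,
#'   `d1`..`d4` additive class shifts).
#' @export
effect_spec <- function(strength = 1) {
  stopifnot(strength >= 0, strength <= 1)
  b <- function(feature, base, r1 = NA, r2 = NA, r3 = NA, r4 = NA)
    data.frame(feature = feature, base = base, r1 = r1, r2 = r2, r3 = r3,
               r4 = r4, stringsAsFactors = FALSE)
  binary <- rbind(
    b("sex", 0.48),
    b("C0004238", 0.15, r2 = 0.80),                      # atrial fibrillation
    b("C0020538", 0.70, r3 = 0.85),                      # hypertensive disease
    b("C0004153", 0.15, r1 = 0.75),                      # atherosclerosis
    b("C0398623", 0.04, r4 = 0.60),                      # hypercoagulability
    b("C0011849", 0.40),                                 # diabetes
    b("C0020473", 0.25),                                 # hyperlipidemia
    b("C0027051", 0.10, r2 = 0.25),                      # myocardial infarction
    b("C0149931", 0.05, r4 = 0.20),                      # migraine
    b("rad_frontal", 0.30, r2 = 0.55, r3 = 0.08),
    b("rad_basal_ganglia", 0.10, r3 = 0.65),
    b("rad_thalamus", 0.08, r3 = 0.50),
    b("rad_mca_occlusion", 0.15, r1 = 0.45, r2 = 0.40),
    b("rad_ica_occlusion", 0.08, r1 = 0.55),
    b("rad_carotid_stenosis", 0.10, r1 = 0.70),
    b("rad_hemorrhage", 0.07),
    b("rad_cerebellar", 0.10),
    b("hrt_left_atrial_enlargement", 0.12, r2 = 0.55),
    b("hrt_vegetation", 0.02, r4 = 0.25),
    b("hrt_thrombus", 0.05, r2 = 0.35),
    b("hrt_pfo", 0.08, r4 = 0.40),
    b("hrt_sinus_rhythm", 0.75, r2 = 0.30),
    b("hex_tobacco", 0.25, r1 = 0.45),
    b("hex_ethanol", 0.20),
    b("hex_drug_use", 0.05, r4 = 0.15)
  )
  for (cc in c("r1", "r2", "r3", "r4")) {
    eff <- binary[[cc]]
    binary[[cc]] <- ifelse(is.na(eff), binary$base,
                           binary$base + strength * (eff - binary$base))
  }
  cn <- function(feature, mean, sd, d1 = 0, d2 = 0, d3 = 0, d4 = 0)
    data.frame(feature = feature, mean = mean, sd = sd,
               d1 = d1 * strength, d2 = d2 * strength, d3 = d3 * strength,
               d4 = d4 * strength, stringsAsFactors = FALSE)
  continuous <- rbind(
    cn("age", 70, 13, d4 = -18),
    cn("nihss", 7, 5, d2 = 3, d3 = -4),
    cn("systolic_bp", 145, 22, d3 = 8),
    cn("respiratory_rate", 17, 3),
    cn("ejection_fraction", 55, 8, d2 = -12),
    cn("sodium", 138, 3), cn("bun", 18, 6), cn("alt", 25, 10),
    cn("ast", 25, 10), cn("wbc", 8, 2.5), cn("hematocrit", 40, 5),
    cn("hemoglobin", 13.5, 1.8), cn("triglycerides", 140, 60),
    cn("hdl", 48, 13), cn("ldl", 95, 30), cn("tsh", 2, 1.2),
    cn("ptt", 30, 5), cn("a1c", 6, 1.2)
  )
  list(binary = binary, continuous = continuous)
}

#' Exchangeable (no-signal) effect specification
#'
#' All classes share the base rates and means, so labels carry no information
#' about features; used for null calibration of the pipeline.
#' @return As [effect_spec()].
#' @export
zero_effect_spec <- function() effect_spec(strength = 0)

#' Site specification for the synthetic cohort
#'
#' @param id Site identifier.
#' @param missingness Named per-group missingness rates in `[0, 1)`. Defaults
#'   emulate the reported per-family completeness of a large academic stroke
#'   cohort (roughly 4--10 percent incompleteness, laboratory data least complete).
#' @param note_style Template style for rendered notes (`"a"` or `"b"`).
#' @param shift Additive covariate shift, in standard-deviation units, applied
#'   to continuous HEX/LAB features at this site.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(id, missingness = c(CUI = 0.043, RAD = 0.059,
                                          HRT = 0.046, HEX = 0.097,
                                          LAB = 0.100),
                      note_style = "a", shift = 0) {
  stopifnot(all(missingness >= 0), all(missingness < 1))
  structure(list(id = id, missingness = missingness,
                 note_style = note_style, shift = shift),
            class = "site_spec")
}

#' Cryptogenic mixture specification
#'
#' Cryptogenic (code 5) records are generated as a mixture: with probability
#' `no_class_fraction` a record has no latent etiology (features at base
#' rates); otherwise a latent class 1--4 is drawn from `mixture_weights` and
#' the record's features are drawn from that class's distribution with every
#' effect attenuated toward the null by `attenuation` (1 = full class effect,
#' 0 = indistinguishable from no-class noise).
#'
#' @param mixture_weights Weights over latent classes 1--4; default
#'   proportional to the non-cryptogenic prior.
#' @param attenuation Attenuation factor in `[0, 1]`.
#' @param no_class_fraction Fraction with no latent class.
#' @return A list of class `cryptogenic_spec`.
#' @export
cryptogenic_spec <- function(mixture_weights = c(0.21, 0.31, 0.13, 0.09) / 0.74,
                             attenuation = 0.7, no_class_fraction = 0.2) {
  stopifnot(length(mixture_weights) == 4, all(mixture_weights >= 0),
            attenuation >= 0, attenuation <= 1,
            no_class_fraction >= 0, no_class_fraction <= 1)
  structure(list(mixture_weights = mixture_weights / sum(mixture_weights),
                 attenuation = attenuation,
                 no_class_fraction = no_class_fraction),
            class = "cryptogenic_spec")
}

#' Generator configuration
#'
#' @param n Total cohort size, split across sites proportionally to
#'   `site_fractions`.
#' @param priors Class priors over adjudicated labels 1--5. The default
#'   follows the merged derivation-cohort etiology distribution
#'   (0.21, 0.31, 0.13, 0.09, 0.26).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param effects An [effect_spec()].
#' @param sites List of [site_spec()]s; default two sites with distinct note
#'   templates, missingness profiles and a mild covariate shift at the second.
#' @param cryptogenic A [cryptogenic_spec()].
#' @param site_fractions Proportions of `n` per site.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n = 2000,
                             priors = c(0.21, 0.31, 0.13, 0.09, 0.26),
                             seed = 1701,
                             effects = effect_spec(),
                             sites = list(
                               site_spec("site_a"),
                               site_spec("site_b",
                                         missingness = c(CUI = 0.055, RAD = 0.080,
                                                         HRT = 0.070, HEX = 0.085,
                                                         LAB = 0.077),
                                         note_style = "b", shift = 0.25)
                             ),
                             cryptogenic = cryptogenic_spec(),
                             site_fractions = NULL) {
  stopifnot(length(priors) == 5, abs(sum(priors) - 1) < 1e-8, n >= 1)
  if (is.null(site_fractions)) site_fractions <- rep(1 / length(sites), length(sites))
  stopifnot(length(site_fractions) == length(sites),
            abs(sum(site_fractions) - 1) < 1e-8)
  structure(list(n = n, priors = priors, seed = seed, effects = effects,
                 sites = sites, cryptogenic = cryptogenic,
                 site_fractions = site_fractions),
            class = "generator_config")
}

#' Generate a labeled synthetic stroke cohort
#'
#' Draws adjudicated labels from the class priors, a hidden latent class for
#' cryptogenic records per the cryptogenic mixture, then features
#' class-conditionally: independent Bernoulli indicators and clipped normal
#' continuous values (age to `[18, 100]`, NIHSS to non-negative integers,
#' laboratory values rounded to one decimal so rendered notes round-trip
#' exactly). Site-specific covariate shift is an additive offset in SD units
#' on continuous HEX/LAB features, and per-group missingness is injected per
#' site. Byte-identical output under the same configuration and seed.
#'
#' @param config A [generator_config()].
#' @return A [feature_matrix()] whose `meta` has columns `id`, `site`, `age`,
#'   `sex`, `toast` (1--5) and `latent` (1--4 or `NA`).
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n = 100, seed = 7))
#' table(coh$meta$toast)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  desc <- default_descriptors()
  ns <- diff(round(cumsum(c(0, config$site_fractions)) * config$n))
  if (config$n < 8)
    warning("cohort smaller than twice the class count; stratified use downstream may fail")
  eff <- config$effects
  cs <- config$cryptogenic
  all_vals <- list(); all_meta <- list()
  for (si in seq_along(config$sites)) {
    site <- config$sites[[si]]
    n <- ns[si]
    if (n == 0L) next
    toast <- sample(1:5, n, replace = TRUE, prob = config$priors)
    latent <- rep(NA_integer_, n)
    atten <- rep(1, n)
    cry <- which(toast == 5L)
    if (length(cry) > 0L) {
      has_latent <- stats::runif(length(cry)) >= cs$no_class_fraction
      latent[cry[has_latent]] <- sample(1:4, sum(has_latent), replace = TRUE,
                                        prob = cs$mixture_weights)
      atten[cry] <- ifelse(has_latent, cs$attenuation, 0)
    }
    # effective class used for feature generation (base-rate when no latent)
    gen_class <- ifelse(toast == 5L, ifelse(is.na(latent), 1L, latent), toast)

    vals <- as.data.frame(matrix(NA_real_, n, nrow(desc)))
    names(vals) <- desc$name
    for (j in seq_len(nrow(eff$binary))) {
      row <- eff$binary[j, ]
      pr_class <- c(row$r1, row$r2, row$r3, row$r4)[gen_class]
      p <- row$base + atten * (pr_class - row$base)
      vals[[row$feature]] <- stats::rbinom(n, 1L, p)
    }
    for (j in seq_len(nrow(eff$continuous))) {
      row <- eff$continuous[j, ]
      d_class <- c(row$d1, row$d2, row$d3, row$d4)[gen_class]
      grp <- desc$group[desc$name == row$feature]
      off <- if (grp %in% c("HEX", "LAB")) site$shift * row$sd else 0
      x <- stats::rnorm(n, row$mean + atten * d_class + off, row$sd)
      vals[[row$feature]] <- x
    }
    vals$age <- round(pmin(pmax(vals$age, 18), 100))
    vals$nihss <- round(pmax(vals$nihss, 0))
    vals$systolic_bp <- round(pmax(vals$systolic_bp, 70))
    vals$respiratory_rate <- round(pmax(vals$respiratory_rate, 8))
    vals$ejection_fraction <- round(pmin(pmax(vals$ejection_fraction, 10), 80))
    for (lab in eff$continuous$feature[!eff$continuous$feature %in%
                                       c("age", "nihss", "systolic_bp",
                                         "respiratory_rate", "ejection_fraction")])
      vals[[lab]] <- round(pmax(vals[[lab]], 0.1), 1)

    meta <- data.frame(
      id = sprintf("%s_%04d", site$id, seq_len(n)),
      site = site$id,
      age = vals$age,
      sex = ifelse(vals$sex == 1, "female", "male"),
      toast = toast, latent = latent, stringsAsFactors = FALSE
    )
    fm <- feature_matrix(vals, desc, meta)
    fm <- inject_missingness(fm, site$missingness)
    all_vals[[si]] <- fm$values
    all_meta[[si]] <- fm$meta
  }
  feature_matrix(do.call(rbind, all_vals), desc, do.call(rbind, all_meta))
}

#' Mask feature cells missing-completely-at-random by group
#'
#' Each cell of a group's columns is masked independently at that group's
#' rate; observed cells are unchanged. Demographics are never masked (rendered
#' notes require complete demographics).
#'
#' @param fm A [feature_matrix()].
#' @param rates Named vector of rates in `[0, 1)` keyed by group tag; groups
#'   not named are untouched.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [generate_cohort()]).
#' @return The masked `feature_matrix`.
#' @export
inject_missingness <- function(fm, rates, seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"),
            all(rates >= 0), all(rates < 1))
  if (!is.null(seed)) set.seed(seed)
  for (g in names(rates)) {
    if (g == "DEMO" || rates[[g]] == 0) next
    cols <- fm$descriptors$name[fm$descriptors$group == g]
    for (cl in cols) {
      mask <- stats::runif(nrow(fm$values)) < rates[[g]]
      fm$values[[cl]][mask] <- NA
    }
  }
  fm
}
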