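# Synthetic cohort and biochemistry generator. The defaults encode the study
# conditions of the SCAR16 cohort: Table-1-style categorical frequencies, the
# biochemical input locations/scales used by the reduced models, and the
# linear effect structures of the published equations plus residual noise.

.stop_alleles <- c("K144*", "Y207*", "E238*", "Y230Cfs*8")

#' Parameters for the synthetic SCAR16 cohort generator
#'
#' The defaults are the cohort's own study conditions: 24 patients; sex,
#' ancestry, homozygosity, tendon-reflex and hypogonadism frequencies as in
#' the cohort summary table; biochemical inputs at the centers/scales of the
#' reduced biochemical models (%HSP70 Ub 43.7/15.5, %Chain 69.9/39.0, K_D
#' 7.8/6.0, B_max 212.0/16.6); cognitive dysfunction assigned per patient with
#' probability 0.94 given a Ubox allele and 0.59 otherwise. The allele-level
#' Ubox probability (0.31) is calibrated so the implied CD prevalence is the
#' cohort's 71%. SARA is induced from the clinical effect model
#' (intercept 17.2; CD +/-5.6, ancestry offsets, TR +/-2.7) and AOO from the
#' biochemical model (intercept 20.6) plus a homozygosity offset of -/+6 years
#' (the 12-year onset gap), each with Gaussian residual noise.
#'
#' @param n_patients number of patients to generate.
#' @param seed RNG seed; identical seed and parameters give identical tables.
#' @param categorical_freqs named list of per-level probabilities for `sex`,
#'   `ancestry`, `tr`, `hypogonadism`, plus scalar `homozygous`.
#' @param ubox_cd_prob,other_cd_prob P(CD = Y) given that the patient does /
#'   does not carry a Ubox allele.
#' @param ubox_allele_prob probability a sampled substitution allele falls in
#'   the Ubox domain.
#' @param stop_second_allele_prob probability the second allele of a compound
#'   heterozygote is a preterminal stop codon.
#' @param biochem_means,biochem_sds named location/scale for the biochemical
#'   variables (`pct_hsp70_ub, pct_chain, kd, bmax, tm, pct_e`).
#' @param dimer_prob probability a mutant retains a dimeric distribution.
#' @param effect_model list with elements `sara` and `aoo`: the
#'   [linear_equation]s that induce the responses
#'   (default [scar16_reference_equations()]).
#' @param hom_aoo_offset additive AOO offset (years) for homozygotes;
#'   heterozygotes receive the negated offset.
#' @param noise_sd named residual standard deviations for `sara` and `aoo`.
#'   The cohort models do not report residual SDs, so these are free
#'   parameters of the generator.
#' @param domain_map mutation-to-domain map used to sample alleles.
#' @return validated parameter list of class `generator_params`.
#' @export
generator_params <- function(
    n_patients = 24,
    seed = 1,
    categorical_freqs = list(
      sex = c(male = 0.54, female = 0.46),
      ancestry = c(AMR = 0.04, SAS = 0.04, MENA = 0.25, EUR = 0.34, EAS = 0.33),
      tr = c(Y = 0.75, N = 0.25),
      hypogonadism = c(Y = 0.17, N = 0.83),
      homozygous = 0.46
    ),
    ubox_cd_prob = 0.94,
    other_cd_prob = 0.59,
    ubox_allele_prob = 0.31,
    stop_second_allele_prob = 0.7,
    biochem_means = c(pct_hsp70_ub = 43.7, pct_chain = 69.9, kd = 7.8,
                      bmax = 212.0, tm = 47, pct_e = 60),
    biochem_sds = c(pct_hsp70_ub = 15.5, pct_chain = 39.0, kd = 6.0,
                    bmax = 16.6, tm = 4, pct_e = 30),
    dimer_prob = 7 / 13,
    effect_model = NULL,
    hom_aoo_offset = -6,
    noise_sd = c(sara = 7, aoo = 5),
    domain_map = default_domain_map()) {
  if (is.null(effect_model)) {
    eqs <- scar16_reference_equations()
    effect_model <- list(sara = eqs$sara_clinical, aoo = eqs$aoo_biochem)
  }
  stopifnot(n_patients >= 0, length(seed) == 1L)
  probs <- c(unlist(categorical_freqs), ubox_cd_prob, other_cd_prob,
             ubox_allele_prob, stop_second_allele_prob, dimer_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(biochem_sds <= 0) || any(noise_sd < 0)) {
    stop("scale parameters must be positive")
  }
  if (!all(c("sara", "aoo") %in% names(effect_model)) ||
      !all(vapply(effect_model, inherits, logical(1), "linear_equation"))) {
    stop("effect_model must hold linear_equation elements 'sara' and 'aoo'")
  }
  structure(list(
    n_patients = n_patients, seed = seed,
    categorical_freqs = categorical_freqs,
    ubox_cd_prob = ubox_cd_prob, other_cd_prob = other_cd_prob,
    ubox_allele_prob = ubox_allele_prob,
    stop_second_allele_prob = stop_second_allele_prob,
    biochem_means = biochem_means, biochem_sds = biochem_sds,
    dimer_prob = dimer_prob, effect_model = effect_model,
    hom_aoo_offset = hom_aoo_offset, noise_sd = noise_sd,
    domain_map = domain_map
  ), class = "generator_params")
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.sample_level <- function(n, freqs) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# draw normal values clamped at physical bounds; truncation (not resampling)
# slightly biases the mean when sd/mean is large -- documented behaviour
.trunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

#' Generate a synthetic SCAR16 cohort and biochemistry table
#'
#' Draws patient demographics and allele assignments from the categorical
#' frequencies, one biochemistry record per mapped substitution (plus the
#' wild-type reference row with its fixed values: K_D 2.9, B_max 204,
#' %HSP70 Ub 73.1, %Chain 100), and induces SARA from the clinical effect
#' model and AOO from the biochemical effect model of the patient's
#' substitution alleles. SARA is clamped to the scale bounds [0, 40] and AOO
#' floored at 0.5 years. Identical parameters and seed give identical tables.
#'
#' @param params a [generator_params] object.
#' @return list with elements `cohort` (patient tibble), `biochem`
#'   (biochemistry tibble incl. WT row) and `params`.
#' @export
generate_cohort <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  .with_seed(params$seed, {
    map <- params$domain_map
    ubox_muts <- map$mutation[map$domain == "Ubox"]
    other_muts <- map$mutation[map$domain != "Ubox"]
    n <- params$n_patients
    fr <- params$categorical_freqs

    # one biochemistry record per mapped substitution + the WT reference
    bm <- params$biochem_means; bs <- params$biochem_sds
    nm <- nrow(map)
    biochem <- tibble::tibble(
      mutation = map$mutation,
      domain = map$domain,
      kd = pmax(.trunc_norm(nm, bm[["kd"]], bs[["kd"]]), 0.05),
      bmax = .trunc_norm(nm, bm[["bmax"]], bs[["bmax"]]),
      pct_hsp70_ub = .trunc_norm(nm, bm[["pct_hsp70_ub"]], bs[["pct_hsp70_ub"]]),
      pct_chain = .trunc_norm(nm, bm[["pct_chain"]], bs[["pct_chain"]]),
      tm = .trunc_norm(nm, bm[["tm"]], bs[["tm"]], lower = 20, upper = 100),
      oligomer = ifelse(stats::runif(nm) < params$dimer_prob,
                        "dimer", "higher_order"),
      pct_e = .trunc_norm(nm, bm[["pct_e"]], bs[["pct_e"]])
    )
    wt <- tibble::tibble(mutation = "WT", domain = NA_character_,
                         kd = 2.9, bmax = 204, pct_hsp70_ub = 73.1,
                         pct_chain = 100, tm = bm[["tm"]], oligomer = "dimer",
                         pct_e = 100)
    biochem <- rbind(biochem, wt)

    draw_mut <- function(k) {
      ifelse(stats::runif(k) < params$ubox_allele_prob,
             sample(ubox_muts, k, replace = TRUE),
             sample(other_muts, k, replace = TRUE))
    }
    homozygous <- stats::runif(n) < fr$homozygous
    allele1 <- draw_mut(n)
    allele2 <- ifelse(
      homozygous, allele1,
      ifelse(stats::runif(n) < params$stop_second_allele_prob,
             sample(.stop_alleles, n, replace = TRUE),
             draw_mut(n)))
    sex <- .sample_level(n, fr$sex)
    ancestry <- .sample_level(n, fr$ancestry)
    tr <- .sample_level(n, fr$tr)
    hypogonadism <- .sample_level(n, fr$hypogonadism)

    has_ubox <- allele1 %in% ubox_muts | allele2 %in% ubox_muts
    p_cd <- ifelse(has_ubox, params$ubox_cd_prob, params$other_cd_prob)
    cd <- ifelse(stats::runif(n) < p_cd, "Y", "N")

    # patient-level biochemistry = copy-weighted mean over substitution alleles
    bio_of <- function(m) biochem[match(m, biochem$mutation), , drop = FALSE]
    bvars <- c("pct_hsp70_ub", "pct_chain", "kd", "bmax")
    patient_bio <- matrix(NA_real_, n, length(bvars),
                          dimnames = list(NULL, bvars))
    for (i in seq_len(n)) {
      alleles <- c(allele1[i], allele2[i])
      alleles <- alleles[!is_stop_allele(alleles)]
      rows <- bio_of(alleles)
      patient_bio[i, ] <- colMeans(as.data.frame(rows[, bvars]))
    }

    sara_mu <- evaluate_equation(
      params$effect_model$sara,
      tibble::tibble(cd = cd, ancestry = ancestry, tr = tr))
    sara <- pmin(pmax(sara_mu + stats::rnorm(n, 0, params$noise_sd[["sara"]]),
                      0), 40)
    aoo_mu <- evaluate_equation(params$effect_model$aoo,
                                tibble::as_tibble(as.data.frame(patient_bio))) +
      ifelse(homozygous, params$hom_aoo_offset, -params$hom_aoo_offset)
    aoo <- pmax(aoo_mu + stats::rnorm(n, 0, params$noise_sd[["aoo"]]), 0.5)

    cohort <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      sex = sex, ancestry = ancestry, homozygous = homozygous,
      allele1 = allele1, allele2 = allele2,
      aoo = round(aoo, 1), sara = round(sara, 1),
      cd = cd, tr = tr, hypogonadism = hypogonadism
    )
    list(cohort = validate_cohort(cohort), biochem = validate_biochem(biochem),
         params = params)
  })
}

#' Generate a regression dataset from a known linear equation
#'
#' Parameter-recovery harness: draws continuous inputs from normal
#' distributions, samples categorical factor levels, and sets each response to
#' the equation's prediction plus Gaussian noise. With `noise_sd = 0` the
#' responses equal the predictions exactly.
#'
#' @param equation a [linear_equation], or a list of them sharing inputs
#'   (multi-response generation).
#' @param n number of observations.
#' @param noise_sd residual standard deviation (scalar, recycled across
#'   responses, or named per response).
#' @param seed RNG seed.
#' @param input_dists optional named list of `c(mean, sd)` per continuous
#'   input; defaults to each term's center/scale.
#' @param level_probs optional named list of level probabilities per factor;
#'   defaults to uniform over the equation's levels.
#' @return tibble of inputs plus one response column per equation.
#' @export
generate_from_equation <- function(equation, n, noise_sd = 0, seed = 1,
                                   input_dists = NULL, level_probs = NULL) {
  eqs <- if (inherits(equation, "linear_equation")) list(equation) else equation
  stopifnot(length(eqs) >= 1,
            all(vapply(eqs, inherits, logical(1), "linear_equation")))
  resp_names <- vapply(eqs, `[[`, character(1), "response")
  if (anyDuplicated(resp_names)) {
    resp_names <- make.unique(resp_names)
  }
  if (length(noise_sd) == 1L) {
    noise_sd <- stats::setNames(rep(noise_sd, length(eqs)), resp_names)
  }
  .with_seed(seed, {
    inputs <- tibble::tibble(.rows = n)
    for (eq in eqs) {
      ct <- eq$continuous
      if (!is.null(ct)) {
        for (i in seq_len(nrow(ct))) {
          nm <- ct$name[i]
          if (!is.null(inputs[[nm]])) next
          d <- if (!is.null(input_dists[[nm]])) input_dists[[nm]] else
            c(ct$center[i], ct$scale[i])
          inputs[[nm]] <- stats::rnorm(n, d[1], d[2])
        }
      }
      for (f in names(eq$categorical)) {
        if (!is.null(inputs[[f]])) next
        levs <- names(eq$categorical[[f]])
        pr <- if (!is.null(level_probs[[f]])) level_probs[[f]] else
          rep(1 / length(levs), length(levs))
        inputs[[f]] <- sample(levs, n, replace = TRUE, prob = pr)
      }
    }
    out <- inputs
    for (k in seq_along(eqs)) {
      mu <- evaluate_equation(eqs[[k]], inputs)
      out[[resp_names[k]]] <- mu + stats::rnorm(n, 0, noise_sd[[resp_names[k]]])
    }
    out
  })
}
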