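# Typed data model for the SCAR16 cohort and the mutant-CHIP biochemistry
# table: validated CSV readers/writers and per-allele expansion.

.sex_levels <- c("male", "female")
.ancestry_levels <- c("AMR", "SAS", "MENA", "EUR", "EAS")
.yn_levels <- c("Y", "N")
.domain_levels <- c("TPR", "CC", "Ubox")
.oligomer_levels <- c("dimer", "higher_order")

.patient_fields <- c("patient_id", "sex", "ancestry", "homozygous",
                     "allele1", "allele2", "aoo", "sara", "cd", "tr",
                     "hypogonadism")
.biochem_fields <- c("mutation", "domain", "kd", "bmax", "pct_hsp70_ub",
                     "pct_chain", "tm", "oligomer", "pct_e")

# preterminal stop codons and frameshifts are written like K144*, Y230Cfs*8
is_stop_allele <- function(x) grepl("\\*|fs|fx", x, ignore.case = TRUE)

.load_error <- function(row, field, msg) {
  stop("row ", row, ", field '", field, "': ", msg, call. = FALSE)
}

.check_levels <- function(x, levels, field, allow_na = FALSE) {
  for (i in seq_along(x)) {
    if (is.na(x[i])) {
      if (!allow_na) .load_error(i, field, "missing value not permitted")
      next
    }
    if (!x[i] %in% levels) {
      .load_error(i, field, paste0("unknown level '", x[i], "' (expected ",
                                   paste(levels, collapse = "/"), ")"))
    }
  }
}

#' Validate a patient cohort table
#'
#' Enforces the cohort data contract: SARA within the 0-40 scale bounds,
#' positive age of onset, enumerated categorical levels, and agreement between
#' the homozygosity flag and the two allele columns. Missing values are
#' permitted only for `aoo` and `hypogonadism` (tests drop incomplete rows for
#' their own variables).
#'
#' @param cohort data frame with the patient fields.
#' @return the validated cohort as a tibble, columns in canonical order.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(.patient_fields, names(cohort))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort <- cohort[.patient_fields]
  cohort$patient_id <- as.character(cohort$patient_id)
  cohort$allele1 <- as.character(cohort$allele1)
  cohort$allele2 <- as.character(cohort$allele2)
  if (is.character(cohort$homozygous)) {
    cohort$homozygous <- toupper(trimws(cohort$homozygous)) %in%
      c("TRUE", "T", "YES", "Y", "1")
  }
  cohort$homozygous <- as.logical(cohort$homozygous)
  .check_levels(cohort$sex, .sex_levels, "sex")
  .check_levels(cohort$ancestry, .ancestry_levels, "ancestry")
  .check_levels(cohort$cd, .yn_levels, "cd")
  .check_levels(cohort$tr, .yn_levels, "tr")
  .check_levels(cohort$hypogonadism, .yn_levels, "hypogonadism",
                allow_na = TRUE)
  for (i in seq_len(nrow(cohort))) {
    if (is.na(cohort$homozygous[i])) .load_error(i, "homozygous", "missing value")
    if (!is.na(cohort$aoo[i]) && cohort$aoo[i] <= 0) {
      .load_error(i, "aoo", paste0("age of onset must be > 0 (got ",
                                   cohort$aoo[i], ")"))
    }
    if (is.na(cohort$sara[i])) .load_error(i, "sara", "missing value not permitted")
    if (cohort$sara[i] < 0 || cohort$sara[i] > 40) {
      .load_error(i, "sara", paste0("SARA must lie in [0, 40] (got ",
                                    cohort$sara[i], ")"))
    }
    if (cohort$homozygous[i] && !identical(cohort$allele1[i], cohort$allele2[i])) {
      .load_error(i, "homozygous",
                  "homozygous patients must carry identical alleles")
    }
  }
  cohort
}

#' Load a patient cohort table
#'
#' Reads a UTF-8 comma-separated table whose header names the patient fields
#' (`patient_id, sex, ancestry, homozygous, allele1, allele2, aoo, sara, cd,
#' tr, hypogonadism`) and validates every record; any missing column,
#' out-of-range value or unknown categorical level is a load error naming the
#' offending row and field. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @return tibble of validated patient records.
#' @export
load_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(.patient_fields, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[.patient_fields]
  num <- function(x, field) {
    x[trimws(x) == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) .load_error(bad[1], field, paste0("not numeric: '", x[bad[1]], "'"))
    v
  }
  raw$aoo <- num(raw$aoo, "aoo")
  raw$sara <- num(raw$sara, "sara")
  raw$hypogonadism[trimws(raw$hypogonadism) == ""] <- NA
  validate_cohort(raw)
}

#' Validate a mutant-CHIP biochemistry table
#'
#' Fields: `mutation, domain, kd, bmax, pct_hsp70_ub, pct_chain, tm, oligomer,
#' pct_e`. Percent fields must be nonnegative, `kd` strictly positive, and
#' `tm` physically plausible (20-100 C). The wild-type reference row (mutation
#' `"WT"`) may leave `domain` empty.
#'
#' @param biochem data frame with the biochemistry fields.
#' @return validated tibble.
#' @export
validate_biochem <- function(biochem) {
  biochem <- tibble::as_tibble(biochem)
  missing_cols <- setdiff(.biochem_fields, names(biochem))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  biochem <- biochem[.biochem_fields]
  biochem$mutation <- as.character(biochem$mutation)
  is_wt <- biochem$mutation == "WT"
  .check_levels(ifelse(is_wt & is.na(biochem$domain), NA, biochem$domain),
                .domain_levels, "domain", allow_na = TRUE)
  if (any(!is_wt & is.na(biochem$domain))) {
    .load_error(which(!is_wt & is.na(biochem$domain))[1], "domain",
                "missing domain for a mutant record")
  }
  .check_levels(biochem$oligomer, .oligomer_levels, "oligomer", allow_na = TRUE)
  for (i in seq_len(nrow(biochem))) {
    if (is.na(biochem$kd[i]) || biochem$kd[i] <= 0) {
      .load_error(i, "kd", "binding affinity K_D must be > 0")
    }
    for (f in c("pct_hsp70_ub", "pct_chain", "pct_e")) {
      if (!is.na(biochem[[f]][i]) && biochem[[f]][i] < 0) {
        .load_error(i, f, "percent values must be >= 0")
      }
    }
    if (!is.na(biochem$tm[i]) && (biochem$tm[i] < 20 || biochem$tm[i] > 100)) {
      .load_error(i, "tm", paste0("melting temperature outside 20-100 C (got ",
                                  biochem$tm[i], ")"))
    }
  }
  biochem
}

#' @rdname validate_biochem
#' @param path path to the CSV file.
#' @export
load_biochem <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  for (f in intersect(c("domain", "oligomer"), names(raw))) {
    raw[[f]][trimws(as.character(raw[[f]])) == ""] <- NA
  }
  validate_biochem(raw)
}

#' Write cohort / biochemistry tables
#'
#' Writes the same CSV dialect the loaders read, so that a write-then-load
#' round trip reproduces records field for field.
#'
#' @param x validated cohort or biochemistry tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(validate_cohort(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_biochem <- function(x, path) {
  utils::write.csv(validate_biochem(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Mutation-to-domain map for characterized CHIP substitutions
#'
#' Ships as a versioned resource file (`extdata/chip_domain_map.csv`) mapping
#' each biochemically characterized SCAR16 substitution to the CHIP domain
#' harboring it (TPR, coiled-coil, Ubox), assigned by residue range
#' (TPR <= 127, CC 128-226, Ubox >= 227). Users may supply their own map to
#' [explode_alleles()].
#'
#' @return tibble with columns `mutation`, `domain`.
#' @export
default_domain_map <- function() {
  path <- system.file("extdata", "chip_domain_map.csv", package = "scar16pls",
                      mustWork = TRUE)
  map <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  .check_levels(map$domain, .domain_levels, "domain")
  map
}

#' Expand a patient cohort to one record per disease allele
#'
#' Association tests against protein biochemistry are run on a per-allele
#' basis: each substitution allele becomes one record carrying the patient's
#' phenotypes plus the allele's mutation and domain. Alleles encoding
#' preterminal stop codons or frameshifts (e.g. `K144*`, `Y230Cfs*8`) are
#' excluded, since the corresponding transcripts are predicted to undergo
#' nonsense-mediated decay and were never characterized biochemically.
#'
#' @param patients validated cohort tibble.
#' @param domain_map data frame mapping `mutation` to `domain`
#'   (default [default_domain_map()]).
#' @param copy_policy `"per_allele_copy"` counts a homozygous patient's
#'   mutation twice (`copies = 2`); `"per_distinct_mutation"` counts each
#'   distinct mutation once per patient (`copies = 1`).
#' @return tibble with columns `patient_id, mutation, domain, copies, cd, tr,
#'   sara, aoo` -- one row per (patient, distinct substitution mutation).
#' @export
explode_alleles <- function(patients,
                            domain_map = default_domain_map(),
                            copy_policy = c("per_allele_copy",
                                            "per_distinct_mutation")) {
  copy_policy <- match.arg(copy_policy)
  patients <- validate_cohort(patients)
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    alleles <- c(patients$allele1[i], patients$allele2[i])
    alleles <- alleles[!is.na(alleles) & !is_stop_allele(alleles)]
    if (!length(alleles)) next
    counts <- table(alleles)
    muts <- names(counts)
    unmapped <- setdiff(muts, domain_map$mutation)
    if (length(unmapped)) {
      stop("substitution(s) absent from the domain map: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    copies <- if (copy_policy == "per_allele_copy") as.integer(counts) else
      rep(1L, length(counts))
    out[[i]] <- tibble::tibble(
      patient_id = patients$patient_id[i],
      mutation = muts,
      domain = domain_map$domain[match(muts, domain_map$mutation)],
      copies = copies,
      cd = patients$cd[i], tr = patients$tr[i],
      sara = patients$sara[i], aoo = patients$aoo[i]
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(tibble::tibble(patient_id = character(), mutation = character(),
                          domain = character(), copies = integer(),
                          cd = character(), tr = character(),
                          sara = numeric(), aoo = numeric()))
  }
  do.call(rbind, out)
}

#' Merge per-allele records with protein biochemistry
#'
#' Joins the per-allele expansion of a cohort to the biochemistry table by
#' mutation, dropping the wild-type reference row. The result is the working
#' table for allele-level screens and for the PLS models of AOO and SARA as a
#' function of CHIP biochemistry.
#'
#' @param alleles output of [explode_alleles()].
#' @param biochem validated biochemistry tibble.
#' @return tibble of allele records augmented with biochemical fields.
#' @export
merge_biochem <- function(alleles, biochem) {
  biochem <- validate_biochem(biochem)
  biochem <- biochem[biochem$mutation != "WT", ]
  idx <- match(alleles$mutation, biochem$mutation)
  if (anyNA(idx)) {
    stop("no biochemistry for mutation(s): ",
         paste(unique(alleles$mutation[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  cbind_cols <- biochem[idx, setdiff(names(biochem), c("mutation", "domain"))]
  tibble::as_tibble(cbind(alleles, cbind_cols))
}
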