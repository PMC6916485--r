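test_that("cohort round-trips through CSV field for field", {
  gen <- generate_cohort(generator_params(n_patients = 24, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(gen$cohort, path)
  loaded <- load_cohort(path)
  expect_equal(nrow(loaded), 24)
  expect_equal(as.data.frame(loaded), as.data.frame(gen$cohort))
})

test_that("an empty file with a header loads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("patient_id", "sex", "ancestry", "homozygous", "allele1",
                     "allele2", "aoo", "sara", "cd", "tr", "hypogonadism"),
                   collapse = ","), path)
  expect_equal(nrow(load_cohort(path)), 0)
})

test_that("loader errors name the offending row and field", {
  p <- make_patients(3)
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- p; bad$sara[2] <- 45
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "row 2, field 'sara'")

  bad <- p; bad$ancestry[3] <- "AFR"
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "row 3, field 'ancestry'.*unknown level")

  bad <- p; bad$aoo[1] <- -2
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "row 1, field 'aoo'")

  bad <- p; bad$allele2[1] <- "L123V"  # homozygous flag contradicts alleles
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "homozygous")

  write.csv(p[setdiff(names(p), "sara")], path, row.names = FALSE)
  expect_error(load_cohort(path), "missing column.*sara")
})

test_that("missing values are tolerated only for aoo and hypogonadism", {
  p <- make_patients(3)
  p$aoo[1] <- NA
  p$hypogonadism[2] <- NA
  expect_silent(validate_cohort(p))
  p$sara[3] <- NA
  expect_error(validate_cohort(p), "sara")
})

test_that("biochemistry table round-trips and enforces bounds", {
  gen <- generate_cohort(generator_params(seed = 5))
  expect_equal(nrow(gen$biochem), 14)  # 13 mutants + WT reference
  wt <- gen$biochem[gen$biochem$mutation == "WT", ]
  expect_equal(c(wt$kd, wt$bmax, wt$pct_hsp70_ub, wt$pct_chain),
               c(2.9, 204, 73.1, 100))

  path <- withr::local_tempfile(fileext = ".csv")
  write_biochem(gen$biochem, path)
  expect_equal(as.data.frame(load_biochem(path)), as.data.frame(gen$biochem))

  bad <- gen$biochem; bad$kd[1] <- -1
  expect_error(validate_biochem(bad), "kd")
  bad <- gen$biochem; bad$tm[2] <- 150
  expect_error(validate_biochem(bad), "tm")
  bad <- gen$biochem; bad$pct_chain[3] <- -5
  expect_error(validate_biochem(bad), "pct_chain")
})

test_that("per-allele expansion follows the copy policy and drops stop alleles", {
  p <- make_patients(2)  # P1 homozygous T246M; P2 compound het L123V / K144*
  al <- explode_alleles(p[1, ])
  expect_equal(nrow(al), 1)
  expect_equal(al$copies, 2L)
  expect_equal(al$domain, "Ubox")

  al1 <- explode_alleles(p[1, ], copy_policy = "per_distinct_mutation")
  expect_equal(al1$copies, 1L)

  al2 <- explode_alleles(p[2, ])
  expect_equal(al2$mutation, "L123V")
  expect_equal(al2$copies, 1L)

  allstop <- p[1, ]
  allstop$homozygous <- TRUE
  allstop$allele1 <- allstop$allele2 <- "K144*"
  expect_equal(nrow(explode_alleles(allstop)), 0)

  unmapped <- p[2, ]; unmapped$allele1 <- "Q999Z"
  expect_error(explode_alleles(unmapped), "Q999Z")
})

test_that("expansion is bounded by 2n and invariant to patient order", {
  gen <- generate_cohort(generator_params(n_patients = 30, seed = 9))
  al <- explode_alleles(gen$cohort)
  expect_lte(nrow(al), 2 * nrow(gen$cohort))
  perm <- sample(nrow(gen$cohort))
  al2 <- explode_alleles(gen$cohort[perm, ])
  key <- function(d) d[order(d$patient_id, d$mutation), ]
  expect_equal(as.data.frame(key(al)), as.data.frame(key(al2)),
               ignore_attr = TRUE)
  # every expanded record carries its patient's phenotypes
  i <- match(al$patient_id, gen$cohort$patient_id)
  expect_equal(al$sara, gen$cohort$sara[i])
  expect_equal(al$cd, gen$cohort$cd[i])
})

test_that("allele records merge with biochemistry by mutation", {
  gen <- generate_cohort(generator_params(n_patients = 20, seed = 2))
  merged <- merge_biochem(explode_alleles(gen$cohort), gen$biochem)
  expect_true(all(c("kd", "bmax", "pct_hsp70_ub", "pct_chain") %in%
                    names(merged)))
  i <- match(merged$mutation, gen$biochem$mutation)
  expect_equal(merged$kd, gen$biochem$kd[i])
})
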