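test_that("the packaged Bering Sea records load and match the printed parameters", {
  expect_warning(
    recs <- load_species_records(skatedemog_example("bering_sea_skates.csv")),
    "alpha50 \\(17.7\\) lies outside")
  expect_named(recs, c("Bathyraja lindbergi", "Bathyraja maculata",
                       "Bathyraja minispinosa", "Bathyraja taranetzi",
                       "Bathyraja trachura"))

  tr <- recs[["Bathyraja trachura"]]
  expect_equal(c(tr$omega_min, tr$omega_mode, tr$omega_max), c(35, 36, 51))
  expect_equal(tr$alpha50, 27.5)
  expect_equal(c(tr$alpha_ci_low, tr$alpha_ci_high), c(25.8, 28.1))
  expect_equal(c(tr$alpha_trunc_low, tr$alpha_trunc_high), c(25, 29))
  expect_equal(c(tr$eggcase_min, tr$eggcase_mode, tr$eggcase_max),
               c(0.64, 0.65, 0.98))
  expect_equal(c(tr$survival_min, tr$survival_max), c(0.71, 0.96))
  expect_equal(c(tr$fecundity_min, tr$fecundity_max), c(16, 52))

  ta <- recs[["Bathyraja taranetzi"]]
  expect_equal(c(ta$omega_min, ta$omega_mode, ta$omega_max), c(13, 14, 20))
  expect_equal(c(ta$alpha_trunc_low, ta$alpha_trunc_high), c(8, 10))
  expect_equal(c(ta$eggcase_min, ta$eggcase_mode, ta$eggcase_max),
               c(0.65, 0.81, 0.98))
  expect_equal(c(ta$survival_min, ta$survival_max), c(0.60, 0.91))

  mi <- recs[["Bathyraja minispinosa"]]
  expect_equal(c(mi$omega_min, mi$omega_mode, mi$omega_max), c(36, 37, 53))
  expect_equal(mi$alpha50, 23.5)
  expect_equal(c(mi$survival_min, mi$survival_max), c(0.83, 0.97))
})

test_that("the CSV and YAML dialects of the packaged records agree", {
  csv <- bering_records()
  yml <- suppressWarnings(
    load_species_records(skatedemog_example("bering_sea_skates.yaml")))
  expect_identical(names(csv), names(yml))
  for (nm in names(csv)) {
    num <- vapply(csv[[nm]], is.numeric, logical(1L))
    expect_identical(csv[[nm]][num], yml[[nm]][num])
  }
})

test_that("record validation enforces hard invariants and warns on soft ones", {
  base <- function(...) {
    args <- utils::modifyList(list(
      species_name = "test", omega_min = 10, omega_mode = 12, omega_max = 20,
      alpha50 = 5, alpha_ci_low = 4.5, alpha_ci_high = 5.5,
      alpha_trunc_low = 4, alpha_trunc_high = 6,
      fecundity_min = 16, fecundity_max = 52,
      eggcase_min = 0.6, eggcase_mode = 0.8, eggcase_max = 0.95,
      survival_min = 0.7, survival_max = 0.9), list(...))
    do.call(species_record, args)
  }
  # degenerate uniform survival is a legal point mass
  expect_s3_class(base(survival_min = 0.9, survival_max = 0.9),
                  "skate_species")
  expect_error(base(eggcase_mode = 0.99), "egg-case")
  expect_error(base(survival_min = 0.95, survival_max = 0.9), "survival")
  expect_error(base(survival_max = 1.0), "survival")
  expect_error(base(omega_mode = 25), "longevity")
  expect_error(base(alpha_trunc_high = 30), "truncation")
  expect_error(base(fecundity_min = 60), "fecundity")
  expect_error(base(alpha_ci_low = 5.5), "CI")
  expect_warning(base(alpha50 = 3.5), "outside its truncation bounds")
})

test_that("schema and parse errors identify the offending field and record", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(skatedemog_example("bering_sea_skates.csv"))
  utils::write.csv(df[, setdiff(names(df), "alpha50")], tmp,
                   row.names = FALSE)
  expect_error(suppressWarnings(load_species_records(tmp)),
               "missing field.*alpha50")

  df2 <- df
  df2$omega_max <- as.character(df2$omega_max)
  df2$omega_max[2] <- "forty-six"
  utils::write.csv(df2, tmp, row.names = FALSE)
  expect_error(suppressWarnings(load_species_records(tmp)),
               "Bathyraja maculata.*omega_max.*non-numeric")

  expect_error(load_species_records("no/such/file.csv"), "not found")
})

test_that("write/read round trip preserves every field to full precision", {
  rec <- suppressWarnings(species_record(
    "roundtrip", 10.123456789012345, 12.000000000000004, 20.99999999999999,
    5.123456789, 4.5001, 5.4999, 4.000001, 6.000002,
    16.5, 51.5, 0.612345678901234, 0.8, 0.951,
    0.712345678912345, 0.898989898989899,
    tmax_observed = 12.5, iape = 0.0271, growth_k = 0.11,
    growth_t0 = -0.45, tl_max_cm = 94, maturity_comment = "note"))
  for (ext in c(".csv", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_species_records(list(rec), path)
    back <- load_species_records(path)[[1L]]
    num <- vapply(rec, is.numeric, logical(1L))
    expect_identical(back[num], rec[num], label = ext)
    expect_identical(back$maturity_comment, "note")
  }
})

test_that("an empty species file yields an empty list with a warning", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(skatedemog_example("bering_sea_skates.csv"))
  utils::write.csv(df[0, ], tmp, row.names = FALSE)
  expect_warning(recs <- load_species_records(tmp), "no species records")
  expect_identical(recs, list())
})

test_that("the comparative table loads with 14 records, 9 of them Alaskan", {
  comp <- comparative_table()
  expect_identical(nrow(comp), 14L)
  expect_identical(sum(comp$group == "alaskan"), 9L)

  tr <- comp[comp$species_name == "Bathyraja trachura", ]
  expect_equal(tr$lambda_pub, 1.048)
  expect_equal(tr$alpha_omega_ratio, 0.75)
  expect_equal(tr$tl_max_cm, 94)
  expect_equal(tr$depth_mid_m, 1169)

  rc <- comp[comp$species_name == "Raja clavata", ]
  expect_equal(rc$lambda_pub, 0.930)
  expect_equal(rc$alpha_omega_ratio, 0.71)
  expect_identical(rc$group, "other_high_latitude")
})

test_that("comparative table validation rejects duplicates and bad values", {
  comp <- comparative_table()
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(comp, comp[3, ]), tmp, row.names = FALSE)
  expect_error(load_comparative_table(tmp), "duplicate species")

  bad <- comp
  bad$alpha_omega_ratio[1] <- 1.2
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_comparative_table(tmp), "alpha_omega_ratio")

  utils::write.csv(comp[0, ], tmp, row.names = FALSE)
  expect_warning(out <- load_comparative_table(tmp), "no comparative")
  expect_identical(nrow(out), 0L)
})
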