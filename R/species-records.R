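#' Species life-history record
#'
#' Bundles every quantity needed to parameterize the probabilistic Leslie
#' matrix model for one species: the triangular longevity PDF (`omega_*`),
#' the truncated-logistic maturity PDF (`alpha50`, its 95% CI, and the
#' effective truncation bounds), the uniform fecundity PDF (already halved
#' for a 1:1 sex ratio, so female offspring per female per year), the
#' triangular egg-case survival PDF, and the uniform annual survival range
#' spanned by the indirect mortality estimators. Optional fields carry the
#' observed maximum age, ageing precision, von Bertalanffy growth
#' parameters (needed only by the Chen-Watanabe estimator) and comparative
#' metadata (maximum total length, depth midpoint, hatch/maturity sizes).
#'
#' @param species_name species label (must be non-empty and unique within a
#'   record set).
#' @param omega_min,omega_mode,omega_max triangular longevity PDF (years).
#' @param alpha50 median age at 50% maturity (years); logistic location.
#' @param alpha_ci_low,alpha_ci_high 95% CI of `alpha50` (years).
#' @param alpha_trunc_low,alpha_trunc_high effective truncation bounds of
#'   the maturity PDF (years).
#' @param fecundity_min,fecundity_max uniform fecundity PDF (female
#'   offspring per female per year).
#' @param eggcase_min,eggcase_mode,eggcase_max triangular egg-case annual
#'   survival PDF (probability per year).
#' @param survival_min,survival_max uniform annual survival PDF
#'   (probability per year).
#' @param tmax_observed optional maximum observed age (years).
#' @param iape optional index of average percent error of the ageing.
#' @param extension_constant longevity extension constant (default 1.4).
#' @param growth_k,growth_t0 optional von Bertalanffy parameters.
#' @param tl_max_cm,depth_mid_m,size_at_hatch_cm,size_at_maturity_cm
#'   optional comparative metadata.
#' @param maturity_comment optional free-text provenance note (e.g. the
#'   first/100%-maturity ages replaced by the effective truncation bounds).
#' @return an object of class `skate_species` (a named list).
#' @seealso [load_species_records()], [draw_vital_rates()]
#' @export
species_record <- function(species_name,
                           omega_min, omega_mode, omega_max,
                           alpha50, alpha_ci_low, alpha_ci_high,
                           alpha_trunc_low, alpha_trunc_high,
                           fecundity_min, fecundity_max,
                           eggcase_min, eggcase_mode, eggcase_max,
                           survival_min, survival_max,
                           tmax_observed = NA_real_, iape = NA_real_,
                           extension_constant = 1.4,
                           growth_k = NA_real_, growth_t0 = NA_real_,
                           tl_max_cm = NA_real_, depth_mid_m = NA_real_,
                           size_at_hatch_cm = NA_real_,
                           size_at_maturity_cm = NA_real_,
                           maturity_comment = NA_character_) {
  rec <- list(
    species_name = as.character(species_name),
    omega_min = as.numeric(omega_min), omega_mode = as.numeric(omega_mode),
    omega_max = as.numeric(omega_max),
    alpha50 = as.numeric(alpha50),
    alpha_ci_low = as.numeric(alpha_ci_low),
    alpha_ci_high = as.numeric(alpha_ci_high),
    alpha_trunc_low = as.numeric(alpha_trunc_low),
    alpha_trunc_high = as.numeric(alpha_trunc_high),
    fecundity_min = as.numeric(fecundity_min),
    fecundity_max = as.numeric(fecundity_max),
    eggcase_min = as.numeric(eggcase_min),
    eggcase_mode = as.numeric(eggcase_mode),
    eggcase_max = as.numeric(eggcase_max),
    survival_min = as.numeric(survival_min),
    survival_max = as.numeric(survival_max),
    tmax_observed = as.numeric(tmax_observed), iape = as.numeric(iape),
    extension_constant = as.numeric(extension_constant),
    growth_k = as.numeric(growth_k), growth_t0 = as.numeric(growth_t0),
    tl_max_cm = as.numeric(tl_max_cm), depth_mid_m = as.numeric(depth_mid_m),
    size_at_hatch_cm = as.numeric(size_at_hatch_cm),
    size_at_maturity_cm = as.numeric(size_at_maturity_cm),
    maturity_comment = as.character(maturity_comment))
  class(rec) <- "skate_species"
  validate_species_record(rec)
}

# field lists shared by the constructor, readers and writers
.species_required <- c(
  "species_name", "omega_min", "omega_mode", "omega_max",
  "alpha50", "alpha_ci_low", "alpha_ci_high",
  "alpha_trunc_low", "alpha_trunc_high",
  "fecundity_min", "fecundity_max",
  "eggcase_min", "eggcase_mode", "eggcase_max",
  "survival_min", "survival_max")
.species_optional <- c(
  "tmax_observed", "iape", "extension_constant", "growth_k", "growth_t0",
  "tl_max_cm", "depth_mid_m", "size_at_hatch_cm", "size_at_maturity_cm",
  "maturity_comment")

#' Validate a species life-history record
#'
#' Hard invariant violations (out-of-range survival probabilities, unordered
#' triangular parameters, inverted bounds) are errors; a maturity location
#' lying outside its truncation interval is biologically possible (the PDF
#' is then sampled as stated, by rejection) and only raises a warning.
#'
#' @param rec a `skate_species` record.
#' @return `rec`, invisibly unchanged, if valid.
#' @export
validate_species_record <- function(rec) {
  nm <- rec$species_name
  fail <- function(...) stop("record '", nm, "': ", ..., call. = FALSE)
  if (!nzchar(nm)) stop("species_name must be non-empty", call. = FALSE)
  for (f in setdiff(.species_required, "species_name")) {
    if (!is.finite(rec[[f]])) fail("field '", f, "' is missing or non-numeric")
  }
  with(rec, {
    if (!(survival_min > 0 && survival_min <= survival_max &&
          survival_max < 1)) {
      fail("survival range must satisfy 0 < min <= max < 1")
    }
    if (!(eggcase_min > 0 && eggcase_min <= eggcase_mode &&
          eggcase_mode <= eggcase_max && eggcase_max <= 1)) {
      fail("egg-case survival must satisfy 0 < min <= mode <= max <= 1")
    }
    if (!(omega_min <= omega_mode && omega_mode <= omega_max)) {
      fail("longevity must satisfy min <= mode <= max")
    }
    if (omega_min < 1) fail("omega_min must be at least 1")
    if (!(alpha_trunc_low < alpha_trunc_high &&
          alpha_trunc_high <= omega_max)) {
      fail("maturity truncation bounds must satisfy low < high <= omega_max")
    }
    if (fecundity_min > fecundity_max) fail("fecundity range inverted")
    if (fecundity_min < 0) fail("fecundity must be non-negative")
    if (alpha_ci_low >= alpha_ci_high) fail("alpha 95% CI has no width")
  })
  if (rec$alpha50 < rec$alpha_trunc_low || rec$alpha50 > rec$alpha_trunc_high) {
    warning("record '", nm, "': alpha50 (", rec$alpha50,
            ") lies outside its truncation bounds [", rec$alpha_trunc_low,
            ", ", rec$alpha_trunc_high, "]; the stated PDF is sampled as-is",
            call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.skate_species <- function(x, ...) {
  cat("<skate_species> ", x$species_name, "\n",
      "  longevity  : triangular(", x$omega_min, ", ", x$omega_mode, ", ",
      x$omega_max, ") yr\n",
      "  maturity   : logistic(", x$alpha50, ") truncated to [",
      x$alpha_trunc_low, ", ", x$alpha_trunc_high, "] yr (95% CI ",
      x$alpha_ci_low, "-", x$alpha_ci_high, ")\n",
      "  survival   : uniform(", x$survival_min, ", ", x$survival_max,
      ") yr^-1\n",
      "  fecundity  : uniform(", x$fecundity_min, ", ", x$fecundity_max,
      ") female offspring female^-1 yr^-1\n",
      "  egg case   : triangular(", x$eggcase_min, ", ", x$eggcase_mode,
      ", ", x$eggcase_max, ") yr^-1\n", sep = "")
  invisible(x)
}

species_records_to_df <- function(records) {
  cols <- c(.species_required, .species_optional)
  rows <- lapply(records, function(r) {
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

record_from_row <- function(row, origin) {
  missing <- setdiff(.species_required, names(row))
  if (length(missing) > 0L) {
    stop("species record schema error in ", origin, ": missing field(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_fields <- setdiff(c(.species_required, .species_optional),
                        c("species_name", "maturity_comment"))
  args <- list(species_name = as.character(row[["species_name"]]))
  for (f in num_fields) {
    if (!f %in% names(row) || is.null(row[[f]]) || is.na(row[[f]]) ||
        identical(row[[f]], "")) {
      args[[f]] <- NA_real_
      next
    }
    v <- suppressWarnings(as.numeric(row[[f]]))
    if (is.na(v)) {
      stop("parse error in ", origin, " (record '", args$species_name,
           "'): field '", f, "' is non-numeric", call. = FALSE)
    }
    args[[f]] <- v
  }
  if (is.na(args$extension_constant)) args$extension_constant <- 1.4
  args$maturity_comment <-
    if (!is.null(row[["maturity_comment"]]) &&
        !is.na(row[["maturity_comment"]])) {
      as.character(row[["maturity_comment"]])
    } else NA_character_
  do.call(species_record, args)
}

#' Read species life-history records
#'
#' Reads a CSV (one row per species, header = field names) or YAML
#' (a `species:` list of mappings) file of life-history records and
#' validates every record. The packaged Bering Sea fixture is at
#' `system.file("extdata", "bering_sea_skates.csv", package = "skatedemog")`.
#'
#' @param path path to a `.csv`, `.yaml` or `.yml` file.
#' @return a named list of `skate_species` records.
#' @examples
#' recs <- load_species_records(
#'   system.file("extdata", "bering_sea_skates.csv", package = "skatedemog"))
#' names(recs)
#' @export
load_species_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y$species)) {
      stop("YAML species file must have a top-level 'species' list",
           call. = FALSE)
    }
    y$species
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (nrow(df) == 0L) {
      warning("no species records in ", path, call. = FALSE)
      return(list())
    }
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  if (length(rows) == 0L) {
    warning("no species records in ", path, call. = FALSE)
    return(list())
  }
  records <- lapply(rows, record_from_row, origin = basename(path))
  names(records) <- vapply(records, `[[`, character(1L), "species_name")
  if (anyDuplicated(names(records))) {
    stop("duplicate species names in ", path, call. = FALSE)
  }
  records
}

#' Write species life-history records
#'
#' Writes records to CSV or YAML with 17 significant digits so that a
#' write/read round trip reproduces every numeric field exactly.
#'
#' @param records a list of `skate_species` records.
#' @param path output path; format chosen by extension (`.csv`, `.yaml`).
#' @return `path`, invisibly.
#' @export
write_species_records <- function(records, path) {
  stopifnot(length(records) > 0L,
            all(vapply(records, inherits, logical(1L), "skate_species")))
  ext <- tolower(tools::file_ext(path))
  df <- species_records_to_df(records)
  if (ext %in% c("yaml", "yml")) {
    fmt <- function(v) {
      if (is.na(v)) return(NULL)
      if (is.character(v)) return(v)
      formatC(v, digits = 17, format = "g")
    }
    lines <- c("species:")
    for (r in records) {
      first <- TRUE
      for (f in names(r)) {
        v <- fmt(r[[f]])
        if (is.null(v)) next
        lines <- c(lines, paste0(if (first) "  - " else "    ", f, ": ",
                                 if (is.character(r[[f]]))
                                   paste0("\"", v, "\"") else v))
        first <- FALSE
      }
    }
    writeLines(lines, path)
  } else {
    num <- vapply(df, is.numeric, logical(1L))
    out <- df
    out[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
    })
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(path)
}

#' Read the comparative growth-rate table
#'
#' Reads the comparative table of published finite population growth rates
#' and candidate life-history correlates for high-latitude skates: one row
#' per species with columns `species_name`, `lambda_pub` (published annual
#' growth rate), `alpha_omega_ratio` (age at maturity over longevity),
#' `tl_max_cm`, `depth_mid_m` (midpoint of the depth range) and `group`
#' (`alaskan` or `other_high_latitude`). The packaged fixture holds 14
#' species, 9 of them Alaskan.
#'
#' @param path path to a CSV file.
#' @return a validated data.frame.
#' @examples
#' comp <- load_comparative_table(
#'   system.file("extdata", "high_latitude_skates.csv",
#'               package = "skatedemog"))
#' table(comp$group)
#' @export
load_comparative_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("no comparative records in ", path, call. = FALSE)
    return(df)
  }
  need <- c("species_name", "lambda_pub", "alpha_omega_ratio", "tl_max_cm",
            "depth_mid_m", "group")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("comparative table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$species_name)) {
    stop("duplicate species in comparative table: ",
         paste(unique(df$species_name[duplicated(df$species_name)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("lambda_pub", "alpha_omega_ratio")) {
    if (any(!is.finite(df[[col]]))) {
      stop("comparative table: non-numeric values in '", col, "'",
           call. = FALSE)
    }
  }
  if (any(df$lambda_pub <= 0)) stop("lambda_pub must be positive", call. = FALSE)
  if (any(df$alpha_omega_ratio <= 0 | df$alpha_omega_ratio >= 1)) {
    stop("alpha_omega_ratio must lie in (0, 1)", call. = FALSE)
  }
  if (!all(df$group %in% c("alaskan", "other_high_latitude"))) {
    stop("group must be 'alaskan' or 'other_high_latitude'", call. = FALSE)
  }
  df
}

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata/`; `NULL` lists them.
#' @return full path (or a character vector of available files).
#' @export
skatedemog_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "skatedemog")))
  }
  path <- system.file("extdata", file, package = "skatedemog")
  if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}
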