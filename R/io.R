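# CSV dataset bundles. All tables are plain CSV in long format, sorted by
# year then age for diffability, with numeric values written at full
# precision so write -> load round-trips are lossless. Missing cells are
# simply absent rows, never zeros; the loader rejects non-positive values
# and duplicate cells with errors naming the file and row.

fmt_num <- function(x) sprintf("%.17g", x)

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

long_from_matrix <- function(m, years, value_name) {
  cells <- which(!is.na(m), arr.ind = TRUE)
  df <- data.frame(year = years[cells[, 2]], age = as.integer(cells[, 1]),
                   value = m[cells])
  names(df)[3] <- value_name
  df[order(df$year, df$age), , drop = FALSE]
}

#' Write a dataset bundle to a directory
#'
#' Writes the observation set and covariates as a bundle of long-format CSV
#' tables (landings, winter survey indices, stage indices, weight-at-age,
#' maturity, temperature) plus a \code{meta.json} with the schema version and
#' age/year structure.
#'
#' @param obs An \code{\link{observation_set}}.
#' @param covars The matching \code{\link{covariates}}.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(obs, covars, dir) {
  ages <- obs$ages
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yrs <- ages$years
  write_table(long_from_matrix(obs$landings, yrs, "landings"),
              file.path(dir, "landings.csv"))
  write_table(long_from_matrix(obs$index_winter, yrs, "index"),
              file.path(dir, "winter_index.csv"))
  stage <- data.frame(
    year = rep(yrs, 3),
    stage = rep(c("egg", "larvae", "zerogroup"), each = length(yrs)),
    index = c(obs$index_egg, obs$index_larv, obs$index_0g))
  stage <- stage[!is.na(stage$index), ]
  write_table(stage[order(stage$year, stage$stage), ],
              file.path(dir, "stage_indices.csv"))
  write_table(long_from_matrix(covars$weight, yrs, "weight_kg"),
              file.path(dir, "weight.csv"))
  write_table(long_from_matrix(covars$maturity, yrs, "p_mature"),
              file.path(dir, "maturity.csv"))
  write_table(data.frame(year = yrs, anomaly = covars$temperature),
              file.path(dir, "temperature.csv"))
  jsonlite::write_json(
    list(schema_version = "1.0", first_year = ages$first_year,
         n_years = ages$n_years, max_age = ages$max_age,
         recruit_age = ages$recruit_age,
         cannibal_ages = ages$cannibal_ages, dd_ages = ages$dd_ages),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

read_table <- function(dir, name, cols) {
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("missing table: ", path)
  df <- utils::read.csv(path)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing columns %s", name,
                 paste(missing, collapse = ", ")))
  df
}

check_cells <- function(df, name, value_col, max_age = NULL,
                        positive = TRUE) {
  if (positive) {
    bad <- which(df[[value_col]] <= 0 | is.na(df[[value_col]]))
    if (length(bad))
      stop(sprintf("%s row %d: %s must be a positive number (missing cells are absent rows, not zeros)",
                   name, bad[1], value_col))
  }
  key <- if ("age" %in% names(df)) paste(df$year, df$age)
  else if ("stage" %in% names(df)) paste(df$year, df$stage)
  else as.character(df$year)
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("%s row %d: duplicate cell (%s)", name, dup[1], key[dup[1]]))
  if (!is.null(max_age) && "age" %in% names(df)) {
    bad <- which(df$age < 0 | df$age > max_age)
    if (length(bad))
      stop(sprintf("%s row %d: age %d outside [0, %d]", name, bad[1],
                   df$age[bad[1]], max_age))
  }
  invisible(df)
}

matrix_from_long <- function(df, ages, value_col, name) {
  m <- matrix(NA_real_, ages$max_age, ages$n_years,
              dimnames = list(age = 1:ages$max_age, year = ages$years))
  yi <- match(df$year, ages$years)
  if (anyNA(yi))
    stop(sprintf("%s: year %d outside the bundle's year range", name,
                 df$year[which(is.na(yi))[1]]))
  m[cbind(df$age, yi)] <- df[[value_col]]
  m
}

#' Load a dataset bundle
#'
#' Reads the CSV bundle written by \code{\link{write_dataset}}, validating
#' the schema: all tables share the bundle's year axis, ages lie within the
#' modelled range, observed values are strictly positive, and no cell is
#' duplicated. Missingness masks are rebuilt from the absent rows. The
#' write/load round trip is lossless.
#'
#' @param dir Bundle directory.
#' @return List with \code{obs} (an \code{\link{observation_set}}),
#'   \code{covars} (a \code{\link{covariates}}) and \code{ages}.
#' @export
load_dataset <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing table: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  ages <- age_structure(meta$first_year, meta$n_years, meta$max_age,
                        meta$recruit_age, meta$cannibal_ages, meta$dd_ages)

  land <- check_cells(read_table(dir, "landings.csv",
                                 c("year", "age", "landings")),
                      "landings.csv", "landings", ages$max_age)
  wint <- check_cells(read_table(dir, "winter_index.csv",
                                 c("year", "age", "index")),
                      "winter_index.csv", "index", ages$max_age)
  stg <- check_cells(read_table(dir, "stage_indices.csv",
                                c("year", "stage", "index")),
                     "stage_indices.csv", "index")
  wt <- check_cells(read_table(dir, "weight.csv",
                               c("year", "age", "weight_kg")),
                    "weight.csv", "weight_kg", ages$max_age)
  mat <- check_cells(read_table(dir, "maturity.csv",
                                c("year", "age", "p_mature")),
                     "maturity.csv", "p_mature", ages$max_age,
                     positive = FALSE)
  tmp <- check_cells(read_table(dir, "temperature.csv",
                                c("year", "anomaly")),
                     "temperature.csv", "anomaly", positive = FALSE)

  stage_vec <- function(s) {
    v <- rep(NA_real_, ages$n_years)
    rows <- stg[stg$stage == s, ]
    v[match(rows$year, ages$years)] <- rows$index
    v
  }
  obs <- observation_set(
    matrix_from_long(land, ages, "landings", "landings.csv"),
    matrix_from_long(wint, ages, "index", "winter_index.csv"),
    stage_vec("egg"), stage_vec("larvae"), stage_vec("zerogroup"), ages)

  wm <- matrix_from_long(wt, ages, "weight_kg", "weight.csv")
  mm <- matrix_from_long(mat, ages, "p_mature", "maturity.csv")
  if (anyNA(wm) || anyNA(mm))
    stop("weight.csv / maturity.csv must cover every age and year")
  ti <- match(ages$years, tmp$year)
  if (anyNA(ti)) stop("temperature.csv must cover every year")
  covars <- covariates(wm, mm, tmp$anomaly[ti], ages)
  list(obs = obs, covars = covars, ages = ages)
}
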