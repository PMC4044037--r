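#' Age and year structure of the life-cycle model
#'
#' Defines the calendar span and the age-class layout used throughout the
#' package: the maximum modelled age, the age of recruitment to the fishery,
#' the ages whose abundance drives cannibalism on the 0-group, and the ages
#' subject to intracohort (within-cohort) density-dependent survival.
#'
#' @param first_year First calendar year of the modelled period.
#' @param n_years Number of modelled years.
#' @param max_age Maximum modelled age (fish leave the model afterwards;
#'   there is no plus group).
#' @param recruit_age Age at recruitment to the fishery; fishing mortality is
#'   zero below this age.
#' @param cannibal_ages Ages whose summed abundance enters the intercohort
#'   (cannibalism) term acting on 0-group survival.
#' @param dd_ages Ages with intracohort Beverton-Holt density-dependent
#'   survival (each transition age a -> a+1 for a in \code{dd_ages}).
#'
#' @return An object of class \code{"age_structure"}: a list with the fields
#'   above plus \code{years}, the vector of calendar years.
#' @export
age_structure <- function(first_year = 1959L, n_years = 52L, max_age = 9L,
                          recruit_age = 4L, cannibal_ages = c(3L, 4L),
                          dd_ages = 1:3) {
  first_year <- as.integer(first_year)
  n_years <- as.integer(n_years)
  max_age <- as.integer(max_age)
  recruit_age <- as.integer(recruit_age)
  cannibal_ages <- sort(as.integer(cannibal_ages))
  dd_ages <- sort(as.integer(dd_ages))
  if (n_years < 2L) stop("n_years must be at least 2")
  if (!(max_age >= recruit_age && recruit_age >= 1L))
    stop("need max_age >= recruit_age >= 1")
  if (any(dd_ages < 1L) || any(dd_ages >= max_age))
    stop("dd_ages must lie in [1, max_age)")
  if (any(cannibal_ages < 1L) || any(cannibal_ages > max_age))
    stop("cannibal_ages must lie in [1, max_age]")
  structure(
    list(first_year = first_year, n_years = n_years, max_age = max_age,
         recruit_age = recruit_age, cannibal_ages = cannibal_ages,
         dd_ages = dd_ages,
         years = seq(first_year, length.out = n_years)),
    class = "age_structure")
}

#' @export
print.age_structure <- function(x, ...) {
  cat("Age structure:", x$first_year, "-", x$first_year + x$n_years - 1L,
      "| ages 1 -", x$max_age,
      "| recruit age", x$recruit_age,
      "| cannibal ages", paste(x$cannibal_ages, collapse = "+"),
      "| DD ages", paste(x$dd_ages, collapse = ","), "\n")
  invisible(x)
}
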