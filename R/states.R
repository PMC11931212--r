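# State space and age-grid helpers shared by every module.

#' Model state names
#'
#' The cohort model tracks 14 mutually exclusive states: never user, current
#' user, ten one-year tunnel states counting years since quitting, a long-term
#' former state (10+ years since quitting, risk equal to never users) and an
#' absorbing dead state.
#'
#' @return Character vector of the 14 state names, in model order.
#' @export
st_states <- function() {
  c("never", "current", paste0("former_", 1:10), "former_long", "dead")
}

#' Exposure class names
#'
#' Living states collapse onto five exposure classes used for relative-risk
#' apportionment: never, current, former 0-4 years since quitting (tunnel
#' years 1-5), former 5-10 years (tunnel years 6-10), and former 10+ years.
#'
#' @return Character vector of the five class names.
#' @export
st_classes <- function() {
  c("never", "current", "former_0_4", "former_5_10", "former_10plus")
}

# Integer class index (1..5) for each living state; NA for dead.
state_class_index <- function() {
  c(1L, 2L, rep(3L, 5), rep(4L, 5), 5L, NA_integer_)
}

#' Standard 5-year age bands
#'
#' @param from,to Lower bounds of the first and last band.
#' @return Character vector of band labels such as `"15-19"`.
#' @export
age_bands <- function(from = 15, to = 70) {
  lo <- seq(from, to, by = 5)
  paste0(lo, "-", lo + 4)
}

#' Lower bound of an age band label
#' @param band Character band label, e.g. `"15-19"`.
#' @return Integer lower bound.
#' @export
band_lower <- function(band) {
  as.integer(sub("-.*$", "", band))
}

#' Map an integer age to its 5-year band label
#' @param age Integer age(s).
#' @param max_lower Lower bound of the final (open-ended) band on the grid.
#' @return Character band label(s).
#' @export
age_to_band <- function(age, max_lower = 85) {
  lo <- pmin((age %/% 5) * 5, max_lower)
  paste0(lo, "-", lo + 4)
}

# Disability-weight age groups: 15-49, 50-69, 70+.
age_to_weight_band <- function(age) {
  dplyr::case_when(
    age < 50 ~ "15-49",
    age < 70 ~ "50-69",
    TRUE ~ "70+"
  )
}

#' Disease labels used throughout the model
#' @return Character vector of the four modelled diseases.
#' @export
st_diseases <- function() {
  c("oral_cancer", "pharyngeal_cancer", "esophageal_cancer", "stroke")
}

#' Outcome labels (mortality plus the four diseases)
#' @return Character vector of the five outcomes carrying relative risks.
#' @export
st_outcomes <- function() {
  c("mortality", st_diseases())
}
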