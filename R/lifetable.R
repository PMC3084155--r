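#' Synthetic non-cardiovascular life table for ages 65 and over
#'
#' Background mortality in the model is death from causes other than
#' cardiovascular disease: cardiovascular deaths are generated inside the
#' event sub-tree and must not be double counted. National cause-deleted
#' life tables for the study population are not distributed, so the package
#' generates one from a Gompertz all-cause hazard with a constant
#' cardiovascular fraction removed:
#' \deqn{h(x) = a e^{b (x - 65)}, \qquad q_x = (1 - e^{-h(x)})(1 - f_{cv})}
#' capped at 1, with \eqn{q_{max\_age} = 1} as an absorbing horizon.
#'
#' The defaults (`a = 0.013`, `b = 0.095`, `cv_fraction = 0.30`) give a
#' remaining life expectancy at 65 of about 17 years under all-cause
#' mortality, typical of an urban middle-class elderly population, with
#' roughly 30% of deaths of cardiovascular origin.
#'
#' @param a Gompertz level (hazard at age 65), > 0.
#' @param b Gompertz slope per year of age, > 0.
#' @param cv_fraction fraction of all-cause mortality attributed to
#'   cardiovascular causes and removed, in `[0, 1)`.
#' @param max_age absorbing horizon (default 100).
#' @return an object of class `life_table`: data.frame with columns `age`
#'   (65..`max_age`) and `qx`.
#' @examples
#' lt <- synthetic_life_table()
#' head(lt)
#' @export
synthetic_life_table <- function(a = 0.013, b = 0.095, cv_fraction = 0.30,
                                 max_age = 100L) {
  if (a <= 0 || b <= 0) stop("a and b must be positive", call. = FALSE)
  if (cv_fraction < 0 || cv_fraction >= 1)
    stop("cv_fraction must be in [0, 1)", call. = FALSE)
  if (max_age <= 65) stop("max_age must exceed 65", call. = FALSE)
  ages <- 65:max_age
  h <- a * exp(b * (ages - 65))
  qx <- pmin(1, (1 - exp(-h)) * (1 - cv_fraction))
  qx[length(qx)] <- 1
  new_life_table(data.frame(age = ages, qx = qx))
}

new_life_table <- function(df) {
  structure(df, class = c("life_table", "data.frame"))
}

validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table needs columns age, qx", call. = FALSE)
  if (any(lt$qx < 0 | lt$qx > 1))
    stop("life table qx outside [0, 1]", call. = FALSE)
  if (any(diff(lt$qx) < 0))
    stop("life table qx must be non-decreasing in age", call. = FALSE)
  if (any(diff(lt$age) != 1))
    stop("life table ages must be consecutive integers", call. = FALSE)
  if (lt$age[1] > 65)
    stop("life table must start at age 65 or below", call. = FALSE)
  if (lt$qx[nrow(lt)] != 1)
    stop("life table must end with qx = 1 at its last age", call. = FALSE)
  invisible(lt)
}

#' Read a life table from CSV
#'
#' The file must have columns `age`, `qx` covering consecutive integer ages
#' from 65 (or below) up to the model horizon, with `qx = 1` at the last age.
#'
#' @param path CSV file path.
#' @return a `life_table`.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lt <- new_life_table(df[c("age", "qx")])
  validate_life_table(lt)
  lt
}

#' Write a life table to CSV
#' @param lt a `life_table`.
#' @param path CSV file path.
#' @export
save_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' Annual probability of non-cardiovascular death at a given age
#'
#' Table lookup; ages beyond the table's last age return 1 (the horizon is
#' absorbing).
#'
#' @param lt a `life_table`.
#' @param age age in years, >= 65.
#' @return probability (vectorised over `age`).
#' @export
q_noncv <- function(lt, age) {
  if (any(age < 65)) stop("the model starts at age 65", call. = FALSE)
  idx <- match(pmin(age, max(lt$age)), lt$age)
  lt$qx[idx]
}

#' Remaining life expectancy at a starting age, by direct summation
#'
#' Curtate life expectancy under the table's mortality alone, capped at the
#' table horizon: the sum over cycles of the probability of being alive at
#' the end of the cycle. This is the closed-form counterpart of a cohort run
#' with all cardiovascular risk removed, and is used as an oracle for the
#' Markov engine.
#'
#' @param lt a `life_table`.
#' @param start_age entry age (default 65).
#' @param discount_rate optional annual discount applied to each survived
#'   year, first year undiscounted (default 0).
#' @return expected (discounted) years lived.
#' @export
life_expectancy <- function(lt, start_age = 65, discount_rate = 0) {
  ages <- lt$age[lt$age >= start_age]
  q <- q_noncv(lt, ages)
  surv <- cumprod(1 - q)           # alive at end of each cycle
  sum(surv / (1 + discount_rate)^(seq_along(surv) - 1))
}
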