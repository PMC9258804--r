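# Age-indexed background mortality.

#' Construct a life table
#'
#' A life table maps integer age to the annual probability of death `q`.
#' Ages must be strictly increasing, every `q` in `[0,1]`, and the terminal
#' age must have `q = 1` (all-cause absorption at the table's end).
#'
#' @param age integer ages, strictly increasing.
#' @param q annual death probabilities, same length as `age`.
#' @return a `cua_life_table` (a data frame with columns `age`, `q`).
#' @export
life_table <- function(age, q) {
  if (length(age) != length(q) || length(age) < 2)
    abort("life table needs matching age and q vectors (length >= 2)",
          "afcua_validation_error")
  lt <- structure(data.frame(age = as.integer(age), q = as.numeric(q)),
                  class = c("cua_life_table", "data.frame"))
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  if (any(diff(lt$age) <= 0))
    abort("life table ages must be strictly increasing",
          "afcua_validation_error")
  if (any(lt$q < 0 | lt$q > 1))
    abort("life table death probabilities must lie in [0,1]",
          "afcua_validation_error")
  if (abs(lt$q[nrow(lt)] - 1) > 1e-12)
    abort("life table must end with q = 1 at its maximum age",
          "afcua_validation_error")
  lt
}

#' Look up the annual probability of death at an age
#'
#' Returns `q` for the greatest tabulated age not exceeding `age`
#' (step interpolation); ages at or beyond the table's maximum return 1.
#' Ages below the table's range are an error.
#'
#' @param lt a `cua_life_table`.
#' @param age age in years (vectorised).
#' @return annual death probability/-ies.
#' @export
mortality <- function(lt, age) {
  if (any(age < lt$age[1]))
    abort(sprintf("age %g below life-table range (starts at %d)",
                  min(age), lt$age[1]), "afcua_domain_error")
  idx <- findInterval(age, lt$age)
  q <- lt$q[idx]
  q[age >= max(lt$age)] <- 1
  q
}

#' Discounted life expectancy implied by a life table
#'
#' Expected discounted person-years from `start_age`, with each surviving
#' year counted at the start of its cycle (cycle 0 counts in full):
#' `sum_t df(t) * S(t)` where `S(t)` is survival to the start of cycle `t`.
#'
#' @param lt a `cua_life_table`.
#' @param start_age starting age in years.
#' @param rate annual discount rate (0 gives plain expected life-years
#'   under the start-of-cycle convention).
#' @param cycles number of one-year cycles (default: to the table's end).
#' @return discounted expected person-years.
#' @export
life_expectancy <- function(lt, start_age, rate = 0,
                            cycles = max(lt$age) - start_age) {
  q <- mortality(lt, start_age + seq_len(cycles) - 1)
  S <- cumprod(c(1, 1 - q))        # survival to start of cycles 0..cycles
  sum(discount_factor(rate, 0:cycles) * S)
}

#' Read / write a life table as CSV
#'
#' Two columns with header: `age`, `q` (annual death probability).
#'
#' @param path CSV file path.
#' @param lt a `cua_life_table` (for writing).
#' @return `read_life_table`: a `cua_life_table`; `write_life_table`:
#'   `path`, invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    abort(sprintf("life-table file not found: %s", path),
          "afcua_config_error")
  df <- utils::read.csv(path)
  if (!all(c("age", "q") %in% names(df)))
    abort("life-table CSV must have columns 'age' and 'q'",
          "afcua_config_error")
  life_table(df$age, df$q)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt)[, c("age", "q")], path,
                   row.names = FALSE)
  invisible(path)
}
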