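# Shared internal helpers.

#' Moment-ratio sample skewness
#'
#' Skewness as the third central moment over the second central moment to the
#' 3/2 power, `m3 / m2^(3/2)`, with no small-sample bias adjustment. A constant
#' sample has no defined skewness and returns `NA` rather than zero.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return A single number, or `NA_real_` if fewer than 2 distinct finite
#'   values remain.
#' @examples
#' sample_skewness(c(1, 2, 3)) # 0: symmetric
#' sample_skewness(c(1, 2, 3, 4, 100)) # strongly right-skewed
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    return(NA_real_)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(NA_real_)
  }
  mean((x - m)^3) / m2^1.5
}

# stopifnot-style scalar checks with readable errors
check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
      class = "sanistunt_parameter_error"
    )
  }
  ok_min <- if (strict_min) x > min else x >= min
  if (!ok_min || x > max) {
    abort(
      sprintf(
        "`%s` must be %s %s and <= %s (got %g).",
        name, if (strict_min) ">" else ">=", format(min), format(max), x
      ),
      class = "sanistunt_parameter_error"
    )
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
      class = "sanistunt_parameter_error"
    )
  }
  invisible(as.integer(x))
}

check_columns <- function(data, cols, what = "data") {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(
      sprintf(
        "%s is missing required column(s): %s.",
        what, paste0("`", missing_cols, "`", collapse = ", ")
      ),
      class = "sanistunt_data_error"
    )
  }
  invisible(data)
}

# Run `expr` under a fixed RNG seed when `seed` is supplied, leaving the
# caller's RNG state untouched; otherwise draw from the current stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}
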