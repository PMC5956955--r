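#' Tidy and glance methods for tipclock result objects
#'
#' Broom-style accessors: `tidy()` returns the per-observation view (one
#' row per regression point, permutation replicate, or date-randomized
#' replicate), `glance()` a one-row model summary.
#'
#' @param x A `rate_estimate`, `ptc_test`, or `drt_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tipclock-tidiers
NULL

#' @rdname tipclock-tidiers
#' @method tidy rate_estimate
#' @export
tidy.rate_estimate <- function(x, ...) {
  if (!is.null(x$data)) return(x$data)
  glance.rate_estimate(x)
}

#' @rdname tipclock-tidiers
#' @method glance rate_estimate
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    rate = x$rate,
    lower = if (is.null(x$interval)) NA_real_ else x$interval[1],
    upper = if (is.null(x$interval)) NA_real_ else x$interval[2],
    level = if (is.null(x$level)) NA_real_ else x$level,
    r_squared = x$r_squared,
    tmrca_age = x$tmrca_age,
    rss = x$rss
  )
}

#' @rdname tipclock-tidiers
#' @method tidy ptc_test
#' @export
tidy.ptc_test <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$perm_rho), perm_rho = x$perm_rho)
}

#' @rdname tipclock-tidiers
#' @method glance ptc_test
#' @export
glance.ptc_test <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_value = x$p_value, n_perm = x$n_perm,
                 alternative = x$alternative)
}

#' @rdname tipclock-tidiers
#' @method tidy drt_result
#' @export
tidy.drt_result <- function(x, ...) {
  reps <- dplyr::bind_rows(purrr::map(x$replicates, glance))
  dplyr::bind_rows(
    dplyr::mutate(glance(x$original), replicate = 0L, randomized = FALSE),
    dplyr::mutate(reps, replicate = dplyr::row_number(), randomized = TRUE)
  )
}

#' @rdname tipclock-tidiers
#' @method glance drt_result
#' @export
glance.drt_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, rate = x$original$rate,
    lower = x$original$interval[1], upper = x$original$interval[2],
    level = x$level, n_reps = x$n_reps, cr1 = x$cr1, cr2 = x$cr2
  )
}
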