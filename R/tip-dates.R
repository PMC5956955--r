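#' Tip sampling-date tables
#'
#' A tip-date table maps each tip label of a tree to its sampling age in
#' years before present (BP). Age 0 denotes a modern (present-day) sample;
#' larger ages are older. `tip_dates()` validates and normalises a data
#' frame (or a named numeric vector) into the canonical two-column tibble
#' used throughout the package.
#'
#' @param x A data frame with columns `name` and `age_years_bp`, or a named
#'   numeric vector of ages.
#' @return A tibble with columns `name` (character) and `age_years_bp`
#'   (non-negative numeric), one row per tip.
#' @examples
#' tip_dates(c(a = 0, b = 12000))
#' @export
tip_dates <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    x <- tibble::tibble(name = names(x), age_years_bp = unname(x))
  }
  if (!is.data.frame(x)) {
    rlang::abort("`x` must be a data frame or a named numeric vector.")
  }
  if (!all(c("name", "age_years_bp") %in% names(x))) {
    rlang::abort("tip dates need columns `name` and `age_years_bp`.")
  }
  out <- tibble::as_tibble(x[, c("name", "age_years_bp")])
  out$name <- as.character(out$name)
  out$age_years_bp <- as.numeric(out$age_years_bp)
  validate_tip_dates(out)
  out
}

validate_tip_dates <- function(dates) {
  if (nrow(dates) < 2) {
    rlang::abort("at least 2 tip dates are required.")
  }
  if (anyDuplicated(dates$name)) {
    dup <- unique(dates$name[duplicated(dates$name)])
    rlang::abort(paste0("duplicate tip names: ", paste(dup, collapse = ", ")))
  }
  if (anyNA(dates$age_years_bp) || any(dates$age_years_bp < 0)) {
    rlang::abort("ages must be non-negative and non-missing.")
  }
  invisible(dates)
}

# named age vector, ordered as `labels` when given
date_vector <- function(dates, labels = NULL) {
  ages <- stats::setNames(dates$age_years_bp, dates$name)
  if (!is.null(labels)) {
    missing <- setdiff(labels, names(ages))
    if (length(missing) > 0) {
      rlang::abort(paste0("no date for tips: ", paste(missing, collapse = ", ")))
    }
    ages <- ages[labels]
  }
  ages
}

#' Simulate heterochronous tip sampling ages
#'
#' Draws a sampling scheme that mixes modern and ancient samples:
#' `round(n_tips * frac_modern)` tips get age exactly 0 and the remainder
#' get ages drawn i.i.d. uniform on `(0, max_ancient_age]`, emulating
#' ancient-DNA data sets in which radiocarbon-dated samples are spread over
#' the sampling window. Labels are deterministic (`modern_###` /
#' `ancient_###`, zero-padded).
#'
#' @param n_tips Total number of tips (>= 2).
#' @param frac_modern Proportion of tips sampled at the present, in \[0, 1\].
#' @param max_ancient_age Upper bound of the ancient sampling window, years BP.
#' @param seed Integer seed controlling the uniform draws.
#' @return A tip-date tibble (see [tip_dates()]).
#' @examples
#' simulate_tip_ages(10, 0.5, 50000, seed = 1)
#' @export
simulate_tip_ages <- function(n_tips, frac_modern = 0.5,
                              max_ancient_age = 50000, seed = 1L) {
  if (!is.numeric(n_tips) || length(n_tips) != 1 || n_tips < 2 ||
      n_tips != round(n_tips)) {
    rlang::abort("`n_tips` must be a single integer >= 2.")
  }
  if (frac_modern < 0 || frac_modern > 1) {
    rlang::abort("`frac_modern` must lie in [0, 1].")
  }
  if (max_ancient_age <= 0) {
    rlang::abort("`max_ancient_age` must be positive.")
  }
  n_modern <- round(n_tips * frac_modern)
  n_ancient <- n_tips - n_modern
  pad <- function(prefix, n) {
    if (n == 0) return(character(0))
    sprintf("%s_%0*d", prefix, max(3L, nchar(n)), seq_len(n))
  }
  ages <- withr_seed(seed, {
    # uniform on (0, max]: reflect 0 draws away from the boundary
    u <- stats::runif(n_ancient)
    (1 - u) * max_ancient_age
  })
  tip_dates(tibble::tibble(
    name = c(pad("modern", n_modern), pad("ancient", n_ancient)),
    age_years_bp = c(rep(0, n_modern), ages)
  ))
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
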