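#' Read and write Newick trees
#'
#' Thin, validating wrappers around ape's Newick parser and writer. Branch
#' length units are declared by the caller, never guessed: `units =
#' "years"` marks a time tree (polytomies rejected, since simulated
#' genealogies are binary), `units = "subs"` a phylogram (polytomies
#' accepted, optionally resolved to zero-length binary splits).
#'
#' @param path File path.
#' @param units `"subs"` (phylogram, default) or `"years"` (time tree).
#' @param resolve_polytomies For phylograms, resolve multifurcations into
#'   zero-length binary splits.
#' @return A `phylo` with attribute `units`.
#' @export
read_newick <- function(path, units = c("subs", "years"),
                        resolve_polytomies = FALSE) {
  units <- match.arg(units)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) rlang::abort(
                    paste0("malformed Newick in ", path, ": ",
                           conditionMessage(e))))
  if (is.null(phy)) rlang::abort(paste0("malformed Newick in ", path))
  if (units == "years") {
    if (!ape::is.rooted(phy) || !ape::is.binary(phy)) {
      rlang::abort("time trees must be rooted and binary; the input has polytomies.")
    }
  } else if (!ape::is.binary(phy) && resolve_polytomies) {
    phy <- ape::multi2di(phy)
  }
  attr(phy, "units") <- units
  phy
}

#' @rdname read_newick
#' @param tree A `phylo` (or [time_tree()], written with branch lengths in
#'   years).
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "time_tree")) tree <- tree$phy
  stopifnot(inherits(tree, "phylo"))
  write_atomic(path, function(p) ape::write.tree(tree, file = p))
  invisible(path)
}

#' Read and write tip-date tables
#'
#' Self-describing TSV with header `name<TAB>age_years_bp`, one row per
#' tip; ages serialised with 17 significant digits so a write/read
#' round-trip reproduces the doubles exactly. Lines starting with `#` are metadata
#' comments (the writer records the package version).
#'
#' @param path File path.
#' @return A tip-date tibble.
#' @export
read_tip_dates <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("name", "age_years_bp") %in% names(df))) {
    rlang::abort('tip-date files need the header "name\\tage_years_bp".')
  }
  tip_dates(df)
}

#' @rdname read_tip_dates
#' @param dates Tip-date tibble.
#' @export
write_tip_dates <- function(dates, path) {
  dates <- tip_dates(dates)
  write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# tipclock %s",
                       as.character(utils::packageVersion("tipclock"))), con)
    writeLines("name\tage_years_bp", con)
    writeLines(sprintf("%s\t%s", dates$name,
                       trimws(formatC(dates$age_years_bp, digits = 17,
                                      format = "g"))), con)
  })
  invisible(path)
}

#' Export tip dates in the LSD date-file dialect
#'
#' First line: number of tips; then one `name<SPACE>date` row per tip,
#' with dates as forward time (minus age), for interoperability with
#' least-squares dating tools.
#'
#' @inheritParams write_tip_dates
#' @export
write_lsd_dates <- function(dates, path) {
  dates <- tip_dates(dates)
  write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(dates)), con)
    writeLines(sprintf("%s %s", dates$name,
                       trimws(formatC(0 - dates$age_years_bp + 0, digits = 17,
                                      format = "g"))), con)
  })
  invisible(path)
}

#' Read and write FASTA alignments
#'
#' Wrappers around ape's FASTA I/O returning/consuming `DNAbin` matrices;
#' sequences are wrapped at 80 columns and labels must match tree tip
#' labels byte-for-byte.
#'
#' @param path File path.
#' @return A `DNAbin` matrix.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  as.matrix(ape::read.FASTA(path))
}

#' @rdname read_fasta
#' @param aln A `DNAbin` matrix.
#' @export
write_fasta <- function(aln, path) {
  write_atomic(path, function(p) {
    ape::write.FASTA(aln, file = p)
  })
  invisible(path)
}

#' Write a results table as TSV
#'
#' Fixed, documented column order; a `#`-prefixed header line records the
#' package version. Read back with [read_results()].
#'
#' @param results Results tibble from [run_scenario_grid()].
#' @param path File path.
#' @export
write_results <- function(results, path) {
  write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(sprintf("# tipclock %s results",
                       as.character(utils::packageVersion("tipclock"))), con)
    utils::write.table(results, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}

# write via a temp file in the same directory then rename, so interrupted
# runs never leave truncated outputs
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    rlang::abort(paste0("could not move temporary file onto ", path))
  }
  invisible(path)
}

#' Run configurations
#'
#' A run configuration bundles every knob of the simulation-estimation
#' pipeline. `run_config()` validates values and fills defaults;
#' `read_run_config()` / `write_run_config()` round-trip it through YAML,
#' rejecting unknown keys by name.
#'
#' @param ... Named configuration values (see Details for the key list).
#' @details Keys and defaults: `n_tips` (100), `frac_modern` (0.5),
#'   `max_ancient_age` (50000), `root_age` (500000), `effective_size`
#'   (250000), `seq_length` (15000), `mean_rates` (1e-7, 1e-8),
#'   `variance_fractions` (0.001, 0.01, 0.1), `clustering` (low, high),
#'   `n_replicates` (5), `seed` (1), `kappa` (10), `base_freq`
#'   (0.31, 0.31, 0.13, 0.25), `gamma_shape` (0.5), `n_gamma_cat` (4),
#'   `dist_model` (TN93), `lsd_c` (10), `n_boot` (100), `level` (0.95),
#'   `n_perm` (1000), `n_reps` (20).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    n_tips = 100L, frac_modern = 0.5, max_ancient_age = 50000,
    root_age = 500000, effective_size = 250000, seq_length = 15000,
    mean_rates = c(1e-7, 1e-8), variance_fractions = c(0.001, 0.01, 0.1),
    clustering = c("low", "high"), n_replicates = 5L, seed = 1L,
    kappa = 10, base_freq = c(0.31, 0.31, 0.13, 0.25), gamma_shape = 0.5,
    n_gamma_cat = 4L, dist_model = "TN93", lsd_c = 10, n_boot = 100L,
    level = 0.95, n_perm = 1000L, n_reps = 20L
  )
  override <- list(...)
  if (length(override) > 0 && is.null(names(override))) {
    rlang::abort("configuration values must be named.")
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, override)
  if (cfg$max_ancient_age >= cfg$root_age) {
    rlang::abort("`max_ancient_age` must be smaller than `root_age`.")
  }
  if (cfg$seq_length < 1) rlang::abort("`seq_length` must be >= 1.")
  if (any(cfg$mean_rates <= 0)) rlang::abort("`mean_rates` must be positive.")
  if (any(cfg$variance_fractions < 0)) {
    rlang::abort("`variance_fractions` must be >= 0.")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path File path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  write_atomic(path, function(p) {
    yaml::write_yaml(unclass(config), p)
  })
  invisible(path)
}
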