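# Monte Carlo clone-picking simulator: clones needed to detect each
# successive new variant when screening a degenerate-codon library.

#' Simulation configuration
#'
#' @param dist A `variant_distribution` or scheme string.
#' @param targets Variant symbols to collect. Default: the distribution's
#'   reachable amino acids (stop excluded). Every target must be reachable.
#' @param n_iterations Number of Monte Carlo iterations (default 1e6, the
#'   conventional choice for these screening simulations; 1e5 already gives
#'   sub-percent standard errors).
#' @param seed Integer seed; recorded in the output. `NULL` leaves the RNG
#'   state untouched (not reproducible).
#' @param record Which per-rank series the TSV writer emits:
#'   `"both"` (default), `"incremental"` or `"cumulative"`. Both are always
#'   computed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dist, targets = reachable_variants(dist, include_stop = FALSE),
                              n_iterations = 1e6, seed = NULL,
                              record = c("both", "incremental", "cumulative")) {
  record <- match.arg(record)
  dist <- amino_acid_distribution(dist)
  stopifnot(n_iterations >= 1)
  p <- .target_probs(dist, targets)
  if (any(p == 0)) {
    stop("unreachable target variant(s): ",
         paste(names(p)[p == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(dist = dist, targets = names(p),
                 n_iterations = as.integer(n_iterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 record = record),
            class = "simulation_config")
}

# run fn under the config's seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate random clone picking until the library is complete
#'
#' Each iteration draws clones i.i.d. from the variant distribution until
#' every target variant has appeared. Stop codons and non-target variants
#' consume a clone without counting as a discovery. Per discovery rank
#' k = 1..|targets| the summary reports mean and SD of (a) clones drawn
#' since the previous discovery (incremental) and (b) total clones drawn
#' (cumulative). Identical config and seed give bit-identical output.
#'
#' @param config A `simulation_config`, or a distribution/scheme (then the
#'   remaining arguments are forwarded to [simulation_config()]).
#' @param ... Passed to [simulation_config()] when `config` is not one.
#' @return A `simulation_summary`: data.frame with columns `rank`,
#'   `incremental_mean`, `incremental_sd`, `cumulative_mean`,
#'   `cumulative_sd`, with the config attached as attribute `config`.
#' @export
#' @examples
#' s <- simulate_screening(variant_distribution(c(a = .5, b = .5)),
#'                         n_iterations = 2000, seed = 1)
#' s$cumulative_mean[2]  # near 3, the two-coupon collector expectation
simulate_screening <- function(config, ...) {
  if (!inherits(config, "simulation_config")) {
    config <- simulation_config(config, ...)
  }
  probs <- config$dist$probs
  target <- as.integer(names(probs) %in% config$targets)
  res <- .with_seed(config$seed, function()
    sim_collect_cpp(unname(probs), target, config$n_iterations))
  out <- data.frame(rank = seq_along(res$incremental_mean),
                    incremental_mean = res$incremental_mean,
                    incremental_sd = res$incremental_sd,
                    cumulative_mean = res$cumulative_mean,
                    cumulative_sd = res$cumulative_sd)
  structure(out, config = config,
            class = c("simulation_summary", "data.frame"))
}

#' Simulate a fixed-size screen
#'
#' Draws `n_clones` clones per iteration and reports the empirical
#' distribution of the number of distinct target variants found; the mean
#' converges to [expected_distinct()].
#'
#' @param dist A `variant_distribution` or scheme string.
#' @param n_clones Clones per iteration, >= 0.
#' @param n_iterations Monte Carlo iterations.
#' @param seed Integer seed or `NULL`.
#' @param targets Target variants (default: reachable amino acids).
#' @param keep_compositions Also return the per-iteration variant count
#'   matrix (n_iterations x variants; memory scales accordingly).
#' @return List with `distinct` (integer vector per iteration), `mean_distinct`,
#'   `table` (distribution of distinct counts), and `compositions` (matrix or
#'   `NULL`).
#' @export
#' @examples
#' f <- simulate_fixed_screen("NNM", 21, n_iterations = 5000, seed = 1)
#' f$mean_distinct  # near expected_distinct("NNM", 21) = 11.45
simulate_fixed_screen <- function(dist, n_clones, n_iterations = 1e5,
                                  seed = NULL,
                                  targets = reachable_variants(dist, include_stop = FALSE),
                                  keep_compositions = FALSE) {
  dist <- amino_acid_distribution(dist)
  stopifnot(n_clones >= 0, n_iterations >= 1)
  p <- .target_probs(dist, targets)
  probs <- dist$probs
  target <- as.integer(names(probs) %in% names(p))
  res <- .with_seed(seed, function()
    sim_fixed_cpp(unname(probs), target, as.integer(n_clones),
                  as.integer(n_iterations), keep_compositions))
  comp <- NULL
  if (keep_compositions) {
    comp <- res$compositions
    colnames(comp) <- names(probs)
  }
  list(distinct = res$distinct,
       mean_distinct = mean(res$distinct),
       table = table(res$distinct),
       compositions = comp,
       n_clones = n_clones, n_iterations = n_iterations, seed = seed)
}

#' Write a simulation summary as TSV
#'
#' Emits the per-rank table (columns selected by the config's `record`
#' field) preceded by a `# config: {...}` JSON metadata line so any output
#' is regenerable from its own header.
#'
#' @param summary A `simulation_summary`.
#' @param path Output file, or `""` for stdout.
#' @return `summary`, invisibly.
#' @export
write_simulation_tsv <- function(summary, path = "") {
  cfg <- attr(summary, "config")
  cols <- switch(cfg$record,
                 both = names(summary),
                 incremental = c("rank", "incremental_mean", "incremental_sd"),
                 cumulative = c("rank", "cumulative_mean", "cumulative_sd"))
  meta <- jsonlite::toJSON(list(scheme = cfg$dist$scheme, targets = cfg$targets,
                                n_iterations = cfg$n_iterations, seed = cfg$seed,
                                record = cfg$record),
                           auto_unbox = TRUE, null = "null", digits = NA)
  con <- if (nzchar(path)) file(path, "w") else stdout()
  if (nzchar(path)) on.exit(close(con))
  writeLines(paste0("# config: ", meta), con)
  utils::write.table(as.data.frame(summary)[, cols], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(summary)
}
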