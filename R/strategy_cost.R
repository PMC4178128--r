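# Cost model for library construction: pure random screening, pure
# one-by-one SDM, and the hybrid strategy (screen n clones, then build the
# still-missing variants by site-directed mutagenesis).

#' Cost model
#'
#' Unit costs of the two ways to obtain a variant. The defaults are typical
#' commercial figures: about 20 currency units to screen one clone (DNA
#' isolation plus sequencing) and about 100 to construct one variant by SDM
#' (oligo synthesis, mutagenesis kit, isolation, sequencing).
#'
#' @param cost_per_screened_clone Cost of screening one clone, > 0.
#' @param cost_per_sdm_variant Cost of one site-directed variant, > 0.
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(cost_per_screened_clone = 20, cost_per_sdm_variant = 100) {
  stopifnot(cost_per_screened_clone > 0, cost_per_sdm_variant > 0)
  structure(list(cost_per_screened_clone = cost_per_screened_clone,
                 cost_per_sdm_variant = cost_per_sdm_variant),
            class = "cost_model")
}

#' Expected cost of a hybrid screen-then-SDM strategy
#'
#' Screen `n_random` clones, then construct every still-missing target by
#' SDM. The expected number of missing targets after the screen is
#' [expected_missing()]; unreachable targets (e.g. Met/Trp under NNM) are
#' always missing and always incur SDM cost.
#'
#' @param dist A `variant_distribution` or scheme string.
#' @param targets Variants the finished library must contain.
#' @param cost A `cost_model`.
#' @param n_random Clones screened before switching to SDM, >= 0.
#' @return A `strategy_evaluation` list: `n_random`, `expected_missing`,
#'   `screening_cost`, `sdm_cost`, `expected_total_cost`.
#' @export
#' @examples
#' evaluate_strategy("NNM", amino_acids(), cost_model(), 21)  # about 1275
evaluate_strategy <- function(dist, targets, cost = cost_model(), n_random) {
  stopifnot(inherits(cost, "cost_model"), n_random >= 0)
  miss <- expected_missing(dist, n_random, targets)
  screening <- n_random * cost$cost_per_screened_clone
  sdm <- miss * cost$cost_per_sdm_variant
  structure(list(n_random = n_random, expected_missing = miss,
                 screening_cost = screening, sdm_cost = sdm,
                 expected_total_cost = screening + sdm),
            class = "strategy_evaluation")
}

#' @export
print.strategy_evaluation <- function(x, ...) {
  cat(sprintf(paste0("hybrid strategy: screen %d clone(s), then SDM\n",
                     "  expected missing after screen: %.3f\n",
                     "  expected total cost: %.2f (screening %.2f + SDM %.2f)\n"),
              x$n_random, x$expected_missing, x$expected_total_cost,
              x$screening_cost, x$sdm_cost))
  invisible(x)
}

#' Cost-optimal switch point from screening to SDM
#'
#' Minimizes the expected hybrid cost over the number of clones screened
#' before switching. The marginal cost of the n-th screened clone is
#' `cost_per_screened_clone - cost_per_sdm_variant * sum(p_i (1-p_i)^(n-1))`,
#' so the curve eventually increases and an exhaustive integer search over
#' `[0, n_max]` is both safe and cheap.
#'
#' @inheritParams evaluate_strategy
#' @param n_max Upper bound of the search. Default: 4 x the 95% library size
#'   over the reachable targets, or 1000 when every reachable target check
#'   is moot (no reachable targets).
#' @return List with `n_opt` (smallest minimizer), `evaluation` (the
#'   [evaluate_strategy()] result at `n_opt`) and `curve` (data.frame
#'   `n`, `expected_missing`, `expected_cost`).
#' @export
#' @examples
#' optimal_switch_point("NNM", amino_acids())$n_opt
optimal_switch_point <- function(dist, targets, cost = cost_model(), n_max = NULL) {
  stopifnot(inherits(cost, "cost_model"))
  dist <- amino_acid_distribution(dist)
  p <- .target_probs(dist, targets)
  if (is.null(n_max)) {
    reach <- names(p)[p > 0]
    if (length(reach)) {
      P <- function(L) completeness_probability(dist, L, reach, method = "product")
      L <- 1L
      while (P(L) < 0.95) L <- L * 2L
      while (L > 1L && P(L - 1L) >= 0.95) L <- L - 1L
      n_max <- 4L * L
    } else {
      n_max <- 1000L
    }
  }
  n <- 0:n_max
  miss <- vapply(n, function(k) expected_missing(dist, k, names(p)), 0)
  cost_curve <- n * cost$cost_per_screened_clone +
    miss * cost$cost_per_sdm_variant
  n_opt <- n[which.min(cost_curve)]  # which.min takes the first => smallest n
  list(n_opt = n_opt,
       evaluation = evaluate_strategy(dist, names(p), cost, n_opt),
       curve = data.frame(n = n, expected_missing = miss,
                          expected_cost = cost_curve))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Observed screen composition
#'
#' Per-variant clone counts from a sequenced screen.
#'
#' @param counts Named nonnegative integer vector, variant symbol -> copies.
#' @return An `observed_composition` with `counts` and `n_clones`.
#' @export
#' @examples
#' observed_composition(c(L = 5, P = 3, R = 3, S = 2, A = 2,
#'                        G = 2, H = 1, T = 1, D = 1, F = 1))
observed_composition <- function(counts) {
  if (is.null(names(counts))) stop("counts must be named", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(list(counts = counts, n_clones = sum(counts)),
            class = "observed_composition")
}

#' Read an observed composition from TSV
#'
#' Expects two columns: variant symbol and count (header optional,
#' `variant` / `count`).
#'
#' @param path TSV file.
#' @return An `observed_composition`.
#' @export
read_composition_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("variant", first, ignore.case = TRUE)
  df <- if (header) {
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("variant", "count"))
  }
  names(df) <- tolower(names(df))
  observed_composition(stats::setNames(df$count, df$variant))
}

#' Realized cost of a finished hybrid library
#'
#' Arithmetic on what actually happened: clones screened plus SDM reactions
#' run to complete the library.
#'
#' @param observed An `observed_composition` (or a bare clone count).
#' @param remaining_sdm_variants Variants built by SDM after the screen
#'   (character vector), or their number.
#' @param cost A `cost_model`.
#' @return Total cost (numeric).
#' @export
#' @examples
#' comp <- observed_composition(c(L = 5, P = 3, R = 3, S = 2, A = 2,
#'                                G = 2, H = 1, T = 1, D = 1, F = 1))
#' realized_cost(comp, 10)  # 21 * 20 + 10 * 100 = 1420
realized_cost <- function(observed, remaining_sdm_variants, cost = cost_model()) {
  stopifnot(inherits(cost, "cost_model"))
  n_clones <- if (inherits(observed, "observed_composition"))
    observed$n_clones else as.numeric(observed)
  n_sdm <- if (is.character(remaining_sdm_variants))
    length(remaining_sdm_variants) else as.numeric(remaining_sdm_variants)
  n_clones * cost$cost_per_screened_clone + n_sdm * cost$cost_per_sdm_variant
}

#' Write a cost curve as TSV or JSON
#'
#' @param switch_result Return value of [optimal_switch_point()].
#' @param path Output file, or `""` for stdout.
#' @param cost The `cost_model` used (echoed into JSON metadata).
#' @param format `"tsv"` or `"json"`.
#' @return `switch_result`, invisibly.
#' @export
write_cost_report <- function(switch_result, path = "", cost = cost_model(),
                              format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- if (nzchar(path)) file(path, "w") else stdout()
    if (nzchar(path)) on.exit(close(con))
    writeLines(sprintf("# n_opt: %d\texpected_cost: %.6g", switch_result$n_opt,
                       switch_result$evaluation$expected_total_cost), con)
    utils::write.table(switch_result$curve, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out <- list(n_opt = switch_result$n_opt,
                expected_total_cost = switch_result$evaluation$expected_total_cost,
                expected_missing = switch_result$evaluation$expected_missing,
                cost_model = unclass(cost),
                curve = switch_result$curve)
    txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (nzchar(path)) writeLines(txt, path) else cat(txt, "\n")
  }
  invisible(switch_result)
}
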