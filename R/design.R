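# Split-plot experimental design utilities. Growth chambers are whole-plot
# units receiving environmental treatment combinations; pots inside each
# chamber are split-plot units receiving genotypes. A single run is
# unreplicated at the whole-plot level, so inference requires repeated runs
# with fresh randomizations — `new_replication` does that bookkeeping.

#' Treatment factor specification
#'
#' @param name factor name (e.g. `"temperature"`)
#' @param levels ordered vector of at least 2 distinct levels
#' @return object of class `factor_spec`
#' @export
factor_spec <- function(name, levels) {
  if (length(unique(levels)) < 2) stop("a factor needs >= 2 distinct levels")
  structure(list(name = name, levels = levels), class = "factor_spec")
}

#' Enumerate treatment combinations
#'
#' Full Cartesian product of the factor levels, ordered lexicographically in
#' the declared factor order (the first factor varies slowest). Three
#' two-level factors — e.g. temperature, humidity and CO2, each low vs.
#' high — give the canonical 8 combinations.
#'
#' @param factors list of `factor_spec`
#' @return data.frame, one row per combination, one column per factor
#' @export
enumerate_combinations <- function(factors) {
  if (!length(factors)) stop("at least one factor is required")
  lv <- lapply(factors, function(f) {
    if (!inherits(f, "factor_spec")) stop("'factors' must be factor_spec objects")
    f$levels
  })
  names(lv) <- vapply(factors, function(f) f$name, character(1))
  # expand.grid varies the first column fastest; reverse to get the declared
  # order lexicographic (first factor slowest)
  g <- expand.grid(rev(lv), stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(lv)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Randomize a split-plot layout
#'
#' Treatment combinations are assigned to chambers by a uniform random
#' permutation; when there are fewer combinations than chambers each
#' combination is replicated on an equal number of chambers (e.g. 2
#' combinations over 8 chambers -> 4 chambers each). Within every chamber
#' the genotypes are independently permuted over pot positions. The whole
#' layout is a deterministic function of the seed.
#'
#' @param chambers vector of chamber identifiers
#' @param combinations data.frame from [enumerate_combinations()]
#' @param genotypes vector of genotype names
#' @param pots_per_chamber number of pot positions per chamber,
#'   `>= length(genotypes)`
#' @param seed integer randomization seed
#' @param run_id run (replication) index stored in the layout
#' @return object of class `design_layout`: `run_id`, `chamber_table`
#'   (chamber + factor columns), `pot_table` (chamber, pot, genotype),
#'   `seed`, plus the inputs needed to re-randomize
#' @export
assign_splitplot <- function(chambers, combinations, genotypes,
                             pots_per_chamber = length(genotypes), seed,
                             run_id = 1L) {
  if (missing(seed)) stop("'seed' is required for a reproducible layout")
  n_ch <- length(chambers)
  n_cb <- nrow(combinations)
  if (n_cb > n_ch)
    stop(sprintf(paste("more combinations (%d) than chambers (%d):",
                       "use an incomplete-block design with multiple runs as blocks"),
                 n_cb, n_ch))
  if (n_ch %% n_cb != 0)
    stop("the number of chambers must be a multiple of the number of combinations")
  if (length(genotypes) > pots_per_chamber)
    stop("more genotypes than pot positions per chamber")
  if (anyDuplicated(chambers)) stop("chamber identifiers must be distinct")
  if (anyDuplicated(genotypes)) stop("genotype names must be distinct")

  with_seed(seed, {
    reps <- n_ch / n_cb
    comb_idx <- sample(rep(seq_len(n_cb), each = reps))
    chamber_table <- cbind(data.frame(chamber = chambers),
                           combinations[comb_idx, , drop = FALSE])
    rownames(chamber_table) <- NULL
    pot_rows <- lapply(seq_len(n_ch), function(i) {
      pos <- sample(pots_per_chamber, length(genotypes))
      data.frame(chamber = chambers[i], pot = sort(pos),
                 genotype = genotypes[order(pos)], stringsAsFactors = FALSE)
    })
    structure(list(run_id = as.integer(run_id),
                   chamber_table = chamber_table,
                   pot_table = do.call(rbind, pot_rows),
                   chambers = chambers, combinations = combinations,
                   genotypes = genotypes, pots_per_chamber = pots_per_chamber,
                   seed = as.integer(seed)),
              class = "design_layout")
  })
}

#' @export
print.design_layout <- function(x, ...) {
  cat(sprintf("<design_layout> run %d: %d chambers x %d genotypes = %d split-plot units\n",
              x$run_id, length(x$chambers), length(x$genotypes),
              length(x$chambers) * length(x$genotypes)))
  invisible(x)
}

#' Fresh randomization for the next run
#'
#' Whole-plot inference needs replication, i.e. repeated runs with new
#' plants and new random assignments. The new layout keeps the chambers,
#' combinations and genotypes, increments `run_id`, and re-randomizes both
#' levels from a child seed derived from (`seed`, new run id) — so passing
#' the original seed still yields a different (but reproducible) layout for
#' run 2.
#'
#' @param layout a `design_layout`
#' @param seed base seed for the new run (default: the layout's seed)
#' @return a new `design_layout` with `run_id + 1`
#' @export
new_replication <- function(layout, seed = layout$seed) {
  stopifnot(inherits(layout, "design_layout"))
  rid <- layout$run_id + 1L
  assign_splitplot(layout$chambers, layout$combinations, layout$genotypes,
                   layout$pots_per_chamber, seed = child_seed(seed, rid),
                   run_id = rid)
}

#' Export a design layout
#'
#' @param layout `design_layout`
#' @param path output file
#' @param format `"csv"` (one row per run/chamber/pot/genotype with the
#'   chamber's treatment combination) or `"json"`
#' @return `path`, invisibly
#' @export
export_layout <- function(layout, path, format = c("csv", "json")) {
  format <- match.arg(format)
  flat <- merge(cbind(run = layout$run_id, layout$pot_table),
                layout$chamber_table, by = "chamber", sort = FALSE)
  flat <- flat[order(flat$chamber, flat$pot), ]
  rownames(flat) <- NULL
  if (format == "csv") utils::write.csv(flat, path, row.names = FALSE)
  else jsonlite::write_json(flat, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' Genotype-specific quadratic response-surface fit
#'
#' Fits, separately for each genotype, response = a + b t + c t^2 by least
#' squares over the treatment levels (e.g. temperatures 22, 24, 26, 28
#' degC), and estimates the level at which the expected response is
#' maximized: the vertex -b / (2c) when the fit is concave (c < 0) and the
#' vertex lies inside the design range; otherwise the range endpoint with
#' the higher fitted value. Genotypes observed at fewer than 3 distinct
#' levels are flagged and not fitted.
#'
#' @param data data.frame with columns `genotype`, `level`, `response`
#' @param level_range length-2 design range the optimum is clipped to
#'   (default: range of observed levels)
#' @return object of class `response_surface_fit`: data.frame `fits` with
#'   per-genotype intercept, linear, quadratic coefficients, standard
#'   errors, `optimum`, `at_boundary`, `flagged`
#' @export
fit_response_surface <- function(data, level_range = range(data$level)) {
  need <- c("genotype", "level", "response")
  if (!all(need %in% names(data)))
    stop("'data' must have columns genotype, level, response")
  gens <- unique(data$genotype)
  rows <- lapply(gens, function(g) {
    d <- data[data$genotype == g, ]
    if (length(unique(d$level)) < 3) {
      return(data.frame(genotype = g, intercept = NA_real_, linear = NA_real_,
                        quadratic = NA_real_, se_intercept = NA_real_,
                        se_linear = NA_real_, se_quadratic = NA_real_,
                        optimum = NA_real_, at_boundary = NA, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(response ~ level + I(level^2), data = d)
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 3))
    if (length(se) < 3) se <- rep(NA_real_, 3)
    a <- cf[[1]]; b <- cf[[2]]; cc <- cf[[3]]
    pred <- function(t) a + b * t + cc * t^2
    vertex <- if (is.finite(cc) && cc < 0) -b / (2 * cc) else NA_real_
    if (!is.na(vertex) && vertex >= level_range[1] && vertex <= level_range[2]) {
      opt <- vertex; boundary <- FALSE
    } else {
      opt <- level_range[[which.max(pred(level_range))]]
      boundary <- TRUE
    }
    data.frame(genotype = g, intercept = a, linear = b, quadratic = cc,
               se_intercept = se[[1]], se_linear = se[[2]], se_quadratic = se[[3]],
               optimum = opt, at_boundary = boundary, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  structure(list(fits = do.call(rbind, rows), level_range = level_range),
            class = "response_surface_fit")
}

#' @export
print.response_surface_fit <- function(x, ...) {
  cat(sprintf("<response_surface_fit> %d genotype(s), level range [%g, %g]\n",
              nrow(x$fits), x$level_range[1], x$level_range[2]))
  print(x$fits[, c("genotype", "quadratic", "optimum", "at_boundary", "flagged")],
        row.names = FALSE)
  invisible(x)
}
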