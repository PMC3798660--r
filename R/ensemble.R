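# Seeded Monte-Carlo ensembles and parameter sweeps over the
# generate -> form-find -> stretch -> modulus pipeline.

# Deterministic per-sample seed stream derived from a master seed
# (Lehmer-style mixing, kept below 2^31).
derive_seed <- function(master, ...) {
  m <- 2147483647
  s <- as.numeric(master) %% m
  for (k in c(...)) s <- (s * 48271 + as.numeric(k)) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(max(1, s))
}

#' Specification of a Monte-Carlo ensemble or parameter sweep
#'
#' @param base_config A [generation_config()] providing all parameters not
#'   being swept.
#' @param n_samples Number of network realisations per sweep point (>= 2).
#' @param master_seed Integer master seed; per-sample seeds are derived
#'   from it deterministically, so results are independent of execution
#'   order.
#' @param sweep_variable One of `"relative_density"`, `"filament_length"`,
#'   `"crosslink_fraction"`, `"domain_size"`, `"prestress"`, or `NULL` for
#'   a single-point ensemble.  `"filament_length"` sets the mean and keeps
#'   the standard deviation perfectly correlated at 20% of the mean;
#'   `"domain_size"` sets both side lengths.
#' @param sweep_values Numeric vector of values for the swept variable.
#' @return An `ensemble_spec`.
#' @export
ensemble_spec <- function(base_config, n_samples, master_seed,
                          sweep_variable = NULL, sweep_values = NULL) {
  validate_generation_config(base_config)
  stopifnot(n_samples >= 2)
  if (!is.null(sweep_variable)) {
    sweep_variable <- match.arg(sweep_variable,
                                c("relative_density", "filament_length",
                                  "crosslink_fraction", "domain_size",
                                  "prestress"))
    if (is.null(sweep_values) || !length(sweep_values))
      stop("`sweep_values` must be given for a sweep", call. = FALSE)
  }
  structure(list(base_config = base_config,
                 n_samples = as.integer(n_samples),
                 master_seed = as.integer(master_seed),
                 sweep_variable = sweep_variable,
                 sweep_values = sweep_values),
            class = "ensemble_spec")
}

# Apply one sweep value to the base configuration; prestress is not a
# generation parameter and is returned separately.
apply_sweep <- function(cfg, variable, value) {
  prestress <- NULL
  if (!is.null(variable)) {
    if (variable == "relative_density") cfg$target_relative_density <- value
    else if (variable == "filament_length") {
      cfg$filament_length_mean <- value
      cfg$filament_length_std <- 0.2 * value
    } else if (variable == "crosslink_fraction") cfg$crosslink_fraction <- value
    else if (variable == "domain_size") {
      cfg$domain_width <- value
      cfg$domain_height <- value
    } else if (variable == "prestress") prestress <- value
  }
  validate_generation_config(cfg)
  list(cfg = cfg, prestress = prestress)
}

#' Run a seeded ensemble (optionally swept over one parameter)
#'
#' For every sweep value and every sample: generate a network with a seed
#' derived from the master seed, form-find it, stretch it to the
#' measurement strain, and record the effective modulus.  A failed sample
#' is retried up to twice with freshly derived seeds; unrecovered failures
#' are reported, and more than 10% failures at any sweep point aborts the
#' ensemble.
#'
#' @param spec An [ensemble_spec()].
#' @param settings A [solver_settings()].
#' @param measure_strain Modulus measurement strain (default 0.01).
#' @param progress Print one line per completed sample.
#' @return An `ensemble_result` with `$samples` (one row per converged
#'   sample), `$summary` (per sweep point: `n`, `mean`, `sd` of the
#'   modulus, in kPa), and `$failures`.
#' @export
run_ensemble <- function(spec, settings = solver_settings(),
                         measure_strain = 0.01, progress = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  values <- if (is.null(spec$sweep_variable)) NA_real_ else spec$sweep_values
  rows <- list(); fails <- list()
  for (vi in seq_along(values)) {
    pt <- apply_sweep(spec$base_config, spec$sweep_variable, values[vi])
    n_fail <- 0L
    for (si in seq_len(spec$n_samples)) {
      row <- NULL; err <- NULL
      for (retry in 0:2) {
        seed <- derive_seed(spec$master_seed, vi, si, retry)
        cfg_i <- pt$cfg
        cfg_i$seed <- seed
        row <- tryCatch(
          simulate_sample(cfg_i, prestress = pt$prestress,
                          measure_strain = measure_strain,
                          settings = settings),
          error = function(e) { err <<- conditionMessage(e); NULL })
        if (!is.null(row)) break
      }
      if (is.null(row)) {
        n_fail <- n_fail + 1L
        fails[[length(fails) + 1L]] <-
          tibble::tibble(sweep_value = values[vi], sample = si, error = err)
      } else {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(sweep_value = values[vi], sample = si), row)
        if (progress)
          message(sprintf("value %s sample %d: E = %.3f kPa",
                          format(values[vi]), si, row$modulus))
      }
      if (n_fail > 0.1 * spec$n_samples)
        stop("more than 10% of samples failed to converge at sweep value ",
             values[vi], call. = FALSE)
    }
  }
  samples <- dplyr::bind_rows(rows)
  summary <- samples |>
    dplyr::group_by(.data$sweep_value) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$modulus),
                     sd = stats::sd(.data$modulus),
                     .groups = "drop")
  structure(list(samples = samples, summary = summary,
                 failures = dplyr::bind_rows(fails), spec = spec),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result>")
  if (!is.null(x$spec$sweep_variable))
    cat(" sweep over", x$spec$sweep_variable)
  cat("\n")
  print(x$summary)
  if (NROW(x$failures))
    cat(NROW(x$failures), "sample(s) failed\n")
  invisible(x)
}

#' Histogram of ensemble moduli
#'
#' @param result An `ensemble_result`.
#' @param bins Number of uniform bins over the sample range (default 20).
#' @return Tibble with `sweep_value`, `bin_left`, `bin_right`, `count`.
#' @export
modulus_histogram <- function(result, bins = 20) {
  stopifnot(inherits(result, "ensemble_result"))
  result$samples |>
    dplyr::group_by(.data$sweep_value) |>
    dplyr::reframe({
      breaks <- seq(min(.data$modulus), max(.data$modulus),
                    length.out = bins + 1)
      if (length(unique(breaks)) == 1)
        breaks <- breaks[1] + c(-0.5, 0.5)
      h <- graphics::hist(.data$modulus, breaks = unique(breaks),
                          plot = FALSE, include.lowest = TRUE)
      tibble::tibble(bin_left = utils::head(h$breaks, -1),
                     bin_right = h$breaks[-1], count = h$counts)
    })
}

#' Ordinary least-squares trend of ensemble means against a swept value
#'
#' @param sweep_values Numeric vector of sweep values (>= 3 distinct).
#' @param means Mean modulus at each value.
#' @return One-row tibble with `slope`, `intercept`, `r_squared`.
#' @export
fit_linear_trend <- function(sweep_values, means) {
  stopifnot(length(sweep_values) == length(means), length(means) >= 3)
  if (length(unique(sweep_values)) < 2)
    stop("all sweep values are equal; the trend is degenerate",
         call. = FALSE)
  fit <- stats::lm(means ~ sweep_values)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared)
}
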