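## broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the background mutation model
#'
#' One row per coefficient with Wald standard errors and normal 95%
#' confidence intervals.  The intercept shown is the cohort-scale value
#' (already corrected for any negative-observation thinning).
#'
#' @param x a `background_model`.
#' @param conf.level confidence level.
#' @param ... unused.
#' @return tibble `term`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @method tidy background_model
#' @export
tidy.background_model <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(se),
         conf.low = unname(x$coefficients - z * se),
         conf.high = unname(x$coefficients + z * se))
}

#' @rdname tidy.background_model
#' @method glance background_model
#' @export
glance.background_model <- function(x, ...) {
  tibble(kind = x$kind, deviance = x$deviance,
         null.deviance = x$null_deviance, df.residual = x$df_residual,
         nobs = x$n_obs, sampling.fraction = x$sampling_fraction,
         converged = x$converged)
}

#' @export
print.background_model <- function(x, ...) {
  cat("Background mutation model (", x$kind, ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a signature exposure profile
#'
#' @param x an `exposure_profile`.
#' @param ... unused.
#' @return tibble `signature`, `weight` (post-threshold).
#' @method tidy exposure_profile
#' @export
tidy.exposure_profile <- function(x, ...) {
  tibble(signature = names(x$weights), weight = unname(x$weights))
}

#' @rdname tidy.exposure_profile
#' @method glance exposure_profile
#' @export
glance.exposure_profile <- function(x, ...) {
  tibble(n_mutations = x$n_mutations, residual = x$residual,
         n_active = sum(x$weights > 0), assigned = sum(x$weights))
}

#' Summary of a recurrence batch
#'
#' @param x a `recurrence_result`.
#' @param q_max significance threshold.
#' @param ... unused.
#' @return one-row tibble with region and hit counts.
#' @method glance recurrence_result
#' @export
glance.recurrence_result <- function(x, q_max = 0.05, ...) {
  tibble(n_regions = nrow(x),
         n_mutated = sum(x$n_mutations > 0),
         n_cluster_tested = sum(!is.na(x$p_cluster)),
         n_significant = sum(x$q < q_max, na.rm = TRUE))
}
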