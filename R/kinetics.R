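#' Normalize raw velocities to an expression signal
#'
#' Divides raw product-formation rates by the enzyme-expression signal of the
#' lysate (e.g. an immunoblot intensity), so that curves from lysates with
#' different expression levels become comparable.
#'
#' @param raw_velocities Numeric vector of raw velocities.
#' @param expression_signal Positive scalar expression signal.
#' @return Normalized velocities.
#' @export
normalize_rates <- function(raw_velocities, expression_signal) {
  if (!is.numeric(expression_signal) || length(expression_signal) != 1L ||
      is.na(expression_signal) || expression_signal <= 0) {
    stop("expression signal must be a positive scalar", call. = FALSE)
  }
  raw_velocities / expression_signal
}

.new_fit <- function(model, method, est, se, rss, converged, flag = NA_character_) {
  structure(list(model = model, method = method,
                 km = unname(est["km"]), vmax = unname(est["vmax"]),
                 ki = unname(est["ki"]),
                 se = se, rss = rss, converged = converged, flag = flag),
            class = "tph2_kinfit")
}

#' @export
print.tph2_kinfit <- function(x, ...) {
  cat(sprintf("%s fit (%s): Km = %.4g, Vmax = %.4g%s; RSS = %.4g; converged: %s\n",
              toupper(x$model), x$method, x$km, x$vmax,
              if (!is.null(x$ki) && !is.na(x$ki)) sprintf(", Ki = %.4g", x$ki) else "",
              x$rss, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

.check_dataset <- function(dataset, min_s = 3L) {
  stopifnot(all(c("S", "v") %in% names(dataset)))
  if (any(dataset$S <= 0)) stop("substrate concentrations must be positive", call. = FALSE)
  if (length(unique(dataset$S)) < min_s) {
    stop(sprintf("need at least %d distinct substrate concentrations", min_s),
         call. = FALSE)
  }
  dataset
}

#' Lineweaver-Burk estimation of Km and Vmax
#'
#' Ordinary least squares of 1/v on 1/S; Km = slope/intercept,
#' Vmax = 1/intercept.  Exact on noiseless Michaelis-Menten data; biased on
#' noisy data relative to nonlinear least squares because the reciprocal
#' transform inflates low-velocity errors (both estimators are therefore
#' reported side by side by the comparison tools).
#'
#' @param dataset Data.frame with columns `S` and `v` (all `v` > 0).
#' @return A `tph2_kinfit`.
#' @export
fit_lineweaver_burk <- function(dataset) {
  .check_dataset(dataset)
  if (any(dataset$v <= 0)) {
    stop("Lineweaver-Burk requires strictly positive velocities", call. = FALSE)
  }
  fit <- stats::lm(I(1 / v) ~ I(1 / S), data = dataset)
  b <- stats::coef(fit)
  intercept <- b[[1]]; slope <- b[[2]]
  if (intercept <= 0) {
    return(.new_fit("mm", "lineweaver_burk", c(km = NA_real_, vmax = NA_real_),
                    se = NULL, rss = NA_real_, converged = FALSE,
                    flag = "invalid fit: non-positive intercept"))
  }
  km <- slope / intercept
  vmax <- 1 / intercept
  rss <- sum((dataset$v - mm_velocity(dataset$S, km, vmax))^2)
  .new_fit("mm", "lineweaver_burk", c(km = km, vmax = vmax), se = NULL,
           rss = rss, converged = TRUE)
}

# Multi-start nonlinear least squares shared by the MM and SI fitters.
.fit_nls <- function(dataset, model, starts, lower) {
  formula <- if (model == "mm") {
    v ~ vmax * S / (km + S)
  } else {
    v ~ vmax * S / (km + S + S^2 / ki)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = dataset, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  best
}

.mm_starts <- function(dataset) {
  lb <- tryCatch(fit_lineweaver_burk(dataset), error = function(e) NULL)
  starts <- list()
  if (!is.null(lb) && lb$converged && lb$km > 0 && lb$vmax > 0) {
    starts[[1]] <- list(km = lb$km, vmax = lb$vmax)
  }
  vtop <- max(dataset$v)
  for (q in stats::quantile(dataset$S, c(0.1, 0.25, 0.5, 0.75))) {
    starts[[length(starts) + 1L]] <- list(km = unname(q), vmax = vtop)
  }
  starts[[length(starts) + 1L]] <- list(km = stats::median(dataset$S),
                                        vmax = 2 * vtop)
  starts
}

#' Fit the Michaelis-Menten model by nonlinear least squares
#'
#' Multi-start Levenberg-Marquardt least squares on
#' v = Vmax S / (Km + S), started from the Lineweaver-Burk estimate and a
#' grid over the substrate range (at least 5 starts).  Saturation-only data
#' (no curvature information on Km) are flagged as non-identifiable.
#'
#' @param dataset Data.frame with columns `S` and `v`, at least 3 distinct
#'   substrate concentrations.
#' @return A `tph2_kinfit` with parameter standard errors.
#' @export
fit_mm <- function(dataset) {
  .check_dataset(dataset, 3L)
  best <- .fit_nls(dataset, "mm", .mm_starts(dataset), lower = c(1e-9, 1e-9))
  if (is.null(best)) {
    return(.new_fit("mm", "nls", c(km = NA_real_, vmax = NA_real_), NULL,
                    NA_real_, FALSE, flag = "no start converged"))
  }
  est <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 2))
  flag <- NA_character_
  converged <- TRUE
  if (any(!is.finite(se)) || (is.finite(se[["km"]]) && se[["km"]] > 100 * est[["km"]])) {
    flag <- "non-identifiable: Km standard error unbounded"
    converged <- FALSE
  }
  .new_fit("mm", "nls", c(km = est[["km"]], vmax = est[["vmax"]]),
           se = se, rss = best$rss, converged = converged, flag = flag)
}

#' Fit the Haldane substrate-inhibition model
#'
#' Multi-start nonlinear least squares on
#' v = Vmax S / (Km + S + S^2/Ki), the standard single-site
#' uncompetitive-substrate-inhibition form, whose velocity peaks at
#' S = sqrt(Km Ki).  Data without a descending limb leave Ki unbounded and
#' are flagged.
#'
#' @param dataset Data.frame with columns `S` and `v`, at least 4 distinct
#'   substrate concentrations.
#' @return A `tph2_kinfit` with `ki`.
#' @export
fit_substrate_inhibition <- function(dataset) {
  .check_dataset(dataset, 4L)
  mm0 <- fit_mm(dataset)
  s_max <- max(dataset$S)
  starts <- list()
  base_km <- if (mm0$converged) mm0$km else stats::median(dataset$S)
  base_vm <- if (mm0$converged) mm0$vmax else max(dataset$v)
  for (ki0 in c(s_max / 2, s_max, 2 * s_max, 10 * s_max)) {
    starts[[length(starts) + 1L]] <- list(km = base_km, vmax = base_vm, ki = ki0)
  }
  starts[[length(starts) + 1L]] <- list(km = stats::median(dataset$S),
                                        vmax = 2 * max(dataset$v), ki = s_max)
  best <- .fit_nls(dataset, "si", starts, lower = c(1e-9, 1e-9, 1e-9))
  if (is.null(best)) {
    return(.new_fit("si", "nls", c(km = NA_real_, vmax = NA_real_, ki = NA_real_),
                    NULL, NA_real_, FALSE, flag = "no start converged"))
  }
  est <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  # no descending limb: mean velocity still rising at the largest S
  mean_v <- tapply(dataset$v, dataset$S, mean)
  s_sorted <- sort(unique(dataset$S))
  flag <- NA_character_
  if (which.max(mean_v[as.character(s_sorted)]) == length(s_sorted) ||
      est[["ki"]] > 100 * s_max) {
    flag <- "Ki unbounded: no descending limb in the data"
  }
  .new_fit("si", "nls", c(km = est[["km"]], vmax = est[["vmax"]],
                          ki = est[["ki"]]),
           se = se, rss = best$rss, converged = TRUE, flag = flag)
}

#' Compare kinetic parameters across enzyme variants
#'
#' Summarizes replicate-level parameter estimates per variant (mean, SEM),
#' runs pairwise two-tailed Welch tests on Km, and reports Vmax ratios
#' relative to a designated baseline variant.
#'
#' @param estimates Data.frame with columns `variant`, `km`, `vmax`
#'   (one row per replicate fit).
#' @param baseline Variant label used as the Vmax-ratio denominator.
#' @return A list with `summary` (per variant: n, mean/SEM of Km and Vmax,
#'   `vmax_ratio` vs baseline) and `pairwise` (variant pair, Welch t, df, p
#'   on Km).
#' @export
compare_variants <- function(estimates, baseline) {
  stopifnot(all(c("variant", "km", "vmax") %in% names(estimates)))
  if (!baseline %in% estimates$variant) {
    stop("baseline variant not present in estimates", call. = FALSE)
  }
  split_km <- split(estimates$km, estimates$variant)
  split_vm <- split(estimates$vmax, estimates$variant)
  variants <- names(split_km)
  summ <- data.frame(
    variant = variants,
    n = vapply(split_km, length, integer(1)),
    km_mean = vapply(split_km, mean, numeric(1)),
    km_sem = vapply(split_km, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    vmax_mean = vapply(split_vm, mean, numeric(1)),
    vmax_sem = vapply(split_vm, function(x)
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  summ$vmax_ratio <- summ$vmax_mean / summ$vmax_mean[summ$variant == baseline]
  summ$flag <- ifelse(summ$n < 2, "single replicate: SEM undefined", NA_character_)
  pairs <- utils::combn(variants, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(p) {
    a <- split_km[[p[1]]]; b <- split_km[[p[2]]]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(variant_1 = p[1], variant_2 = p[2], t = NA_real_,
                        df = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    cmp <- compare_editing(a, b)
    data.frame(variant_1 = p[1], variant_2 = p[2], t = cmp$t, df = cmp$df,
               p = cmp$p, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- rownames(pw) <- NULL
  list(summary = summ, pairwise = pw)
}

#' Parameter-recovery study for the kinetics fitters
#'
#' Simulates `n_reps` replicate experiments at known parameters, refits each,
#' and returns the replicate-level estimates together with medians; the
#' workhorse behind the recovery checks on printed Km values.
#'
#' @param model `"mm"` or `"si"`.
#' @param km,vmax,ki True parameters.
#' @param s_grid Substrate grid (uM).
#' @param noise_cv Multiplicative lognormal noise CV.
#' @param n_reps Number of replicate experiments.
#' @param method `"nls"` or `"lineweaver_burk"` (MM only).
#' @param seed Optional integer seed.
#' @return A list with `estimates` (data.frame km, vmax, ki, converged) and
#'   `median_km`, `median_vmax`.
#' @export
recover_parameters <- function(model = c("mm", "si"), km, vmax, ki = NULL,
                               s_grid, noise_cv = 0.05, n_reps = 200L,
                               method = c("nls", "lineweaver_burk"),
                               seed = NULL) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (!is.null(seed)) {
    old_rng <- .save_rng()
    on.exit(.restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }
  rows <- lapply(seq_len(n_reps), function(r) {
    d <- generate_kinetic_dataset(model, km, vmax, ki, s_grid, noise_cv, 1L)
    fit <- if (model == "si") {
      fit_substrate_inhibition(d)
    } else if (method == "nls") {
      fit_mm(d)
    } else {
      fit_lineweaver_burk(d)
    }
    data.frame(km = fit$km, vmax = fit$vmax,
               ki = if (is.null(fit$ki)) NA_real_ else fit$ki,
               converged = fit$converged)
  })
  est <- do.call(rbind, rows)
  list(estimates = est,
       median_km = stats::median(est$km, na.rm = TRUE),
       median_vmax = stats::median(est$vmax, na.rm = TRUE))
}
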