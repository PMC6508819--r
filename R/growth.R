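# Two-stage growth analysis. Stage 1: nonlinear least-squares logistic fit
# H(t) = A / (1 + exp(-r (t - t_half))) to each replicate's height series,
# with the derived parameters t_half and dt(1/2 -> 3/4) = ln(3)/r. Stage 2:
# per-parameter one-way comparison of the fitted parameters across groups,
# the pragmatic alternative to a full nonlinear mixed model.

#' Validate a single growth trajectory
#'
#' @param times Observation times (weeks), strictly increasing, length >= 5.
#' @param heights Heights (cm), non-negative, same length as `times`.
#' @param plant_id,genotype,vernalization_weeks Metadata carried through.
#' @return A `growth_trajectory` list.
#' @export
growth_trajectory <- function(times, heights, plant_id = "plant",
                              genotype = NA_character_,
                              vernalization_weeks = NA_integer_) {
  times <- as.numeric(times); heights <- as.numeric(heights)
  if (length(times) != length(heights)) stop("times/heights length mismatch", call. = FALSE)
  if (length(times) < 5L) stop("need >= 5 observations to fit", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(heights < 0)) stop("heights must be >= 0", call. = FALSE)
  structure(list(plant_id = plant_id, genotype = genotype,
                 vernalization_weeks = vernalization_weeks,
                 times = times, heights = heights),
            class = "growth_trajectory")
}

.logistic <- function(t, A, r, t_half) A / (1 + exp(-r * (t - t_half)))

# starting values: A0 slightly above the max height, t_half0 at the first
# half-maximum crossing, r0 from a log-linear fit of logit(H/A0) on t
.logistic_start <- function(t, h) {
  A0 <- 1.05 * max(h)
  cross <- which(h >= A0 / 2)
  t_half0 <- if (length(cross)) t[cross[1L]] else max(t)
  frac <- pmin(pmax(h / A0, 1e-6), 1 - 1e-6)
  lg <- log(frac / (1 - frac))
  sl <- stats::coef(stats::lm(lg ~ t))[2L]
  r0 <- if (is.finite(sl) && sl > 0.01) unname(sl) else 0.5
  list(A = A0, r = r0, t_half = t_half0)
}

#' Fit a logistic growth curve to one replicate (stage 1)
#'
#' Least-squares fit of `H(t) = A / (1 + exp(-r (t - t_half)))`. Reported
#' alongside the parameters: `dt_half_to_3q = ln(3) / r`, the time from half
#' to three-quarters of the asymptote (an analytic identity of the
#' logistic), and `r2 = 1 - SSE/SST` against the mean-only model.
#'
#' @param traj A [growth_trajectory()], or anything accepted by it when
#'   `heights` is given.
#' @param heights,... Optional; passed to [growth_trajectory()] when `traj`
#'   is a numeric time vector.
#' @param tol Relative SSE convergence tolerance for the fallback optimizer.
#' @param max_iter Iteration cap (default 500).
#' @return A `growth_fit`: `A`, `r`, `t_half`, `dt_half_to_3q`, `r2`,
#'   `converged`, `sse`, plus the trajectory metadata.
#' @export
fit_logistic <- function(traj, heights = NULL, ..., tol = 1e-8, max_iter = 500L) {
  if (!inherits(traj, "growth_trajectory")) {
    traj <- growth_trajectory(traj, heights, ...)
  }
  t <- traj$times; h <- traj$heights
  if (stats::sd(h) < 1e-10) {
    stop("degenerate trajectory: heights are constant", call. = FALSE)
  }
  start <- .logistic_start(t, h)
  fit <- NULL
  converged <- FALSE
  try({
    fit <- stats::nls(h ~ A / (1 + exp(-r * (t - t_half))), start = start,
                      control = stats::nls.control(maxiter = max_iter,
                                                   tol = tol, minFactor = 1e-10,
                                                   warnOnly = FALSE))
    converged <- TRUE
  }, silent = TRUE)
  if (is.null(fit)) {
    # fall back to direct SSE minimization (Nelder-Mead)
    obj <- function(p) {
      if (p[1] <= 0 || p[2] <= 0) return(1e12)
      sum((h - .logistic(t, p[1], p[2], p[3]))^2)
    }
    op <- stats::optim(unlist(start), obj,
                       control = list(maxit = max_iter * 10, reltol = tol))
    par <- stats::setNames(op$par, c("A", "r", "t_half"))
    converged <- op$convergence == 0
  } else {
    par <- stats::coef(fit)
  }
  # polish to (near) machine precision with analytic gradients; nls's
  # relative-offset criterion can stop early on exactly-logistic data
  obj2 <- function(p) sum((h - .logistic(t, p[1], p[2], p[3]))^2)
  grad2 <- function(p) {
    s <- 1 / (1 + exp(-p[2] * (t - p[3])))
    res <- h - p[1] * s
    c(-2 * sum(res * s),
      -2 * sum(res * p[1] * s * (1 - s) * (t - p[3])),
      2 * sum(res * p[1] * s * (1 - s) * p[2]))
  }
  pol <- tryCatch(
    stats::optim(par, obj2, grad2, method = "BFGS",
                 control = list(maxit = 1000L, reltol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= obj2(par)) par <- pol$par
  A <- unname(par["A"]); r <- unname(par["r"]); t_half <- unname(par["t_half"])
  pred <- .logistic(t, A, r, t_half)
  sse <- sum((h - pred)^2)
  sst <- sum((h - mean(h))^2)
  r2 <- 1 - sse / sst
  if (A <= 0 || r <= 0) converged <- FALSE
  structure(list(plant_id = traj$plant_id, genotype = traj$genotype,
                 vernalization_weeks = traj$vernalization_weeks,
                 A = A, r = r, t_half = t_half,
                 dt_half_to_3q = log(3) / r,
                 r2 = r2, sse = sse, converged = converged),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s: A=%.2f cm, r=%.3f /wk, t_half=%.2f wk, dt(1/2->3/4)=%.2f wk, R2=%.4f%s\n",
              x$plant_id, x$A, x$r, x$t_half, x$dt_half_to_3q, x$r2,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Collect stage-1 fits into a data frame
#'
#' @param fits List of `growth_fit`.
#' @return Data frame, one row per fit.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    plant_id = f$plant_id, genotype = f$genotype,
    vernalization_weeks = f$vernalization_weeks,
    A = f$A, r = f$r, t_half = f$t_half,
    dt_half_to_3q = f$dt_half_to_3q, r2 = f$r2,
    converged = f$converged, stringsAsFactors = FALSE)))
}

#' Stage-2 comparison of fitted growth parameters across groups
#'
#' Treats each converged replicate fit's parameters (`A`, `t_half`,
#' `dt_half_to_3q`) as observations and runs an independent one-way
#' comparison per parameter across the supplied groups (classic or
#' Welch-corrected ANOVA). Groups with fewer than two converged fits are
#' excluded with a warning.
#'
#' @param fits List of `growth_fit` or a [fits_table()] data frame.
#' @param group Group label per fit (e.g. genotype x vernalization); defaults
#'   to `genotype` crossed with `vernalization_weeks`.
#' @param welch Use Welch's correction (unequal variances); default `FALSE`.
#' @return A `stage_two_result`: per parameter, a list with `means`
#'   (group means), `sd` (group SDs), `n` (group sizes), `statistic`, `df`,
#'   `p`.
#' @export
stage_two <- function(fits, group = NULL, welch = FALSE) {
  tab <- if (is.data.frame(fits)) fits else fits_table(fits)
  if (is.null(group)) {
    group <- paste(tab$genotype, tab$vernalization_weeks, sep = ":")
  }
  group <- as.character(group)
  stopifnot(length(group) == nrow(tab))
  conv <- tab$converged
  tab <- tab[conv, , drop = FALSE]
  group <- group[conv]
  sizes <- table(group)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding group(s) with < 2 converged fits: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !group %in% small
    tab <- tab[keep, , drop = FALSE]
    group <- group[keep]
  }
  if (length(unique(group)) < 2L) stop("need >= 2 groups with >= 2 fits", call. = FALSE)
  params <- c("A", "t_half", "dt_half_to_3q")
  res <- lapply(params, function(pm) {
    y <- tab[[pm]]
    g <- factor(group)
    if (stats::sd(y) < 1e-10 * (abs(mean(y)) + 1e-10)) {
      # no variation at all in this parameter: nothing to compare
      return(list(means = tapply(y, g, mean), sd = tapply(y, g, stats::sd),
                  n = as.integer(table(g)), statistic = 0, df = NA, p = 1))
    }
    if (welch) {
      tst <- stats::oneway.test(y ~ g)
      stat <- unname(tst$statistic); df <- unname(tst$parameter); p <- tst$p.value
    } else {
      av <- stats::anova(stats::lm(y ~ g))
      stat <- av$`F value`[1L]; df <- av$Df; p <- av$`Pr(>F)`[1L]
      if (is.na(p) && isTRUE(all.equal(stat, 0))) p <- 1
      if (is.nan(stat) || is.na(stat)) { stat <- 0; p <- 1 }
    }
    list(means = tapply(y, g, mean), sd = tapply(y, g, stats::sd),
         n = as.integer(table(g)), statistic = stat, df = df, p = p)
  })
  names(res) <- params
  structure(list(parameters = res, groups = levels(factor(group)),
                 welch = welch), class = "stage_two_result")
}

#' @export
print.stage_two_result <- function(x, ...) {
  cat(sprintf("<stage_two_result> groups: %s%s\n",
              paste(x$groups, collapse = ", "),
              if (x$welch) " (Welch)" else ""))
  for (pm in names(x$parameters)) {
    r <- x$parameters[[pm]]
    cat(sprintf("  %-14s F=%.3f p=%.4g | means: %s\n", pm, r$statistic, r$p,
                paste(sprintf("%s=%.2f", names(r$means), r$means), collapse = ", ")))
  }
  invisible(x)
}

#' Read growth trajectories from CSV
#'
#' Expected columns: `plant_id`, `genotype`, `weeks_vernalized`, `week`,
#' `height_cm`.
#'
#' @param path CSV path.
#' @return List of [growth_trajectory()] (one per plant).
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "genotype", "weeks_vernalized", "week", "height_cm")
  if (!all(need %in% colnames(df))) {
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(df, df$plant_id), function(d) {
    d <- d[order(d$week), , drop = FALSE]
    growth_trajectory(d$week, d$height_cm, plant_id = d$plant_id[1],
                      genotype = d$genotype[1],
                      vernalization_weeks = d$weeks_vernalized[1])
  })
}
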