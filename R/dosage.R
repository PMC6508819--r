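# Allele-dosage inference for a deletion segregating among homeologous gene
# copies: binomial maximum likelihood over integer dosages d of m alleles,
# Pearson chi-square goodness-of-fit against hypothesized ratios, and
# likelihood ranking of candidate copy configurations.

#' Hypothesize a deletion-allele dosage
#'
#' @param d Integer deletion-allele count at the locus.
#' @param m Integer total allele count (e.g. 6 for three diploid-behaving
#'   copies).
#' @param label Optional display label, e.g. a copy-configuration string.
#' @return A `dosage_hypothesis`.
#' @export
dosage_hypothesis <- function(d, m, label = NULL) {
  d <- as.integer(d); m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  if (is.na(d) || d < 0L || d > m) stop("d must be in 0..m", call. = FALSE)
  if (is.null(label)) label <- sprintf("%d/%d", d, m)
  structure(list(d = d, m = m, label = label), class = "dosage_hypothesis")
}

#' Parse a "d/m" string into a dosage hypothesis
#' @param x String like `"1/6"`.
#' @return A `dosage_hypothesis`.
#' @export
parse_dosage <- function(x) {
  parts <- strsplit(trimws(x), "/")[[1]]
  if (length(parts) != 2L) stop("expected 'd/m', got: ", x, call. = FALSE)
  dosage_hypothesis(as.integer(parts[1]), as.integer(parts[2]))
}

.ratio_lowest_terms <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  g <- function(x, y) if (y == 0L) x else Recall(y, x %% y)
  k <- g(max(a, b), min(a, b))
  if (k == 0L) k <- 1L
  c(a %/% k, b %/% k)
}

#' Pearson chi-square goodness of fit for an allele-count ratio
#'
#' Tests observed (deletion, reference) probe-read counts against the ratio
#' implied by a dosage hypothesis `d : (m - d)`. Two categories, expected
#' counts `N d/m` and `N (m-d)/m`, 1 degree of freedom, no continuity
#' correction. A boundary hypothesis (`d = 0` with deletion reads observed,
#' or `d = m` with reference reads observed) is impossible and returns
#' `p = 0` with `impossible = TRUE`. When any expected count is below 5 a
#' warning is issued and a two-sided exact binomial p-value is reported
#' alongside in `p_exact`.
#'
#' @param n_alt,n_ref Observed deletion- and reference-allele read counts.
#' @param hyp A [dosage_hypothesis()] (or `"d/m"` string).
#' @param exact_if_small Compute the exact binomial companion p-value when
#'   expected counts are small (default `TRUE`).
#' @return A `gof_result`: `chi2`, `df`, `p`, `hypothesis`, `impossible`,
#'   `expected`, and optionally `p_exact`.
#' @examples
#' chisq_gof(5, 21, dosage_hypothesis(1, 6))
#' @export
chisq_gof <- function(n_alt, n_ref, hyp, exact_if_small = TRUE) {
  if (is.character(hyp)) hyp <- parse_dosage(hyp)
  stopifnot(inherits(hyp, "dosage_hypothesis"))
  n_alt <- as.numeric(n_alt); n_ref <- as.numeric(n_ref)
  if (any(c(n_alt, n_ref) < 0)) stop("counts must be non-negative", call. = FALSE)
  N <- n_alt + n_ref
  if (N == 0) stop("no classified reads (N = 0)", call. = FALSE)
  pr <- hyp$d / hyp$m
  if ((pr == 0 && n_alt > 0) || (pr == 1 && n_ref > 0)) {
    return(structure(list(chi2 = Inf, df = 1L, p = 0, hypothesis = hyp,
                          impossible = TRUE, expected = c(alt = N * pr, ref = N * (1 - pr))),
                     class = "gof_result"))
  }
  expected <- c(alt = N * pr, ref = N * (1 - pr))
  if (pr %in% c(0, 1)) {
    # boundary hypothesis consistent with the data: perfect fit
    res <- list(chi2 = 0, df = 1L, p = 1, hypothesis = hyp,
                impossible = FALSE, expected = expected)
    return(structure(res, class = "gof_result"))
  }
  # algebraically the Pearson statistic; this form is exactly symmetric
  # under (n_alt, n_ref, d) -> (n_ref, n_alt, m - d) in floating point
  chi2 <- (hyp$m * n_alt - N * hyp$d)^2 / (N * hyp$d * (hyp$m - hyp$d))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  res <- list(chi2 = chi2, df = 1L, p = p, hypothesis = hyp,
              impossible = FALSE, expected = expected)
  if (any(expected < 5)) {
    warning(sprintf("expected count below 5 (N = %g); chi-square approximation is rough", N),
            call. = FALSE)
    if (exact_if_small) {
      res$p_exact <- stats::binom.test(round(n_alt), round(N), p = pr)$p.value
    }
  }
  structure(res, class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("<gof_result> H: d=%d of m=%d (%s)  chi2=%.4f df=%d p=%.4g%s\n",
              x$hypothesis$d, x$hypothesis$m, x$hypothesis$label,
              x$chi2, x$df, x$p,
              if (isTRUE(x$impossible)) " [impossible]" else ""))
  invisible(x)
}

.dosage_loglik <- function(n_alt, n_ref, m) {
  d <- 0:m
  pr <- d / m
  ll <- numeric(m + 1L)
  for (i in seq_along(d)) {
    la <- if (n_alt == 0) 0 else n_alt * log(pr[i])
    lr <- if (n_ref == 0) 0 else n_ref * log(1 - pr[i])
    ll[i] <- la + lr
  }
  stats::setNames(ll, as.character(d))
}

#' Maximum-likelihood integer allele dosage from probe counts
#'
#' Evaluates the binomial log-likelihood
#' `n_alt * log(d/m) + n_ref * log(1 - d/m)` on the integer dosage grid
#' `d = 0..m` (boundary dosages are impossible, `-Inf`, unless the
#' corresponding count is zero) and reports the argmax together with the
#' implied allele ratio in lowest integer terms and the per-dosage
#' goodness-of-fit tests.
#'
#' @param n_alt,n_ref Classified deletion-/reference-allele read counts
#'   (ambiguous reads are excluded upstream).
#' @param m Total allele count at the locus.
#' @return A `dosage_inference`: `counts`, `m`, `loglik` (named vector over
#'   `d`), `d_hat` (integer vector; length > 1 only on an exact likelihood
#'   tie), `tie` flag, `implied_ratio` (string `"a:b"`, or `"ambiguous"` on a
#'   tie), and `gof` (list of `gof_result`, one per dosage).
#' @examples
#' ml_dosage(23, 12, m = 6)
#' @export
ml_dosage <- function(n_alt, n_ref, m) {
  m <- as.integer(m)
  n_alt <- as.numeric(n_alt); n_ref <- as.numeric(n_ref)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (n_alt + n_ref <= 0) stop("no classified reads (N = 0)", call. = FALSE)
  ll <- .dosage_loglik(n_alt, n_ref, m)
  top <- max(ll)
  d_hat <- as.integer(names(ll)[ll >= top - 1e-12])
  tie <- length(d_hat) > 1L
  ratio <- if (tie) "ambiguous" else {
    rt <- .ratio_lowest_terms(d_hat, m - d_hat)
    sprintf("%d:%d", rt[1], rt[2])
  }
  gof <- suppressWarnings(lapply(0:m, function(d) {
    chisq_gof(n_alt, n_ref, dosage_hypothesis(d, m), exact_if_small = FALSE)
  }))
  structure(list(counts = c(n_alt = n_alt, n_ref = n_ref), m = m,
                 loglik = ll, d_hat = d_hat, tie = tie,
                 implied_ratio = ratio, gof = gof),
            class = "dosage_inference")
}

#' @export
print.dosage_inference <- function(x, ...) {
  cat(sprintf("<dosage_inference> counts alt=%g ref=%g, m=%d\n",
              x$counts["n_alt"], x$counts["n_ref"], x$m))
  cat(sprintf("  d_hat = %s (implied ratio %s)%s\n",
              paste(x$d_hat, collapse = ","), x$implied_ratio,
              if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Rank candidate dosage configurations by likelihood
#'
#' @param n_alt,n_ref Observed counts.
#' @param configs List of [dosage_hypothesis()] (or `"d/m"` strings).
#' @return Data frame sorted by descending log-likelihood with columns
#'   `label`, `d`, `m`, `loglik`, `chi2`, `df`, `p`.
#' @export
rank_configurations <- function(n_alt, n_ref, configs) {
  if (length(configs) < 1L) stop("need >= 1 configuration", call. = FALSE)
  configs <- lapply(configs, function(h) if (is.character(h)) parse_dosage(h) else h)
  rows <- lapply(configs, function(h) {
    g <- suppressWarnings(chisq_gof(n_alt, n_ref, h, exact_if_small = FALSE))
    pr <- h$d / h$m
    la <- if (n_alt == 0) 0 else n_alt * log(pr)
    lr <- if (n_ref == 0) 0 else n_ref * log(1 - pr)
    data.frame(label = h$label, d = h$d, m = h$m, loglik = la + lr,
               chi2 = g$chi2, df = g$df, p = g$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$loglik), , drop = FALSE]
  rownames(out) <- NULL
  out
}
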