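# Statistical layer: Pearson correlations with effect-size categories,
# correlation maps over pooled or between-visit data, exploratory factor
# analysis (parallel analysis + principal-component extraction with
# Varimax rotation), and two-wave cross-lagged panel analysis.

#' Effect-size category of a correlation coefficient
#'
#' Bands on |r|: negligible (<= 0.3), weak (0.3, 0.5], moderate
#' (0.5, 0.7], strong (0.7, 0.9], very strong (> 0.9).
#'
#' @param r numeric vector of correlation coefficients in [-1, 1].
#' @return character vector of categories.
#' @export
strengthCategory <- function(r) {
  stopifnot3(all(abs(r[!is.na(r)]) <= 1 + 1e-12), "|r| must be <= 1")
  as.character(cut(abs(r), breaks = c(-Inf, 0.3, 0.5, 0.7, 0.9, Inf),
      labels = c("negligible", "weak", "moderate", "strong",
                 "very strong"), right = TRUE))
}

#' Pearson correlation with significance and effect-size category
#'
#' @param x,y numeric vectors of equal length.
#' @param missing "pairwise" drops incomplete pairs; "error" refuses
#'   missing values.
#' @return a [CorrelationResult-class].
#' @examples
#' pearsonCor(1:10, (1:10)^2)
#' @export
pearsonCor <- function(x, y, missing = c("pairwise", "error")) {
  missing <- match.arg(missing)
  stopifnot3(length(x) == length(y), "x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (missing == "error" && !all(ok))
    stop("missing values present", call. = FALSE)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot3(n >= 3, "need at least 3 complete pairs")
  stopifnot3(stats::var(x) > 0 && stats::var(y) > 0,
             "zero variance in x or y")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  new("CorrelationResult", r = r, n = as.integer(n), p = p,
      strength = strengthCategory(r))
}

# first-order partial correlation r(a, b | c); undefined when either
# marginal correlation with c is (numerically) perfect
partialCor <- function(rab, rac, rbc) {
  if (abs(rac) >= 1 - 1e-12 || abs(rbc) >= 1 - 1e-12) return(NA_real_)
  (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
}

#' Correlation map between SPECT and qCT variables
#'
#' Computes the full Pearson r matrix between two variable sets from a
#' tidy subject-visit table, either pooling all subject-visit rows
#' (cross-sectional) or correlating between-visit changes
#' (longitudinal). Cells with |r| > 0.7 are highlighted, following the
#' effect-size-first reporting appropriate for small samples.
#'
#' @param table tidy data.frame with columns \code{subject},
#'   \code{visit} (V0/V1/V2) and the variables.
#' @param spectVars,qctVars character vectors of column names (rows and
#'   columns of the map).
#' @param mode "cross_sectional_pooled", or one of "delta_v1_v0",
#'   "delta_v2_v1", "delta_v2_v0" for between-visit changes.
#' @return a [CorrelationMap-class].
#' @export
correlationMap <- function(table, spectVars, qctVars,
                           mode = c("cross_sectional_pooled",
                                    "delta_v1_v0", "delta_v2_v1",
                                    "delta_v2_v0")) {
  mode <- match.arg(mode)
  vars <- union(spectVars, qctVars)
  stopifnot3(all(vars %in% names(table)),
             paste("missing variables:",
                   paste(setdiff(vars, names(table)), collapse = ", ")))
  if (mode == "cross_sectional_pooled") {
    dat <- table[, vars, drop = FALSE]
  } else {
    vis <- switch(mode, delta_v1_v0 = c("V0", "V1"),
                  delta_v2_v1 = c("V1", "V2"), delta_v2_v0 = c("V0", "V2"))
    a <- table[table$visit == vis[1], c("subject", vars)]
    b <- table[table$visit == vis[2], c("subject", vars)]
    m <- merge(a, b, by = "subject", suffixes = c(".a", ".b"))
    dat <- as.data.frame(lapply(vars, function(v)
      m[[paste0(v, ".b")]] - m[[paste0(v, ".a")]]))
    names(dat) <- vars
    nBoth <- sum(stats::complete.cases(dat))
    stopifnot3(nBoth >= 3,
               "fewer than 3 subjects with complete data at both visits")
  }
  mk <- function() matrix(NA_real_, length(spectVars), length(qctVars),
                          dimnames = list(spectVars, qctVars))
  rM <- mk(); nM <- mk(); pM <- mk()
  sM <- matrix(NA_character_, length(spectVars), length(qctVars),
               dimnames = dimnames(rM))
  for (i in seq_along(spectVars)) for (j in seq_along(qctVars)) {
    res <- tryCatch(pearsonCor(dat[[spectVars[i]]], dat[[qctVars[j]]]),
                    error = function(e) NULL)
    if (!is.null(res)) {
      rM[i, j] <- res@r; nM[i, j] <- res@n; pM[i, j] <- res@p
      sM[i, j] <- res@strength
    }
  }
  new("CorrelationMap", r = rM, n = nM, p = pM, strength = sM,
      highlighted = !is.na(rM) & abs(rM) > 0.7, mode = mode)
}

#' Parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation matrix against
#' the chosen quantile of eigenvalues from random standard-normal
#' datasets of identical shape; the retained count is the length of the
#' leading run of observed eigenvalues exceeding their random
#' benchmarks.
#'
#' @param data numeric matrix or data.frame (observations x variables).
#' @param nReps number of random datasets (>= 1).
#' @param quantile benchmark quantile of the random eigenvalues
#'   (default 0.95).
#' @param seed integer RNG seed for the random datasets.
#' @return integer retained factor count, with attributes
#'   \code{"eigenvalues"} and \code{"thresholds"}.
#' @export
parallelAnalysis <- function(data, nReps = 500L, quantile = 0.95,
                             seed = 1L) {
  stopifnot3(nReps >= 1, "nReps must be >= 1")
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  stopifnot3(n > 2 && p >= 1, "need more observations")
  sds <- apply(data, 2, stats::sd)
  stopifnot3(all(sds > 0), "constant columns are not allowed")
  obs <- eigen(stats::cor(data), symmetric = TRUE,
               only.values = TRUE)$values
  null <- withPhantomSeed(as.integer(seed), {
    vapply(seq_len(nReps), function(i)
      eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
            symmetric = TRUE, only.values = TRUE)$values,
      numeric(p))
  })
  thr <- apply(matrix(null, nrow = p), 1, stats::quantile,
               probs = quantile, names = FALSE)
  k <- 0L
  while (k < p && obs[k + 1L] > thr[k + 1L]) k <- k + 1L
  structure(k, eigenvalues = obs, thresholds = thr)
}

#' Exploratory factor analysis: principal components + Varimax
#'
#' Extracts \code{nFactors} principal components of the correlation
#' matrix (loadings = eigenvectors scaled by the square roots of their
#' eigenvalues) and applies Varimax orthogonal rotation (identity for a
#' single factor). Variables whose absolute rotated loading exceeds the
#' threshold are the key variables of each factor.
#'
#' @param data numeric matrix or data.frame (observations x variables).
#' @param nFactors factors to extract (1..p).
#' @param loadingThreshold key-variable threshold on |loading|
#'   (default 0.6).
#' @return an [EFAResult-class].
#' @export
efaVarimax <- function(data, nFactors, loadingThreshold = 0.6) {
  data <- as.matrix(data)
  p <- ncol(data)
  stopifnot3(nFactors >= 1 && nFactors <= p,
             "nFactors must lie in 1..ncol(data)")
  stopifnot3(all(apply(data, 2, stats::sd) > 0),
             "constant columns are not allowed")
  R <- stats::cor(data)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors[, seq_len(nFactors), drop = FALSE] %*%
       diag(sqrt(pmax(e$values[seq_len(nFactors)], 0)), nFactors)
  rownames(L) <- colnames(data)
  rot <- diag(nFactors)
  if (nFactors > 1L) {
    vm <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
    L <- unclass(vm$loadings)
    rot <- vm$rotmat
  }
  # sign convention: dominant loading of each factor positive
  for (k in seq_len(nFactors)) {
    if (L[which.max(abs(L[, k])), k] < 0) {
      L[, k] <- -L[, k]; rot[, k] <- -rot[, k]
    }
  }
  colnames(L) <- paste0("F", seq_len(nFactors))
  key <- lapply(seq_len(nFactors), function(k)
    rownames(L)[abs(L[, k]) > loadingThreshold])
  names(key) <- colnames(L)
  new("EFAResult", nFactors = as.integer(nFactors), loadings = L,
      rotation = rot,
      varianceExplainedPct = 100 * sum(e$values[seq_len(nFactors)]) / p,
      keyVariables = key, loadingThreshold = loadingThreshold)
}

#' Two-wave cross-lagged panel analysis
#'
#' Computes the six correlations of the classic two-variable, two-wave
#' panel: synchronous r(x1,y1) and r(x2,y2); stability r(x1,x2) and
#' r(y1,y2); and the two cross-lagged partial correlations with the
#' same-variable stability partialled out, r(x1,y2 | y1) and
#' r(y1,x2 | x1). A cross-lagged path asymmetry (one partial
#' significantly greater than zero, the other not) supports a causal
#' direction. Tests are one-sided (greater than zero) against t with
#' n - 2 df (simple) or n - 3 df (partial). Assumption flags report
#' non-significant synchronous correlations (synchronicity) or a
#' significant difference between the two synchronous correlations
#' (stationarity, Fisher-z approximation).
#'
#' @param x1,x2 exposure variable at waves 1 and 2.
#' @param y1,y2 outcome variable at waves 1 and 2.
#' @param alpha one-sided type-I error rate for the verdicts.
#' @return a [CrossLaggedResult-class].
#' @examples
#' d <- makePanelDataset(100, crossLagEffect = 0.5, seed = 2)
#' crossLaggedPanel(d$x1, d$x2, d$y1, d$y2)
#' @export
crossLaggedPanel <- function(x1, x2, y1, y2, alpha = 0.05) {
  ok <- stats::complete.cases(x1, x2, y1, y2)
  x1 <- x1[ok]; x2 <- x2[ok]; y1 <- y1[ok]; y2 <- y2[ok]
  n <- length(x1)
  stopifnot3(n >= 4, "need at least 4 complete cases")
  for (v in list(x1, x2, y1, y2))
    stopifnot3(stats::var(v) > 0, "zero variance in a panel variable")
  r <- c(sync1 = stats::cor(x1, y1), sync2 = stats::cor(x2, y2),
         stab_x = stats::cor(x1, x2), stab_y = stats::cor(y1, y2),
         cross_xy = partialCor(stats::cor(x1, y2), stats::cor(x1, y1),
                               stats::cor(y1, y2)),
         cross_yx = partialCor(stats::cor(y1, x2), stats::cor(y1, x1),
                               stats::cor(x1, x2)))
  pOne <- function(rv, df) {
    if (is.na(rv)) return(NA_real_)
    if (rv >= 1) return(0)
    if (rv <= -1) return(1)
    stats::pt(rv * sqrt(df / (1 - rv^2)), df, lower.tail = FALSE)
  }
  p <- c(vapply(r[1:4], pOne, 0, df = n - 2),
         vapply(r[5:6], pOne, 0, df = n - 3))
  names(p) <- names(r)
  sig <- p < alpha
  flags <- character(0)
  if (any(is.na(r[5:6])))
    flags <- c(flags,
      "cross-lagged partials undefined (perfect stability or synchrony)")
  if (!all(sig[1:2], na.rm = TRUE))
    flags <- c(flags, "synchronicity: a synchronous correlation is not significant")
  z <- atanh(pmin(pmax(r[1:2], -1 + 1e-12), 1 - 1e-12))
  zstat <- abs(z[1] - z[2]) / sqrt(2 / (n - 3))
  if (2 * stats::pnorm(zstat, lower.tail = FALSE) < alpha)
    flags <- c(flags, "stationarity: synchronous correlations differ")
  new("CrossLaggedResult", r = r, p = p, significant = sig,
      alpha = alpha, n = as.integer(n), flags = flags)
}
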