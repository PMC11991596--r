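#' Discretize a continuous factor into strata
#'
#' Cuts a continuous layer into `L` strata by one of five break schemes:
#' `equal` (equal-width intervals), `quantile` (equal-count), `natural_breaks`
#' (variance-minimizing 1-D clustering, deterministic k-means seeded at the
#' quantile centers), `geometric` (geometrically growing interval widths) and
#' `std_dev` (breaks at mean plus multiples of the standard deviation).
#' Breaks are strictly monotone; every valid sample gets exactly one stratum.
#'
#' @param values numeric vector/matrix of the factor (NA = nodata).
#' @param method one of `"equal"`, `"quantile"`, `"natural_breaks"`,
#'   `"geometric"`, `"std_dev"`.
#' @param L number of strata (>= 2); must not exceed the distinct-value
#'   count.
#' @param name factor name used in error messages.
#' @return object of class `factor_layer`: integer `strata` (same shape as
#'   `values`, codes `1..L_effective`), `L`, `breaks`, `method`,
#'   `provenance`.
#' @export
discretize <- function(values, method = c("equal", "quantile",
                                          "natural_breaks", "geometric",
                                          "std_dev"),
                       L, name = "factor") {
  method <- match.arg(method)
  v <- as_values(values)
  shape <- dim(v)
  x <- as.vector(v)
  ok <- !is.na(x)
  xs <- x[ok]
  if (length(unique(xs)) < L)
    stop("factor ", name, ": only ", length(unique(xs)),
         " distinct values; cannot form L = ", L, " strata")
  rng <- range(xs)
  breaks <- switch(method,
    equal = seq(rng[1], rng[2], length.out = L + 1),
    quantile = stats::quantile(xs, probs = seq(0, 1, length.out = L + 1),
                               names = FALSE),
    natural_breaks = jenks_breaks(xs, L),
    geometric = {
      shift <- if (rng[1] <= 0) 1 - rng[1] else 0
      exp(seq(log(rng[1] + shift), log(rng[2] + shift),
              length.out = L + 1)) - shift
    },
    std_dev = {
      ctr <- mean(xs); s <- stats::sd(xs)
      inner <- ctr + s * seq(-(L - 1) / 2, (L - 1) / 2, length.out = L - 1)
      c(rng[1], inner, rng[2])
    })
  breaks[1] <- rng[1]; breaks[L + 1] <- rng[2]
  breaks <- unique(sort(breaks))
  codes <- as.integer(cut(x, breaks = breaks, include.lowest = TRUE))
  out <- if (is.null(shape)) codes else array(codes, shape)
  structure(list(strata = out, L = length(breaks) - 1L, breaks = breaks,
                 method = method, name = name,
                 provenance = sprintf("discretized(%s, L=%d)", method,
                                      length(breaks) - 1L)),
            class = "factor_layer")
}

# Deterministic 1-D variance-minimizing breaks: k-means initialized at the
# type-7 quantile centers (the standard fast Jenks approximation).
jenks_breaks <- function(x, L) {
  ctrs <- stats::quantile(x, probs = (seq_len(L) - 0.5) / L, names = FALSE)
  ctrs <- unique(ctrs)
  if (length(ctrs) < L) {
    # heavy ties: fall back to distinct-value spread centers
    ux <- sort(unique(x))
    ctrs <- ux[round(seq(1, length(ux), length.out = L))]
  }
  # Lloyd iterations are deterministic given the seeded centers; a rare
  # non-convergence note still yields a valid (monotone, sorted) break set
  km <- suppressWarnings(
    stats::kmeans(x, centers = matrix(sort(ctrs), ncol = 1),
                  iter.max = 100, algorithm = "Lloyd"))
  ord <- order(km$centers)
  hi <- vapply(ord, function(cl) max(x[km$cluster == cl]), numeric(1))
  lo <- vapply(ord, function(cl) min(x[km$cluster == cl]), numeric(1))
  c(min(x), (hi[-L] + lo[-1]) / 2, max(x))
}

#' Wrap a native categorical layer as a factor layer
#'
#' @param values integer-coded matrix/vector (codes need not be contiguous).
#' @param name factor name.
#' @return a `factor_layer` with `provenance = "native_categorical"`.
#' @export
as_factor_layer <- function(values, name = "factor") {
  v <- as_values(values)
  codes <- as.integer(factor(as.vector(v)))
  out <- if (is.null(dim(v))) codes else array(codes, dim(v))
  structure(list(strata = out, L = max(codes, na.rm = TRUE), breaks = NULL,
                 method = "native", name = name,
                 provenance = "native_categorical"),
            class = "factor_layer")
}

strata_vector <- function(strata) {
  if (inherits(strata, "factor_layer")) as.vector(strata$strata)
  else as.integer(as.vector(as_values(strata)))
}

#' GeoDetector q-statistic of a stratified factor
#'
#' Explanatory power of a stratification for the spatial variance of a
#' response: `q = 1 - sum_h(N_h * sigma_h^2) / (N * sigma^2)` with
#' population variances weighted by stratum sizes — the share of the
#' response variance accounted for by between-strata differences,
#' `q` in `[0, 1]`. Significance comes from the noncentral-F transform
#' `F = (N - L) / (L - 1) * q / (1 - q)` with noncentrality
#' `lambda = (sum_h ybar_h^2 - (sum_h sqrt(N_h) ybar_h)^2 / N) / sigma^2`,
#' the standard GeoDetector test; [permutation_q_test()] offers a
#' distribution-free cross-check.
#'
#' @param y numeric response samples.
#' @param strata a `factor_layer` or integer stratum codes matching `y`.
#' @return object of class `q_result`: `q`, `p`, `L`, `N`, per-stratum
#'   `N_h`, `mean_h`, `var_h` (population), global `var_total`, and the
#'   factor's discretization metadata when available.
#' @export
factor_q <- function(y, strata) {
  s <- strata_vector(strata)
  y <- as.vector(as_values(y))
  if (length(y) != length(s)) stop("response and strata lengths differ")
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  N <- length(y)
  nh <- tapply(y, s, length)
  L <- length(nh)
  if (L < 2) stop("need at least 2 non-empty strata, got ", L)
  if (N < L) stop("fewer samples than strata")
  varp <- function(v) mean((v - mean(v))^2)
  var_total <- varp(y)
  if (var_total == 0)
    return(structure(list(q = NA_real_, p = NA_real_, L = L, N = N,
                          reason = "zero total variance"),
                     class = "q_result"))
  vh <- tapply(y, s, varp)
  mh <- tapply(y, s, mean)
  q <- 1 - sum(nh * vh) / (N * var_total)
  q <- min(max(q, 0), 1)
  if (q < 1) {
    Fst <- (N - L) / (L - 1) * q / (1 - q)
    lambda <- (sum(mh^2) - (sum(sqrt(nh) * mh))^2 / N) / var_total
    # tail probabilities far below machine precision trigger a harmless
    # pnbeta accuracy note; the value itself is what we report
    p <- suppressWarnings(
      stats::pf(Fst, L - 1, N - L, ncp = lambda, lower.tail = FALSE))
  } else p <- 0
  meta <- if (inherits(strata, "factor_layer"))
    strata[c("method", "breaks", "name", "provenance")] else NULL
  structure(list(q = q, p = p, L = L, N = N,
                 N_h = as.integer(nh), mean_h = as.numeric(mh),
                 var_h = as.numeric(vh), var_total = var_total,
                 discretization = meta),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("q = %.4f (p = %.3g), L = %d strata, N = %d\n",
              x$q, x$p, x$L, x$N))
  invisible(x)
}

#' Permutation test for the q-statistic
#'
#' Seeded permutation null: shuffles the response over the samples
#' `n_perm` times and reports the fraction of permuted q-values at or above
#' the observed one (add-one estimator).
#'
#' @param y response samples.
#' @param strata `factor_layer` or codes.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with observed `q` and permutation `p`.
#' @export
permutation_q_test <- function(y, strata, n_perm = 999, seed = 1L) {
  s <- strata_vector(strata)
  y <- as.vector(as_values(y))
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  obs <- factor_q(y, s)$q
  perm <- withr::with_seed(as.integer(seed),
    vapply(seq_len(n_perm),
           function(i) factor_q(sample(y), s)$q, numeric(1)))
  list(q = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Optimal-parameter discretization of a continuous factor
#'
#' Searches every (break scheme, stratum count) combination, keeps only
#' candidates whose smallest stratum holds at least `min_stratum_size`
#' samples, and returns the stratification maximizing q. Ties go to the
#' smaller L, then to the earlier method in `methods`. The full search table
#' is retained for reporting.
#'
#' @param values continuous factor layer.
#' @param y response samples aligned with `values`.
#' @param methods break schemes to search (default all five).
#' @param L_range candidate stratum counts (default `3:10`).
#' @param min_stratum_size minimum admissible stratum size (default 2).
#' @param name factor name.
#' @return list of class `opgd_result`: `factor` (best `factor_layer`),
#'   `q_result`, and `search` (data.frame of method, L, q, admissible).
#' @export
optimize_discretization <- function(values, y,
                                    methods = c("equal", "quantile",
                                                "natural_breaks", "geometric",
                                                "std_dev"),
                                    L_range = 3:10, min_stratum_size = 2,
                                    name = "factor") {
  # candidates ordered by (L, method order); a strict comparison then makes
  # ties resolve to the smallest L and the earlier method
  grid <- expand.grid(method = methods, L = sort(L_range),
                      stringsAsFactors = FALSE)
  search <- list()
  best <- NULL; best_q <- -Inf
  for (k in seq_len(nrow(grid))) {
    m <- grid$method[k]; L <- grid$L[k]
    fl <- tryCatch(discretize(values, m, L, name = name),
                   error = function(e) NULL)
    row <- data.frame(method = m, L = L, q = NA_real_,
                      L_effective = NA_integer_)
    admissible <- FALSE
    if (!is.null(fl)) {
      qa <- tryCatch(factor_q(y, fl), error = function(e) NULL)
      if (!is.null(qa) && !is.na(qa$q) && min(qa$N_h) >= min_stratum_size) {
        admissible <- TRUE
        row$q <- qa$q; row$L_effective <- fl$L
        if (qa$q > best_q + 1e-12) {
          best <- list(factor = fl, q_result = qa); best_q <- qa$q
        }
      }
    }
    row$admissible <- admissible
    search[[k]] <- row
  }
  search <- do.call(rbind, search)
  if (is.null(best))
    stop("factor ", name, ": no admissible (method, L) combination")
  structure(c(best, list(search = search)), class = "opgd_result")
}

interaction_type_levels <- c("nonlinear_enhancement", "linear_enhancement",
                             "independence", "linear_weakening",
                             "nonlinear_weakening")

#' Interaction type from a (q1, q2, q12) triple
#'
#' The comparison rules behind the interaction detector, applied to
#' ready-made q-values: additive within `tol` -> independence;
#' `q12 > q1 + q2` -> nonlinear enhancement; above both singles (bivariate)
#' -> linear enhancement; between the singles (univariate) -> linear
#' weakening; below both -> nonlinear weakening. Note that on complete
#' samples without stratum merging `q12 >= max(q1, q2)` always holds (the
#' cross-classification refines both factors), so the weakening types can
#' only arise from merged or degraded stratifications.
#'
#' @param q1,q2 single-factor q-values.
#' @param q12 q-value of the cross-classification.
#' @param tol additivity tolerance for the independence call.
#' @return one of the five interaction type labels.
#' @export
classify_interaction <- function(q1, q2, q12, tol = 1e-6) {
  if (abs(q12 - (q1 + q2)) < tol) "independence"
  else if (q12 > q1 + q2) "nonlinear_enhancement"
  else if (q12 > max(q1, q2)) "linear_enhancement"
  else if (q12 >= min(q1, q2)) "linear_weakening"
  else "nonlinear_weakening"
}

#' Interaction detector for two factors
#'
#' Computes q for each factor alone and for their cross-classification (each
#' distinct code pair is a stratum) and classifies the interaction:
#' `q12 > q1 + q2` nonlinear enhancement; `max(q1, q2) < q12 <= q1 + q2`
#' linear (bivariate) enhancement; `q12 = q1 + q2` (within `tol`)
#' independence; `min <= q12 <= max` linear (univariate) weakening;
#' `q12 < min(q1, q2)` nonlinear weakening. Cross strata smaller than
#' `min_stratum_size` are merged into the stratum with the nearest response
#' mean (merges counted in the result).
#'
#' @param y response samples.
#' @param f1,f2 `factor_layer`s (or code vectors) on the same samples.
#' @param min_stratum_size minimum cross-stratum size before merging.
#' @param tol additivity tolerance for the independence call.
#' @return object of class `interaction_result`: `q1`, `q2`, `q12`, `type`,
#'   `n_merged`.
#' @export
interaction_detect <- function(y, f1, f2, min_stratum_size = 2, tol = 1e-6) {
  y <- as.vector(as_values(y))
  s1 <- strata_vector(f1); s2 <- strata_vector(f2)
  ok <- !is.na(y) & !is.na(s1) & !is.na(s2)
  y <- y[ok]; s1 <- s1[ok]; s2 <- s2[ok]
  q1 <- factor_q(y, s1)$q
  q2 <- factor_q(y, s2)$q
  cross <- as.integer(factor(paste(s1, s2)))
  n_merged <- 0L
  repeat {
    nh <- table(cross)
    small <- names(nh)[nh < min_stratum_size]
    if (!length(small) || length(nh) <= 2) break
    code <- as.integer(small[1])
    mh <- tapply(y, cross, mean)
    others <- setdiff(as.integer(names(mh)), code)
    tgt <- others[which.min(abs(mh[as.character(others)] -
                                  mh[as.character(code)]))]
    cross[cross == code] <- tgt
    n_merged <- n_merged + 1L
  }
  cross <- as.integer(factor(cross))
  q12 <- factor_q(y, cross)$q
  structure(list(q1 = q1, q2 = q2, q12 = q12,
                 type = classify_interaction(q1, q2, q12, tol),
                 n_merged = n_merged),
            class = "interaction_result")
}

#' Risk detector: per-stratum response means and the optimal range
#'
#' Reports the mean response of every stratum, identifies the optimal
#' (maximum-mean) and minimal stratum, and tests all stratum pairs with
#' Welch t-tests at `alpha`. Strata of size 1 keep their mean but are
#' excluded from the t-tests.
#'
#' @param y response samples.
#' @param strata `factor_layer` or codes (>= 2 strata).
#' @param labels optional character labels per stratum code (range or type
#'   names).
#' @param alpha significance level for pairwise differences.
#' @return object of class `risk_result`: `stratum_means` (named), `N_h`,
#'   `optimal_stratum`, `optimal_label`, `minimal_stratum`, `minimal_label`,
#'   `pairwise_significant` (logical matrix), `pairwise_p`.
#' @export
risk_detect <- function(y, strata, labels = NULL, alpha = 0.05) {
  s <- strata_vector(strata)
  y <- as.vector(as_values(y))
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  codes <- sort(unique(s))
  if (length(codes) < 2) stop("need at least 2 strata")
  if (is.null(labels)) {
    labels <- if (inherits(strata, "factor_layer") &&
                  !is.null(strata$breaks))
      sprintf("[%.4g, %.4g]", strata$breaks[codes],
              strata$breaks[codes + 1])
    else as.character(codes)
  }
  mh <- vapply(codes, function(k) mean(y[s == k]), numeric(1))
  nh <- vapply(codes, function(k) sum(s == k), numeric(1))
  names(mh) <- labels
  K <- length(codes)
  pw_p <- matrix(NA_real_, K, K, dimnames = list(labels, labels))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ya <- y[s == codes[a]]; yb <- y[s == codes[b]]
    if (length(ya) >= 2 && length(yb) >= 2 &&
        (stats::sd(ya) > 0 || stats::sd(yb) > 0)) {
      pw_p[a, b] <- pw_p[b, a] <- stats::t.test(ya, yb)$p.value
    }
  }
  opt <- which.max(mh); mn <- which.min(mh)
  structure(list(stratum_means = mh, N_h = nh,
                 optimal_stratum = codes[opt], optimal_label = labels[opt],
                 minimal_stratum = codes[mn], minimal_label = labels[mn],
                 pairwise_p = pw_p,
                 pairwise_significant = !is.na(pw_p) & pw_p < alpha,
                 alpha = alpha),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat("risk detector: optimal stratum", x$optimal_label,
      sprintf("(mean %.2f)", max(x$stratum_means)), "\n")
  invisible(x)
}
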