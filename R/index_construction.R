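# Index construction: orientation, Rankit standardisation, equal-weight
# domain scores, exponential rank transformation, the overall index and
# deciles, and correlation diagnostics.
#
# Polarity convention used throughout: after orientation, LARGER values mean
# LESS healthy; rank 1 / rank fraction R = 1/N / decile 1 is the most
# health-promoting zone, and the transformed scores X and the overall index
# increase with unhealthiness. The exponential transform deliberately puts
# its weight on the worst-ranked zones, so one very poor domain cannot be
# cancelled out by two good ones.

#' Orient raw indicator values
#'
#' `flip` negates (used for the retail distances and green-space area, whose
#' larger raw values are healthier); `keep` leaves values unchanged. After
#' orientation a larger value always means less healthy.
#'
#' @param values numeric vector of raw per-zone values.
#' @param orientation `"flip"` or `"keep"`.
#' @return oriented numeric vector.
#' @export
orient_values <- function(values, orientation = c("keep", "flip")) {
  orientation <- match.arg(orientation)
  if (orientation == "flip") -values else values
}

#' Rankit standardisation
#'
#' Rank-based inverse normal transform with the Rankit plotting position:
#' `qnorm((r - 0.5) / n)` where `r` is the ascending rank (average ranks for
#' ties).
#'
#' @param values numeric vector (finite).
#' @return standard-normal scores, same length.
#' @examples
#' rankit(c(3, 1, 2)) # qnorm(c(5, 1, 3) / 6)
#' @export
rankit <- function(values) {
  if (anyNA(values) || any(!is.finite(values))) {
    stop(sprintf("non-finite value at position %s",
                 paste(which(!is.finite(values)), collapse = ", ")))
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 0.5) / n)
}

#' Equal-weight domain scores from standardised indicators
#'
#' Weighted mean across a domain's indicator columns; the default weights are
#' equal (1/5 for retail and health, 1/4 for physical).
#'
#' @param scores numeric matrix (zones x indicators of one domain).
#' @param weights optional weight vector, normalised to sum to 1.
#' @return numeric vector of per-zone standardised domain scores.
#' @export
domain_score <- function(scores, weights = NULL) {
  scores <- as.matrix(scores)
  if (is.null(weights)) weights <- rep(1, ncol(scores))
  stopifnot(length(weights) == ncol(scores), all(weights >= 0), sum(weights) > 0)
  drop(scores %*% (weights / sum(weights)))
}

#' Exponential rank transformation
#'
#' `X = -23 * ln(1 - R * (1 - exp(-100/23)))` maps the rank fraction
#' `R = rank / N` in (0, 1] onto (0, 100], strictly increasing, with
#' `X(1) = 100` exactly. This is the transformation of the 2015 English
#' Index of Multiple Deprivation; it emphasises the worst-ranked zones and
#' thereby reduces cancellation between domains.
#'
#' @param R numeric vector of rank fractions in (0, 1].
#' @return transformed scores in (0, 100].
#' @examples
#' exp_transform(1)    # exactly 100
#' exp_transform(0.5)  # ~15.647
#' @export
exp_transform <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0) || any(R > 1)) {
    stop("rank fraction R must lie in (0, 1]")
  }
  -23 * log(1 - R * (1 - exp(-100 / 23)))
}

# Ordinal ascending ranks with deterministic tie-break by zone_code, so rank
# fractions are distinct and deciles exactly partition the zones.
ordinal_rank <- function(values, zone_code) {
  ord <- order(values, zone_code)
  r <- integer(length(values))
  r[ord] <- seq_along(values)
  r
}

# decile from ordinal rank: each decile holds floor(N/10) or ceiling(N/10)
rank_decile <- function(r, n) as.integer(floor((r - 1) * 10 / n) + 1L)

#' Overall index from the three domain scores
#'
#' Ranks each zone's mean of the three exponential-transformed domain scores
#' (equal weights by default), with rank 1 = lowest score = most
#' health-promoting, and assigns deciles by rank (decile 1 = best tenth).
#'
#' @param domains data frame with `zone_code` and columns `retail_X`,
#'   `health_X`, `physical_X`.
#' @param weights optional length-3 domain weight vector.
#' @return data frame `zone_code`, `index_score`, `index_rank`, `index_decile`.
#' @export
build_index <- function(domains, weights = NULL) {
  need <- c("zone_code", "retail_X", "health_X", "physical_X")
  miss <- setdiff(need, names(domains))
  if (length(miss)) stop(sprintf("missing domain column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(is.na(domains$retail_X) | is.na(domains$health_X) | is.na(domains$physical_X))
  if (length(bad)) {
    stop(sprintf("missing domain score for zone(s): %s",
                 paste(domains$zone_code[bad], collapse = ", ")))
  }
  xm <- as.matrix(domains[, c("retail_X", "health_X", "physical_X")])
  score <- domain_score(xm, weights)
  n <- nrow(domains)
  r <- ordinal_rank(score, domains$zone_code)
  data.frame(zone_code = domains$zone_code,
             index_score = score,
             index_rank = r,
             index_decile = rank_decile(r, n),
             stringsAsFactors = FALSE)
}

#' Equal weights for indicators and domains
#'
#' The published index uses equal weights throughout; this helper makes the
#' implied 1/5, 1/5, 1/4 indicator weights and 1/3 domain weights explicit
#' and user-replaceable.
#'
#' @return list with per-domain indicator weight vectors and `domain` weights.
#' @export
ahah_weights <- function() {
  specs <- indicator_specs()
  w <- lapply(split(specs$name, specs$domain), function(nms) {
    stats::setNames(rep(1 / length(nms), length(nms)), nms)
  })
  list(retail = w$retail, health = w$health, physical = w$physical,
       domain = c(retail = 1, health = 1, physical = 1) / 3)
}

#' Construct the composite access index from an indicator table
#'
#' The full published construction: orient each indicator so larger = less
#' healthy, Rankit-standardise, average with equal weights into three domain
#' scores, rank each domain (rank 1 = healthiest, ties broken by zone code),
#' scale ranks to fractions `R = rank/N`, apply the exponential rank
#' transformation, average the three transformed domain scores with equal
#' weights into the overall index, and rank/decile the result.
#'
#' @param table `indicator_table` (or data frame with `zone_code` and the 14
#'   indicator columns of [indicator_specs()]).
#' @param weights weight structure as produced by [ahah_weights()].
#' @return object of class `ahah` with elements `components`, `rankit_scores`,
#'   `domains`, `index`, `weights`, `n`.
#' @export
ahah <- function(table, weights = ahah_weights()) {
  specs <- indicator_specs()
  miss <- setdiff(specs$name, names(table))
  if (length(miss)) {
    stop(sprintf("indicator table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  n <- nrow(table)
  if (n < 1L) stop("indicator table has no rows")
  zone_code <- as.character(table$zone_code)

  oriented <- sapply(specs$name, function(nm) {
    orient_values(table[[nm]], specs$orientation[specs$name == nm])
  })
  oriented <- matrix(oriented, nrow = n,
                     dimnames = list(zone_code, specs$name))
  rk <- apply(oriented, 2L, rankit)
  rk <- matrix(rk, nrow = n, dimnames = dimnames(oriented))

  domains <- data.frame(zone_code = zone_code, stringsAsFactors = FALSE)
  for (dom in c("retail", "health", "physical")) {
    cols <- specs$name[specs$domain == dom]
    std <- domain_score(rk[, cols, drop = FALSE], weights[[dom]][cols])
    r <- ordinal_rank(std, zone_code)
    R <- r / n
    domains[[paste0(dom, "_std")]] <- std
    domains[[paste0(dom, "_rank")]] <- r
    domains[[paste0(dom, "_R")]] <- R
    domains[[paste0(dom, "_X")]] <- exp_transform(R)
    domains[[paste0(dom, "_decile")]] <- rank_decile(r, n)
  }
  index <- build_index(domains, weights$domain)

  structure(list(components = table, rankit_scores = rk, domains = domains,
                 index = index, weights = weights, n = n),
            class = "ahah")
}

#' @export
print.ahah <- function(x, ...) {
  cat(sprintf("Access to Healthy Assets and Hazards index: %d zones\n", x$n))
  cat("  polarity: higher score / decile = less healthy; rank 1 = healthiest\n")
  cat(sprintf("  index score: min %.3f, median %.3f, max %.3f\n",
              min(x$index$index_score), stats::median(x$index$index_score),
              max(x$index$index_score)))
  invisible(x)
}

#' @export
summary.ahah <- function(object, ...) {
  idx <- object$index
  dom <- object$domains
  out <- list(
    n = object$n,
    index = summary(idx$index_score),
    domain_means = c(retail = mean(dom$retail_X), health = mean(dom$health_X),
                     physical = mean(dom$physical_X)),
    decile_counts = table(idx$index_decile))
  class(out) <- "summary.ahah"
  out
}

#' @export
print.summary.ahah <- function(x, ...) {
  cat(sprintf("AHAH index over %d zones (higher = less healthy)\n", x$n))
  cat("index score:\n"); print(x$index)
  cat("mean domain scores (X):\n"); print(round(x$domain_means, 3))
  cat("zones per decile (1 = healthiest):\n"); print(x$decile_counts)
  invisible(x)
}

#' @export
as.data.frame.ahah <- function(x, ...) {
  specs <- indicator_specs()
  out <- merge(x$index,
               x$domains[, c("zone_code", "retail_X", "retail_decile",
                             "health_X", "health_decile",
                             "physical_X", "physical_decile")],
               by = "zone_code", sort = TRUE)
  comp <- as.data.frame(x$components)
  for (i in seq_len(nrow(specs))) {
    nm <- specs$name[i]
    oriented <- orient_values(comp[[nm]], specs$orientation[i])
    r <- ordinal_rank(oriented, comp$zone_code)
    comp[[paste0(nm, "_decile")]] <- rank_decile(r, x$n)
  }
  merge(out, comp, by = "zone_code", sort = TRUE)
}

#' Plot an index
#'
#' With a region attached (see [run_pipeline()]) draws zone centroids coloured
#' by index decile; otherwise a histogram of index scores.
#'
#' @param x `ahah` object.
#' @param region optional `synthetic_region` for a spatial plot.
#' @param ... passed to the underlying plot call.
#' @export
plot.ahah <- function(x, region = attr(x, "region"), ...) {
  if (!is.null(region)) {
    zt <- zone_table(region)
    m <- merge(zt, x$index, by = "zone_code")
    pal <- grDevices::hcl.colors(10, "RdYlBu", rev = TRUE)
    graphics::plot(m$centroid_x, m$centroid_y, pch = 15, cex = 2,
                   col = pal[m$index_decile],
                   xlab = "easting (m)", ylab = "northing (m)",
                   main = "Index decile (blue = healthiest)", asp = 1, ...)
  } else {
    graphics::hist(x$index$index_score, breaks = 20,
                   xlab = "index score (higher = less healthy)",
                   main = "AHAH index", ...)
  }
  invisible(x)
}

#' Correlation diagnostics of the indicator table
#'
#' Pairwise correlations of the 14 raw indicators plus correlations of each
#' domain score and the overall index, mirroring the published usage notes
#' (accessibility measures correlate positively with one another because
#' services co-cluster in urban cores). Zero-variance columns yield `NA`
#' entries rather than propagating NaN.
#'
#' @param table `indicator_table`.
#' @param method `"pearson"` (product-moment) or `"spearman"` (rank).
#' @param fit optional `ahah` object; adds domain-vs-index correlations.
#' @return list of class `ahah_diagnostics` with `indicator_cor` (14 x 14
#'   matrix) and optionally `domain_index_cor`.
#' @export
ahah_diagnostics <- function(table, method = c("pearson", "spearman"), fit = NULL) {
  method <- match.arg(method)
  specs <- indicator_specs()
  m <- as.matrix(as.data.frame(table)[, specs$name])
  sds <- apply(m, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(m, method = method))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- ifelse(sds == 0, NA_real_, 1)
  out <- list(indicator_cor = cm, method = method)
  if (!is.null(fit)) {
    dm <- cbind(retail = fit$domains$retail_X, health = fit$domains$health_X,
                physical = fit$domains$physical_X)
    out$domain_index_cor <- suppressWarnings(
      stats::cor(dm, fit$index$index_score, method = method))[, 1L]
  }
  class(out) <- "ahah_diagnostics"
  out
}

#' @export
print.ahah_diagnostics <- function(x, ...) {
  cat(sprintf("indicator correlations (%s):\n", x$method))
  print(round(x$indicator_cor, 2))
  if (!is.null(x$domain_index_cor)) {
    cat("domain X vs index score:\n")
    print(round(x$domain_index_cor, 3))
  }
  invisible(x)
}
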