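#' Build a 2x2 contingency table of carriage vs phenotype
#'
#' Cell layout follows the clone-screen convention: `a` carriers that do not
#' fruit, `b` non-carriers that do not fruit, `c` carriers that fruit, `d`
#' non-carriers that fruit.
#'
#' @param a,b,c,d non-negative counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d, total = a + b + c + d),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("nonfruiting", "fruiting"),
                              c("carrier", "noncarrier")))
  print(m)
  invisible(x)
}

#' Tally clone-screen records into contingency tables
#'
#' Partitions the screened clones exhaustively into the four cells of
#' [contingency_table()], grouped by line, by variant, or by gene region
#' (via `region_map`). A clone screened for several variants of the same
#' group counts once per group, as a carrier when it carries any of them.
#'
#' @param records clone-screen data frame (`line`, `clone_id`, `variant_id`,
#'   `fruits`, `carries`).
#' @param group_by `"line"`, `"variant"` or `"region"`.
#' @param region_map named character vector variant_id -> region (required
#'   for `group_by = "region"`).
#' @return Named list of `contingency_table`s.
#' @export
build_contingency <- function(records, group_by = c("line", "variant", "region"),
                              region_map = NULL) {
  group_by <- match.arg(group_by)
  if (nrow(records) == 0) return(list())
  group <- switch(group_by,
    line = as.character(records$line),
    variant = records$variant_id,
    region = {
      if (is.null(region_map)) stop("region_map required for group_by='region'")
      miss <- setdiff(unique(records$variant_id), names(region_map))
      if (length(miss) > 0) {
        stop("variant(s) without region assignment: ",
             paste(miss, collapse = ", "))
      }
      unname(region_map[records$variant_id])
    })
  out <- lapply(split(records, group), function(sub) {
    clone <- paste(sub$line, sub$clone_id)
    carries <- tapply(sub$carries, clone, max)
    fruits <- tapply(sub$fruits, clone, max)
    contingency_table(a = sum(carries == 1 & fruits == 0),
                      b = sum(carries == 0 & fruits == 0),
                      c = sum(carries == 1 & fruits == 1),
                      d = sum(carries == 0 & fruits == 1))
  })
  out
}

#' Fisher's exact test for a 2x2 table, from first principles
#'
#' Two-sided p-value by the minimum-likelihood method: with both margins
#' fixed, the hypergeometric probability of every admissible table is
#' computed in log space via cumulative log factorials, and the p-value is
#' the sum of probabilities not exceeding that of the observed table (with
#' a relative tolerance of 1e-7 for floating-point ties). This is the
#' conventional two-sided definition used by mainstream statistics
#' software.
#'
#' @param t a [contingency_table()] with total >= 1.
#' @return p-value in (0, 1].
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$total < 1) stop("empty table")
  r1 <- t$a + t$b; c1 <- t$a + t$c; n <- t$total
  lchoose_ <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  a_min <- max(0, r1 + c1 - n)
  a_max <- min(r1, c1)
  a_all <- a_min:a_max
  logp <- lchoose_(c1, a_all) + lchoose_(n - c1, r1 - a_all) - lchoose_(n, r1)
  p_obs <- logp[a_all == t$a]
  # minimum-likelihood two-sided sum with relative tie tolerance
  include <- exp(logp) <= exp(p_obs) * (1 + 1e-7)
  min(1, sum(exp(logp[include])))
}

#' Odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`; `Inf` when `b c = 0` with `a d > 0`; `NaN` (explicit
#' undefined marker) when both products are zero.
#'
#' @param t a [contingency_table()].
#' @return Numeric scalar, possibly `Inf` or `NaN`.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_table"), t$total >= 1)
  num <- t$a * t$d
  den <- t$b * t$c
  if (den == 0) {
    if (num == 0) NaN else Inf
  } else {
    num / den
  }
}

#' Clone-screen association report
#'
#' Per line: contingency table and two-sided Fisher p. Per region
#' (pooled over lines): table, Fisher p, odds ratio, and carrier
#' percentages among nonfruiters `a/(a+b)` and among fruiters `c/(c+d)`
#' (NA, reported as no data, when a phenotype class is empty).
#'
#' @param records clone-screen records.
#' @param region_map named character vector variant_id -> region.
#' @return A list with data frames `per_line` and `per_region`, plus the
#'   underlying tables.
#' @export
screen_report <- function(records, region_map) {
  by_line <- build_contingency(records, "line")
  per_line <- do.call(rbind, lapply(names(by_line), function(l) {
    t <- by_line[[l]]
    data.frame(line = l, a = t$a, b = t$b, c = t$c, d = t$d,
               p_value = fisher_exact(t))
  }))
  by_region <- build_contingency(records, "region", region_map = region_map)
  per_region <- do.call(rbind, lapply(names(by_region), function(r) {
    t <- by_region[[r]]
    data.frame(region = r, a = t$a, b = t$b, c = t$c, d = t$d,
               p_value = fisher_exact(t),
               odds_ratio = odds_ratio(t),
               pct_carrier_nonfruiting = carrier_pct(t$a, t$b),
               pct_carrier_fruiting = carrier_pct(t$c, t$d))
  }))
  list(per_line = per_line, per_region = per_region,
       tables = list(line = by_line, region = by_region))
}

carrier_pct <- function(x, y) {
  if (x + y == 0) NA_real_ else 100 * x / (x + y)
}

#' Proportion with exact (Clopper-Pearson) binomial confidence interval
#'
#' The interval endpoints are found by inverting the exact binomial tail
#' probabilities numerically: the lower bound is the `p` at which observing
#' `k` or more successes has probability `(1-conf)/2`, the upper bound the
#' `p` at which observing `k` or fewer has that probability. Degenerate
#' bounds (k = 0 or k = n) are 0 and 1.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param conf confidence level.
#' @return List with `proportion`, `lower`, `upper`, `conf`.
#' @export
prevalence <- function(k, n, conf = 0.95) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(k >= 0, k <= n, conf > 0, conf < 1)
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p,
                                             lower.tail = FALSE) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  list(proportion = k / n, lower = lower, upper = upper, conf = conf)
}
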