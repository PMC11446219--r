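#' Exact Wilcoxon-Mann-Whitney genotype comparison
#'
#' Two-sided exact rank-sum test between two samples (typically one value
#' per animal for each genotype). Without ties the exact distribution of
#' the Mann-Whitney statistic is used; with ties an exact permutation test
#' enumerates all assignments of the pooled values to the two groups
#' (feasible at home-cage sample sizes), falling back to the normal
#' approximation only when enumeration would be too large. The
#' standardized statistic Z is reported alongside for comparability with
#' published tables.
#'
#' @param x,y Numeric samples for the two groups.
#' @param max_enumerate Largest number of group assignments enumerated for
#'   the tie-handling permutation test (default 2e5).
#' @return A tibble with `W` (Mann-Whitney U for the first sample), `z`,
#'   `p`, `n1`, `n2`, `method`, `flag` (`"degenerate"` when the pooled
#'   sample is constant, else `"ok"`).
#' @export
#' @examples
#' genotype_compare(c(1, 2, 3), c(10, 11, 12)) # p = 0.1 exactly
genotype_compare <- function(x, y, max_enumerate = 2e5) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  pooled <- c(x, y)
  ranks <- rank(pooled)
  W <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  sigma2 <- n1 * n2 / 12 *
    (n1 + n2 + 1 - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (length(unique(pooled)) == 1) {
    return(tibble::tibble(W = W, z = 0, p = 1, n1 = n1, n2 = n2,
                          method = "degenerate", flag = "degenerate"))
  }
  has_ties <- any(duplicated(pooled))
  if (!has_ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else if (choose(n1 + n2, n1) <= max_enumerate) {
    splits <- utils::combn(n1 + n2, n1)
    obs_dev <- abs(W - mu)
    stat <- apply(splits, 2, function(idx) {
      sum(ranks[idx]) - n1 * (n1 + 1) / 2
    })
    p <- mean(abs(stat - mu) >= obs_dev - 1e-12)
    method <- "exact-permutation"
  } else {
    cc <- sign(W - mu) * 0.5
    p <- 2 * stats::pnorm(-abs((W - mu - cc) / sqrt(sigma2)))
    p <- min(1, p)
    method <- "normal-approximation"
  }
  tibble::tibble(W = W, z = z, p = p, n1 = n1, n2 = n2,
                 method = method, flag = "ok")
}

#' Behavior-behavior correlation table
#'
#' Spearman rank correlations between per-animal behavior totals, with
#' multiplicity-corrected q-values across the upper triangle (one family
#' per call). The matrix is symmetric with unit diagonal.
#'
#' @param totals A behavior-totals tibble (from [behavior_totals()]); the
#'   (animal x behavior) matrix is formed by summing counts over the
#'   remaining keys. A wide numeric data frame (animals in rows) is also
#'   accepted.
#' @param method Correlation method, default `"spearman"`.
#' @param adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default Benjamini-Hochberg `"BH"`).
#' @return A list of class `behavior_correlations` with matrices `rho`,
#'   `p`, `q`, and `flag` marking behaviors with zero variance (their
#'   correlations are reported as `NA`).
#' @export
behavior_correlations <- function(totals, method = "spearman",
                                  adjust = "BH") {
  if (all(c("animal", "behavior", "n") %in% names(totals))) {
    wide <- tidyr::pivot_wider(
      dplyr::summarise(
        dplyr::group_by(totals, .data$animal, .data$behavior),
        n = sum(.data$n), .groups = "drop"
      ),
      names_from = "behavior", values_from = "n"
    )
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$animal
  } else {
    m <- as.matrix(totals)
  }
  k <- ncol(m)
  constant <- apply(m, 2, function(v) stats::var(v) == 0 || all(is.na(v)))
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  p <- rho
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (constant[i] || constant[j]) next
      ct <- suppressWarnings(
        stats::cor.test(m[, i], m[, j], method = method, exact = FALSE)
      )
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  up <- upper.tri(p)
  q <- p
  q[up] <- stats::p.adjust(p[up], method = adjust)
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  structure(
    list(rho = rho, p = p, q = q,
         flag = colnames(m)[constant]),
    class = "behavior_correlations"
  )
}
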