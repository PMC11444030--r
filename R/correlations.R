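#' Polychoric correlation from a contingency table
#'
#' Two-step estimator: thresholds are set from the inverse-normal of the
#' cumulative marginal proportions, then the latent bivariate-normal
#' correlation is found by maximising the multinomial cell likelihood over
#' (-0.999, 0.999). Assumes each ordinal variable discretises a standard
#' normal latent variable, keeping the estimate on the Pearson (-1, 1) scale
#' for comparability.
#'
#' Rows or columns with zero margins are collapsed into their neighbour with
#' a warning. The standard error is the curvature-based SE of the profile
#' likelihood in rho (threshold uncertainty ignored, as usual for the
#' two-step estimator).
#'
#' @param tab contingency table (matrix of counts, at least 2x2 after
#'   collapsing, positive margins).
#' @return list: `rho`, `se`, `thresholds_row`, `thresholds_col`, `n`.
#' @export
polychoric_rho <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("negative cell counts")
  tab <- collapse_zero_margins(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stopf("contingency table must be at least 2x2 with positive margins")
  }
  n <- sum(tab)
  row_cum <- cumsum(rowSums(tab))[-nrow(tab)] / n
  col_cum <- cumsum(colSums(tab))[-ncol(tab)] / n
  a <- stats::qnorm(row_cum)  # row thresholds
  b <- stats::qnorm(col_cum)  # column thresholds

  negll <- function(rho) -polychoric_loglik(rho, tab, a, b)
  opt <- stats::optimize(negll, interval = c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  se <- NA_real_
  if (abs(rho) < 0.995) {
    h <- tryCatch(numDeriv::hessian(negll, rho), error = function(e) NA)
    if (is.finite(h) && h > 0) se <- sqrt(1 / h)
  }
  list(rho = rho, se = se, thresholds_row = a, thresholds_col = b, n = n)
}

polychoric_loglik <- function(rho, tab, a, b) {
  P <- cell_probs_bvn(rho, a, b)
  P <- pmax(P, 1e-12)
  sum(tab * log(P))
}

# Bivariate-normal rectangle probabilities for all cells given thresholds.
cell_probs_bvn <- function(rho, a, b) {
  av <- c(-Inf, a, Inf)
  bv <- c(-Inf, b, Inf)
  R <- matrix(c(1, rho, rho, 1), 2)
  K <- length(av) - 1L
  L <- length(bv) - 1L
  # cumulative CDF grid, then finite differences
  Phi <- matrix(0, K + 1L, L + 1L)
  for (i in seq_len(K + 1L)) {
    for (j in seq_len(L + 1L)) {
      ai <- av[i]; bj <- bv[j]
      Phi[i, j] <- if (ai == -Inf || bj == -Inf) 0
        else if (ai == Inf && bj == Inf) 1
        else mvtnorm::pmvnorm(upper = c(ai, bj), corr = R,
                              keepAttr = FALSE)
    }
  }
  P <- matrix(0, K, L)
  for (i in seq_len(K)) {
    for (j in seq_len(L)) {
      P[i, j] <- Phi[i + 1, j + 1] - Phi[i, j + 1] - Phi[i + 1, j] + Phi[i, j]
    }
  }
  P
}

collapse_zero_margins <- function(tab) {
  repeat {
    rs <- rowSums(tab)
    cs <- colSums(tab)
    if (all(rs > 0) && all(cs > 0)) return(tab)
    if (any(rs == 0)) {
      i <- which(rs == 0)[1]
      warnf("collapsing zero-margin row %d", i)
      tab <- tab[-i, , drop = FALSE]
    } else {
      j <- which(cs == 0)[1]
      warnf("collapsing zero-margin column %d", j)
      tab <- tab[, -j, drop = FALSE]
    }
  }
}

#' Correlations between significant mediators
#'
#' Audits the overlap of mediators retained as significant: binary-binary
#' pairs use Pearson's correlation; any pair involving an ordinal variable
#' uses the polychoric correlation. Pairs where either variable is constant
#' are reported as missing with a reason. Pairs with `|r| > flag_threshold`
#' are flagged (the reporting convention for correlated mediation pathways).
#'
#' @param records data.frame restricted to the analysis rows (one season).
#' @param mediator_specs list of [mediator_spec()] for the significant
#'   mediators (>= 2).
#' @param flag_threshold absolute-correlation flag level (default 0.5).
#' @return data.frame: `var1`, `var2`, `method` (pearson/polychoric), `r`,
#'   `n`, `flagged`, `reason`.
#' @export
mediator_correlations <- function(records, mediator_specs,
                                  flag_threshold = 0.5) {
  if (length(mediator_specs) < 2) {
    stopf("need at least 2 significant mediators to correlate")
  }
  names_ <- vapply(mediator_specs, function(s) s$name, "")
  types <- vapply(mediator_specs, function(s) s$type, "")
  combs <- utils::combn(seq_along(names_), 2)
  out <- vector("list", ncol(combs))
  for (k in seq_len(ncol(combs))) {
    i <- combs[1, k]; j <- combs[2, k]
    x <- records[[names_[i]]]
    y <- records[[names_[j]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    method <- if (types[i] == "ordinal" || types[j] == "ordinal") {
      "polychoric"
    } else "pearson"
    r <- NA_real_; reason <- NA_character_
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      reason <- "constant variable; correlation undefined"
    } else if (method == "pearson") {
      r <- stats::cor(as.numeric(x), as.numeric(y))
    } else {
      tab <- table(x, y)
      r <- tryCatch(polychoric_rho(tab)$rho, error = function(e) NA_real_)
      if (is.na(r)) reason <- "polychoric estimation failed"
    }
    out[[k]] <- data.frame(var1 = names_[i], var2 = names_[j],
                           method = method, r = r, n = length(x),
                           flagged = !is.na(r) & abs(r) > flag_threshold,
                           reason = reason, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
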