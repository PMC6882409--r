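# Two-factor permutational univariate ANOVA (pseudo-F, unrestricted
# permutations) for treatment contrasts on per-fish endpoints.
#
# The pseudo-F statistics come from the sequential (Type I) sums-of-squares
# decomposition of the two-way layout on the raw response; the reference
# distribution comes from unrestricted permutation of the raw observations,
# with the observed assignment always counted among the permutations:
# p = (1 + #{F* >= F_obs}) / (n_perm + 1).

#' Two-factor permutational ANOVA
#'
#' @param response Numeric response vector (one value per fish).
#' @param a,b Factors (or vectors coerced to factors), each with at least
#'   two levels. Terms are tested in the sequential order `a`, `b`, `a:b`.
#' @param n_perm Number of unrestricted permutations (default 999).
#' @param seed Integer seed for reproducibility.
#' @param term_labels Optional labels for the two factors in the output.
#' @return Object of class `perm_anova` holding a table of term, df, sums
#'   of squares, pseudo-F and permutation p-value. For balanced designs
#'   the pseudo-F values equal the classical two-way ANOVA F statistics.
#'   When a cell structure leaves zero residual degrees of freedom, the
#'   interaction cannot be tested and is flagged.
#' @examples
#' set.seed(1)
#' d <- expand.grid(temp = c(20, 24, 28), oxy = c("norm", "low"),
#'                  rep = 1:4)
#' y <- rnorm(nrow(d)) + (d$oxy == "low") * 2
#' perm_anova(y, d$temp, d$oxy, n_perm = 199, seed = 1)
#' @export
perm_anova <- function(response, a, b, n_perm = 999, seed = NULL,
                       term_labels = c("A", "B")) {
  y <- as.numeric(response)
  a <- factor(a); b <- factor(b)
  n <- length(y)
  if (length(a) != n || length(b) != n) {
    stop("`response`, `a` and `b` must have equal length", call. = FALSE)
  }
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("each factor needs at least 2 levels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  X <- stats::model.matrix(~ a * b)
  asgn <- attr(X, "assign")           # 0 = intercept, 1 = a, 2 = b, 3 = a:b
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # empty cells: drop the unestimable interaction columns
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
    asgn <- asgn[sort(keep)]
    qrX <- qr(X)
  }
  Q <- qr.Q(qrX)                      # orthonormal, ordered as X columns
  df_terms <- tabulate(asgn + 1L, nbins = 4L)[2:4]
  df_res <- n - sum(df_terms) - 1L
  test_int <- df_terms[3] > 0 && df_res > 0
  skip_flag <- df_terms[3] == 0 || df_res == 0

  term_ss <- function(yv) {
    e <- crossprod(Q, yv)             # coordinates in the Q basis
    ss <- c(sum(e[asgn == 1]^2), sum(e[asgn == 2]^2),
            sum(e[asgn == 3]^2))
    ss
  }
  tot_ss <- sum((y - mean(y))^2)
  f_from_ss <- function(ss) {
    res <- tot_ss - sum(ss)
    ms_res <- if (df_res > 0) res / df_res else NA_real_
    f <- ifelse(df_terms > 0, (ss / pmax(df_terms, 1)) / ms_res, NA_real_)
    f[!is.finite(f)] <- NA_real_
    f
  }

  if (tot_ss <= 0) {                  # zero-variance response
    tab <- data.frame(
      term = c(term_labels[1], term_labels[2],
               paste(term_labels, collapse = ":")),
      df = df_terms, ss = 0, pseudo_F = 0, p_value = 1,
      n_perm = n_perm)
    out <- list(table = tab, df_residual = df_res, n = n,
                seed = seed, flags = "zero_variance",
                data = list(y = y, a = a, b = b), n_perm = n_perm,
                term_labels = term_labels)
    class(out) <- "perm_anova"
    return(out)
  }

  ss_obs <- term_ss(y)
  f_obs <- f_from_ss(ss_obs)

  # permutation distribution, vectorised: each column a permuted response
  Yp <- matrix(0, n, n_perm)
  for (p in seq_len(n_perm)) Yp[, p] <- y[sample.int(n)]
  E <- crossprod(Q, Yp)               # p x n_perm
  ss_a <- colSums(E[asgn == 1, , drop = FALSE]^2)
  ss_b <- colSums(E[asgn == 2, , drop = FALSE]^2)
  ss_ab <- if (any(asgn == 3)) {
    colSums(E[asgn == 3, , drop = FALSE]^2)
  } else rep(0, n_perm)
  res_p <- tot_ss - ss_a - ss_b - ss_ab
  ms_res_p <- if (df_res > 0) res_p / df_res else rep(NA_real_, n_perm)
  fp <- rbind(ss_a / max(df_terms[1], 1),
              ss_b / max(df_terms[2], 1),
              ss_ab / max(df_terms[3], 1)) /
    rep(ms_res_p, each = 3)

  pvals <- vapply(1:3, function(k) {
    if (!is.finite(f_obs[k])) return(NA_real_)
    (1 + sum(fp[k, ] >= f_obs[k] - 1e-12, na.rm = TRUE)) / (n_perm + 1)
  }, 0)
  if (!test_int) { f_obs[3] <- NA_real_; pvals[3] <- NA_real_ }

  tab <- data.frame(
    term = c(term_labels[1], term_labels[2],
             paste(term_labels, collapse = ":")),
    df = df_terms, ss = ss_obs, pseudo_F = f_obs, p_value = pvals,
    n_perm = n_perm)
  out <- list(table = tab, df_residual = df_res,
              ss_residual = tot_ss - sum(ss_obs), n = n, seed = seed,
              flags = if (skip_flag) "interaction_untestable"
                      else character(),
              data = list(y = y, a = a, b = b), n_perm = n_perm,
              term_labels = term_labels)
  class(out) <- "perm_anova"
  out
}

#' @export
print.perm_anova <- function(x, ...) {
  cat(sprintf(
    "Permutational two-factor ANOVA (%d unrestricted permutations)\n",
    x$n_perm))
  tab <- x$table
  tab$ss <- signif(tab$ss, 5)
  tab$pseudo_F <- signif(tab$pseudo_F, 5)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual df: %d\n", x$df_residual))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.perm_anova <- function(object, ...) print(object)

#' Permutation pairwise post-hoc comparisons
#'
#' Pairwise permutation t-style tests between the levels of one factor of
#' a fitted [perm_anova()], run when the omnibus term is significant.
#' For each level pair the two-sample t statistic is compared with its
#' distribution under permutation of the pooled observations; raw and
#' Holm-adjusted p-values are reported.
#'
#' @param fit A `perm_anova` object.
#' @param term Which factor to compare: `"A"` or `"B"` (or its label).
#' @param n_perm Permutations per pair (default 999).
#' @param seed Integer seed.
#' @param alpha Significance level required of the omnibus test
#'   (default 0.05).
#' @param force Run even when the omnibus term is not significant.
#' @return Data frame with one row per level pair: the two levels, mean
#'   difference, t statistic, raw and Holm-adjusted permutation p-values.
#' @export
pairwise_posthoc <- function(fit, term = "A", n_perm = 999, seed = NULL,
                             alpha = 0.05, force = FALSE) {
  stopifnot(inherits(fit, "perm_anova"))
  idx <- match(term, c("A", "B", fit$term_labels))
  if (is.na(idx)) stop("`term` must name a tested factor", call. = FALSE)
  idx <- if (idx > 2) idx - 2L else idx
  p_omni <- fit$table$p_value[idx]
  if (!force && (!is.finite(p_omni) || p_omni > alpha)) {
    stop(sprintf(
      "omnibus p = %.3f for term '%s' is not significant at alpha = %g; ",
      p_omni, fit$table$term[idx], alpha),
      "use force = TRUE to run anyway", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  f <- if (idx == 1L) fit$data$a else fit$data$b
  y <- fit$data$y
  levs <- levels(f)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    sel <- f %in% pr
    yy <- y[sel]
    g <- droplevels(f[sel])
    t_stat <- function(yv) {
      m <- tapply(yv, g, mean)
      v <- tapply(yv, g, stats::var)
      nn <- tabulate(g)
      sp <- sqrt(((nn[1] - 1) * v[1] + (nn[2] - 1) * v[2]) /
                   (sum(nn) - 2) * (1 / nn[1] + 1 / nn[2]))
      if (!is.finite(sp) || sp == 0) return(0)
      (m[1] - m[2]) / sp
    }
    t_obs <- abs(t_stat(yy))
    t_perm <- vapply(seq_len(n_perm),
                     function(i) abs(t_stat(yy[sample.int(length(yy))])),
                     0)
    p <- (1 + sum(t_perm >= t_obs - 1e-12)) / (n_perm + 1)
    data.frame(level_1 = pr[1], level_2 = pr[2],
               mean_diff = unname(diff(rev(tapply(yy, g, mean)))),
               t = unname(t_obs), p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  out
}
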