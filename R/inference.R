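.orth_contr <- function(l) {
  C <- stats::contr.helmert(l)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

.unit_vec <- function(l) matrix(1 / sqrt(l), l, 1)

#' Mixed-design ANOVA with sphericity handling
#'
#' Fits a split-plot (mixed) design with up to one between-subjects factor
#' and up to two fully crossed within-subjects factors, one observation per
#' participant per within-cell. The engine projects the participant-by-cell
#' response matrix onto orthonormal within-effect contrasts and tests each
#' effect against its own stratum error, using Type III sums of squares
#' (sum-to-zero coding, so hypotheses are about unweighted marginal means
#' even when group sizes differ). Per within stratum with more than two
#' levels it computes Mauchly's sphericity test and the Greenhouse-Geisser
#' epsilon in eigenvalue form from the stratum error covariance; when
#' Mauchly's p falls below `sphericity_alpha` the degrees of freedom of that
#' stratum's effects are multiplied by epsilon. Generalized eta squared
#' follows the observed/manipulated decomposition: effects involving an
#' `observed` factor contribute their sum of squares to every denominator.
#'
#' Participants with any missing within-cell are dropped case-wise with a
#' warning.
#'
#' @param data Long-format data frame.
#' @param dv Name of the numeric dependent-variable column.
#' @param id Name of the participant identifier column.
#' @param within Character vector (length 0-2) of within-subject factor
#'   columns.
#' @param between Optional name of the between-subjects factor column.
#' @param observed Factors treated as observed (not manipulated) for
#'   generalized eta squared; defaults to the between factor.
#' @param sphericity_alpha Mauchly p-value below which the
#'   Greenhouse-Geisser correction is applied.
#' @return A data frame of class `"implearn_anova"`, one row per effect:
#'   `effect`, `ss`, `ss_error`, `mauchly_chi2`, `mauchly_df`, `mauchly_p`,
#'   `gg_epsilon`, `corrected`, `df`, `df_error`, `F`, `p`, `ges`, `mse`.
#'   `df`/`df_error`/`p` reflect the correction when it is active; `F` and
#'   `mse` are never rescaled.
#' @examples
#' d <- expand.grid(id = factor(1:8), block = factor(1:3))
#' d$y <- rnorm(nrow(d)) + as.numeric(d$block)
#' mixed_anova(d, dv = "y", id = "id", within = "block")
#' @export
mixed_anova <- function(data, dv, id, within = NULL, between = NULL,
                        observed = between, sphericity_alpha = 0.05) {
  for (v in c(dv, id, within, between)) {
    if (!v %in% names(data)) stop(sprintf("column '%s' not found", v))
  }
  if (length(within) > 2L) stop("at most two within-subject factors")
  d0 <- data
  d0[[id]] <- factor(d0[[id]])
  for (f in c(within, between)) d0[[f]] <- factor(d0[[f]])
  if (!is.numeric(d0[[dv]])) stop("dependent variable must be numeric")

  key <- if (length(within)) {
    interaction(d0[within], drop = FALSE, lex.order = FALSE)
  } else {
    factor(rep("cell", nrow(d0)))
  }
  if (any(table(d0[[id]], key) > 1)) {
    stop("more than one observation per participant and within-cell; aggregate first")
  }
  Y <- tapply(d0[[dv]], list(d0[[id]], key), function(x) x[1])
  complete <- stats::complete.cases(Y)
  if (!all(complete)) {
    warning(sprintf("%d participant(s) dropped case-wise (missing within-cells)",
                    sum(!complete)))
  }
  Y <- Y[complete, , drop = FALSE]
  ids <- rownames(Y)
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 participants with complete data")

  if (!is.null(between)) {
    gmap <- unique(d0[, c(id, between)])
    if (anyDuplicated(gmap[[id]])) {
      stop("between-subjects factor varies within participant")
    }
    g <- droplevels(factor(gmap[[between]][match(ids, as.character(gmap[[id]]))]))
    X <- stats::model.matrix(~g, contrasts.arg = list(g = "contr.sum"))
    between_idx <- 2:ncol(X)
  } else {
    X <- matrix(1, n, 1)
    between_idx <- integer(0)
  }
  p_x <- ncol(X)
  if (qr(X)$rank < p_x) stop("between design is rank-deficient")
  XtXinv <- solve(crossprod(X))

  lv <- lapply(within, function(f) levels(d0[[f]]))
  contrast_for <- function(subset) {
    M <- matrix(1, 1, 1)
    for (j in rev(seq_along(within))) {
      l <- length(lv[[j]])
      Mj <- if (j %in% subset) .orth_contr(l) else .unit_vec(l)
      M <- M %x% Mj
    }
    M
  }
  subsets <- list(integer(0))
  if (length(within) >= 1L) subsets <- c(subsets, list(1L))
  if (length(within) == 2L) subsets <- c(subsets, list(2L), list(c(1L, 2L)))

  rows <- list()
  error_ss <- numeric(0)
  for (subset in subsets) {
    Cm <- contrast_for(subset)
    dct <- ncol(Cm)
    U <- Y %*% Cm
    B <- XtXinv %*% crossprod(X, U)
    E <- crossprod(U - X %*% B)
    df_e_m <- n - p_x
    df_e <- df_e_m * dct
    ss_e <- sum(diag(E))
    error_ss <- c(error_ss, ss_e)
    eps <- NA_real_
    m_chi2 <- NA_real_
    m_df <- NA_real_
    m_p <- NA_real_
    if (dct > 1L) {
      lam <- eigen(E / df_e_m, symmetric = TRUE, only.values = TRUE)$values
      lam <- pmax(lam, 0)
      eps <- sum(lam)^2 / (dct * sum(lam^2))
      W <- prod(lam) / mean(lam)^dct
      m_chi2 <- -(df_e_m - (2 * dct^2 + dct + 2) / (6 * dct)) * log(W)
      m_df <- dct * (dct + 1) / 2 - 1
      m_p <- stats::pchisq(m_chi2, m_df, lower.tail = FALSE)
    }
    hyps <- list()
    if (length(subset)) {
      hyps[[paste(within[subset], collapse = ":")]] <- 1L
    }
    if (length(between_idx)) {
      nm <- if (length(subset)) {
        paste(c(between, within[subset]), collapse = ":")
      } else {
        between
      }
      hyps[[nm]] <- between_idx
    }
    for (nm in names(hyps)) {
      idx <- hyps[[nm]]
      Bi <- B[idx, , drop = FALSE]
      Vi <- XtXinv[idx, idx, drop = FALSE]
      H <- crossprod(Bi, solve(Vi, Bi))
      ss_h <- sum(diag(H))
      df_h <- length(idx) * dct
      Fv <- (ss_h / df_h) / (ss_e / df_e)
      corrected <- !is.na(m_p) && m_p < sphericity_alpha
      df_rep <- if (corrected) df_h * eps else df_h
      df_e_rep <- if (corrected) df_e * eps else df_e
      rows[[nm]] <- data.frame(
        effect = nm, ss = ss_h, ss_error = ss_e,
        mauchly_chi2 = m_chi2, mauchly_df = m_df, mauchly_p = m_p,
        gg_epsilon = eps, corrected = corrected,
        df = df_rep, df_error = df_e_rep, F = Fv,
        p = stats::pf(Fv, df_rep, df_e_rep, lower.tail = FALSE),
        ges = NA_real_, mse = ss_e / df_e
      )
    }
  }

  # reporting order: between main effect first, then each within effect
  # followed by its between interaction, then the within interaction
  ord <- character(0)
  if (!is.null(between)) ord <- between
  for (j in seq_along(within)) {
    ord <- c(ord, within[j])
    if (!is.null(between)) ord <- c(ord, paste(between, within[j], sep = ":"))
  }
  if (length(within) == 2L) {
    nm2 <- paste(within, collapse = ":")
    ord <- c(ord, nm2)
    if (!is.null(between)) ord <- c(ord, paste(between, nm2, sep = ":"))
  }
  tab <- do.call(rbind, rows[ord[ord %in% names(rows)]])

  obs_flag <- vapply(strsplit(tab$effect, ":", fixed = TRUE),
                     function(fs) any(fs %in% observed), logical(1))
  obs_sum <- sum(tab$ss[obs_flag])
  denom <- ifelse(obs_flag, 0, tab$ss) + sum(error_ss) + obs_sum
  tab$ges <- tab$ss / denom
  rownames(tab) <- NULL
  class(tab) <- c("implearn_anova", "data.frame")
  attr(tab, "n") <- n
  tab
}

#' Tukey's HSD over a set of cell means
#'
#' Studentized-range-adjusted pairwise comparisons given the cell means, the
#' ANOVA mean squared error, its degrees of freedom, and the per-cell sample
#' sizes (the Tukey-Kramer standard error is used when sizes differ). With
#' two cells the adjusted p equals the unadjusted two-sided t-test p.
#'
#' @param means Named numeric vector of cell means (length `>= 2`).
#' @param mse Error mean square from the ANOVA context.
#' @param df_error Its degrees of freedom.
#' @param ns Per-cell sample sizes (recycled if scalar).
#' @return Data frame with one row per pair: `cell_1`, `cell_2`, `diff`,
#'   `se`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(means, mse, df_error, ns) {
  k <- length(means)
  if (k < 2L) stop("need at least 2 cell means")
  if (is.null(names(means))) names(means) <- paste0("cell", seq_len(k))
  ns <- rep_len(ns, k)
  pairs <- utils::combn(k, 2)
  out <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    data.frame(cell_1 = names(means)[i], cell_2 = names(means)[j],
               diff = unname(means[i] - means[j]), se = se, q = unname(q),
               p_adj = stats::ptukey(q, k, df_error, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with a two-sided p-value from the t transform.
#'
#' @param x,y Numeric vectors of equal length `>= 3` with finite values.
#' @return List with `r`, `n`, `df`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x),
       df = unname(ct$parameter), p = ct$p.value)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction by default (the
#' correction can be enabled).
#'
#' @param counts Matrix of non-negative integer counts.
#' @param correct Apply Yates' continuity correction (2x2 only)?
#' @return List with `chi2`, `df`, `p`.
#' @export
contingency_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: empty margin")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
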