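#' Run one of the study's standard statistical comparisons
#'
#' Thin orchestration over the standard tests, with explicit Bonferroni
#' family handling: `corrected_p = min(1, raw_p * correction_family_size)`.
#' Supported tests: `friedman_dunn` (Friedman omnibus over a subjects x
#' conditions matrix, followed by pairwise Dunn's z tests, see
#' [dunn_posthoc()]), `wilcoxon_bonferroni` (paired signed-rank),
#' `mannwhitney_bonferroni` (unpaired rank-sum), `fisher_exact`, `chi2`
#' (contingency tables) and `one_sample_t_vs_50` (percentages against the
#' 50% chance level).
#'
#' @param data test-dependent: a matrix (friedman), list of two vectors
#'   (wilcoxon/mannwhitney), a table/matrix (fisher, chi2) or a vector (one
#'   sample t).
#' @param test test name (see above).
#' @param alpha significance level.
#' @param correction_family_size Bonferroni family size.
#' @param ... passed to the underlying test.
#' @return list of class `stat_result`: `test`, `statistic`, `raw_p`,
#'   `corrected_p`, `n`, `significant`, `degenerate` plus test-specific
#'   extras.
#' @export
run_comparison <- function(data, test = c("friedman_dunn",
                                          "wilcoxon_bonferroni",
                                          "mannwhitney_bonferroni",
                                          "fisher_exact", "chi2",
                                          "one_sample_t_vs_50"),
                           alpha = 0.05, correction_family_size = 1, ...) {
  test <- match.arg(test)
  degenerate <- FALSE
  extras <- list()
  switch(test,
    friedman_dunn = {
      m <- as.matrix(data)
      ft <- friedman.test(m)
      stat <- unname(ft$statistic); p <- ft$p.value; n <- nrow(m)
      extras$dunn <- dunn_posthoc(m)
    },
    wilcoxon_bonferroni = {
      x <- data[[1]]; y <- data[[2]]
      if (length(x) != length(y)) stop("paired test needs matched samples")
      if (all(x == y)) {
        degenerate <- TRUE; stat <- NA_real_; p <- NA_real_
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
      n <- length(x)
    },
    mannwhitney_bonferroni = {
      wt <- suppressWarnings(wilcox.test(data[[1]], data[[2]]))
      stat <- unname(wt$statistic); p <- wt$p.value
      n <- c(length(data[[1]]), length(data[[2]]))
    },
    fisher_exact = {
      ftab <- fisher.test(as.matrix(data), ...)
      stat <- if (!is.null(ftab$estimate)) unname(ftab$estimate) else NA_real_
      p <- ftab$p.value; n <- sum(data)
    },
    chi2 = {
      ct <- suppressWarnings(chisq.test(as.matrix(data), ...))
      stat <- unname(ct$statistic); p <- ct$p.value; n <- sum(data)
    },
    one_sample_t_vs_50 = {
      if (length(data) < 2) stop("insufficient n for a one-sample t test")
      tt <- t.test(data, mu = 50)
      stat <- unname(tt$statistic); p <- tt$p.value; n <- length(data)
      extras$direction <- if (mean(data) > 50) "above" else "below"
    })
  corrected <- if (is.na(p)) NA_real_ else
    min(1, p * correction_family_size)
  structure(c(list(test = test, statistic = stat, raw_p = p,
                   corrected_p = corrected, n = n,
                   significant = isTRUE(corrected < alpha),
                   degenerate = degenerate,
                   correction_family_size = correction_family_size),
              extras), class = "stat_result")
}

#' Dunn's post hoc test after a Friedman omnibus
#'
#' Pairwise z statistics on the within-block rank sums,
#' \eqn{z = (\bar R_i - \bar R_j) / \sqrt{k (k + 1) / (6 n) \cdot C}}
#' with the tie-correction factor
#' \eqn{C = 1 - \sum (t^3 - t) / (n k (k^2 - 1))} over all tie groups, and
#' two-sided normal p values with Bonferroni correction over the reported
#' pairs.
#'
#' @param m subjects x conditions matrix.
#' @param reference optional condition (column) index; when given, only
#'   comparisons against it are reported (and corrected for).
#' @return data.frame: `i`, `j`, `z`, `raw_p`, `corrected_p`.
#' @export
dunn_posthoc <- function(m, reference = NULL) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rbar <- colMeans(r)
  ties <- sum(apply(m, 1, function(row) {
    tg <- table(rank(row))
    sum(tg^3 - tg)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  se <- sqrt(k * (k + 1) / (6 * n) * C)
  pairs <- utils::combn(k, 2)
  if (!is.null(reference))
    pairs <- pairs[, pairs[1, ] == reference | pairs[2, ] == reference,
                   drop = FALSE]
  fam <- ncol(pairs)
  out <- apply(pairs, 2, function(pr) {
    z <- (rbar[pr[1]] - rbar[pr[2]]) / se
    p <- 2 * pnorm(-abs(z))
    c(i = pr[1], j = pr[2], z = z, raw_p = p,
      corrected_p = min(1, p * fam))
  })
  as.data.frame(t(out))
}

#' Proportion-of-responsive-neurons trend across sessions
#'
#' Overall chi-squared test on the responsive/total counts of the three
#' sessions, followed by session-1-referenced pairwise Fisher exact tests
#' with Bonferroni correction (family = number of pairwise tests).
#'
#' @param responsive_by_session logical matrix, neurons x sessions (3
#'   columns).
#' @param alpha significance level.
#' @return list: `counts`, `chi2` (a `stat_result`), `pairwise`
#'   (data.frame of Fisher results vs session 1).
#' @export
responsive_proportion_trend <- function(responsive_by_session, alpha = 0.05) {
  m <- as.matrix(responsive_by_session)
  if (ncol(m) < 2) stop("need at least two sessions")
  if (any(colSums(!is.na(m)) == 0)) stop("empty session")
  counts <- rbind(responsive = colSums(m), total = colSums(!is.na(m)))
  tab <- rbind(counts["responsive", ],
               counts["total", ] - counts["responsive", ])
  chi2 <- run_comparison(tab, "chi2")
  fam <- ncol(m) - 1
  pairwise <- do.call(rbind, lapply(2:ncol(m), function(s) {
    sub <- tab[, c(1, s)]
    fr <- fisher.test(sub)
    data.frame(session = s, vs = 1, raw_p = fr$p.value,
               corrected_p = min(1, fr$p.value * fam),
               odds_ratio = unname(fr$estimate))
  }))
  pairwise$significant <- pairwise$corrected_p < alpha
  list(counts = counts, chi2 = chi2, pairwise = pairwise)
}

#' Aggregate comparison results into a machine-readable report
#'
#' @param results named list of `stat_result` objects (or lists).
#' @return list of class `stat_report`: `table` (one row per comparison) and
#'   `json` (deterministic JSON string).
#' @export
build_report <- function(results) {
  if (!length(results)) {
    tab <- data.frame(name = character(0), test = character(0),
                      statistic = numeric(0), raw_p = numeric(0),
                      corrected_p = numeric(0), significant = logical(0))
  } else {
    tab <- do.call(rbind, lapply(names(results), function(nm) {
      r <- results[[nm]]
      data.frame(name = nm, test = r$test,
                 statistic = if (is.null(r$statistic)) NA_real_ else
                   as.numeric(r$statistic)[1],
                 raw_p = as.numeric(r$raw_p)[1],
                 corrected_p = as.numeric(r$corrected_p)[1],
                 significant = isTRUE(r$significant))
    }))
  }
  json <- jsonlite::toJSON(tab, digits = NA, auto_unbox = TRUE,
                           na = "null")
  structure(list(table = tab, json = json), class = "stat_report")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result> ", x$test, ": statistic = ",
      format(x$statistic, digits = 4), ", raw p = ",
      format(x$raw_p, digits = 4), ", corrected p = ",
      format(x$corrected_p, digits = 4),
      if (isTRUE(x$degenerate)) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}
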