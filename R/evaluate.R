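#' Token error rate from a minimum-edit-distance alignment
#'
#' Aligns a hypothesis token sequence against a reference with unit-cost
#' Levenshtein dynamic programming and counts substitutions (S), deletions (D,
#' reference tokens missing from the hypothesis) and insertions (I, hypothesis
#' tokens absent from the reference).  The token error rate is
#' \deqn{TER = 100 (S + D + I) / n_{tok}}
#' where `n_tok` is the number of scored reference tokens.  Start (6) and end
#' (7) markers are stripped before scoring, so for this corpus `n_tok = 3`;
#' TER can exceed 100% through insertions.
#'
#' @param reference Integer reference token sequence.
#' @param hypothesis Integer decoded token sequence.
#' @param strip_markers Drop tokens 6/7 before scoring (default TRUE).
#' @param start_token,end_token Marker token IDs.
#' @return A one-row data.frame with columns `S`, `D`, `I`, `n_tok`, `ter`.
#' @examples
#' ter(c(6, 0, 2, 4, 7), c(0, 2, 4))        # 0%
#' ter(c(0, 2, 4), c(1, 2, 4))              # one substitution: 33.3%
#' @export
ter <- function(reference, hypothesis, strip_markers = TRUE,
                start_token = 6L, end_token = 7L) {
  if (strip_markers) {
    reference <- reference[!(reference %in% c(start_token, end_token))]
    hypothesis <- hypothesis[!(hypothesis %in% c(start_token, end_token))]
  }
  n <- length(reference)
  if (n == 0L) stop("reference has no scored tokens", call. = FALSE)
  counts <- edit_counts(reference, hypothesis)
  data.frame(S = counts["S"], D = counts["D"], I = counts["I"],
             n_tok = n, ter = 100 * sum(counts) / n, row.names = NULL)
}

# Levenshtein DP with backtrace yielding (S, D, I).  Rows index the reference,
# columns the hypothesis.  Ties during backtrace prefer match/substitution,
# then deletion, then insertion; any minimal alignment gives the same S+D+I.
edit_counts <- function(reference, hypothesis) {
  nr <- length(reference); nh <- length(hypothesis)
  d <- matrix(0L, nr + 1L, nh + 1L)
  d[, 1L] <- 0:nr
  d[1L, ] <- 0:nh
  for (i in seq_len(nr)) {
    for (j in seq_len(nh)) {
      cost <- as.integer(reference[i] != hypothesis[j])
      d[i + 1L, j + 1L] <- min(d[i, j] + cost,       # match / substitute
                               d[i, j + 1L] + 1L,    # delete ref token
                               d[i + 1L, j] + 1L)    # insert hyp token
    }
  }
  S <- D <- I <- 0L
  i <- nr; j <- nh
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        d[i + 1L, j + 1L] == d[i, j] + (reference[i] != hypothesis[j])) {
      if (reference[i] != hypothesis[j]) S <- S + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && d[i + 1L, j + 1L] == d[i, j + 1L] + 1L) {
      D <- D + 1L; i <- i - 1L
    } else {
      I <- I + 1L; j <- j - 1L
    }
  }
  c(S = S, D = D, I = I)
}

#' Aggregate decode results into a TER report
#'
#' Scores every decode result against its reference and averages per grouping
#' (typically condition or participant-surrogate).
#'
#' @param results A list of decode results, each a list with `reference` and
#'   `hypothesis` token vectors plus optional provenance fields (`fold`,
#'   `repeat_id`, `trial`, `condition`).
#' @return An object of class `ter_report`: a list with `per_result` (one row
#'   per decode: provenance, S, D, I, n_tok, ter) and `summary` (mean/sd TER
#'   per condition).
#' @export
aggregate_ter <- function(results) {
  if (length(results) == 0L) stop("no results to aggregate", call. = FALSE)
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    entry <- ter(r$reference, r$hypothesis)
    entry$result_id <- k
    entry$condition <- if (is.null(r$condition)) "all" else r$condition
    entry$fold <- if (is.null(r$fold)) NA_integer_ else r$fold
    entry$repeat_id <- if (is.null(r$repeat_id)) NA_integer_ else r$repeat_id
    entry$trial <- if (is.null(r$trial)) NA_integer_ else r$trial
    entry
  })
  per_result <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_result, per_result$condition),
    function(g) data.frame(condition = g$condition[1], n = nrow(g),
                           mean_ter = mean(g$ter), sd_ter = stats::sd(g$ter))))
  rownames(summary) <- NULL
  structure(list(per_result = per_result, summary = summary),
            class = "ter_report")
}

#' @export
print.ter_report <- function(x, ...) {
  cat("Token error rate report:", nrow(x$per_result), "decodes\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two TER vectors
#'
#' One-sided Wilcoxon signed-rank test of the hypothesis that condition `b`
#' outperforms (has lower TER than) condition `a`, with Holm-Bonferroni
#' adjustment for `m` planned comparisons and Cohen's d effect size.  The test
#' is exact for n <= 25 without ties; zero differences are dropped (the
#' conventional signed-rank treatment).
#'
#' @param a,b Paired per-unit TER vectors (e.g. one value per
#'   participant-surrogate); the alternative is `a > b`.
#' @param m Number of planned comparisons for the Holm-Bonferroni step
#'   (default 6).
#' @param label Comparison label carried into the result.
#' @param paired_d If TRUE, Cohen's d is `mean(a - b) / sd(a - b)`; default
#'   uses the pooled-sd form `(mean(a) - mean(b)) / sd_pooled`.
#' @return An object of class `ter_comparison` with fields `label`, `n`,
#'   `p_value`, `p_adjusted` (raw p Holm-scaled as the largest of its step-down
#'   position, capped at 1), `cohens_d`, `statistic`.
#' @export
compare_ter <- function(a, b, m = 6L, label = "a vs b", paired_d = FALSE) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  diffs <- a - b
  if (all(diffs == 0))
    stop("all paired differences are zero; the signed-rank test is degenerate",
         call. = FALSE)
  wt <- stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                           exact = NULL, correct = TRUE)
  d <- if (paired_d) mean(diffs) / stats::sd(diffs) else {
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    (mean(a) - mean(b)) / sp
  }
  structure(list(label = label, n = length(a),
                 p_value = unname(wt$p.value),
                 p_adjusted = min(1, unname(wt$p.value) * m),
                 m = as.integer(m),
                 cohens_d = unname(d),
                 statistic = unname(wt$statistic)),
            class = "ter_comparison")
}

#' Holm-Bonferroni adjustment over a family of comparisons
#'
#' Step-down Holm adjustment of the raw p-values of several
#' [compare_ter()] results, replacing each result's single-comparison
#' Bonferroni bound with the joint monotone adjustment.
#'
#' @param comparisons A list of `ter_comparison` objects.
#' @return The list with `p_adjusted` replaced by `stats::p.adjust(..., "holm")`
#'   values.
#' @export
adjust_comparisons <- function(comparisons) {
  p <- vapply(comparisons, `[[`, numeric(1), "p_value")
  adj <- stats::p.adjust(p, method = "holm")
  for (k in seq_along(comparisons)) {
    comparisons[[k]]$p_adjusted <- adj[k]
    comparisons[[k]]$m <- length(comparisons)
  }
  comparisons
}

#' @export
print.ter_comparison <- function(x, ...) {
  cat(sprintf("%s: n=%d, one-sided Wilcoxon p=%.4g (Holm m=%d: %.4g), Cohen's d=%.3f\n",
              x$label, x$n, x$p_value, x$m, x$p_adjusted, x$cohens_d))
  invisible(x)
}
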