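# Fold-level statistical comparisons: exact paired Wilcoxon signed-rank
# (zero differences dropped, tied absolute differences mean-ranked, exact
# two-sided p by enumeration of sign assignments) and Holm step-down
# adjustment over the comparison family.

# Exact distribution tail counts via meet-in-the-middle enumeration of all
# 2^m sign assignments of the positive-rank sum.
wilcoxon_exact_p <- function(ranks, w) {
  m <- length(ranks)
  if (m == 0) return(1)
  stop_if(m > 25, "exact enumeration supported up to 25 nonzero differences")
  half <- m %/% 2
  sums_of <- function(r) {
    s <- 0
    for (x in r) s <- c(s, s + x)
    s
  }
  s1 <- sums_of(ranks[seq_len(half)])
  s2 <- sort(sums_of(ranks[setdiff(seq_len(m), seq_len(half))]))
  total <- 2^m
  eps <- 1e-9
  count_le <- function(q)  # #{assignments with W <= q}
    sum(findInterval(q - s1 + eps, s2))
  count_ge <- function(q)
    total - sum(findInterval(q - s1 - eps, s2))
  p <- 2 * min(count_le(w), count_ge(w)) / total
  min(p, 1)
}

#' Exact two-sided paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped before ranking (classic variant), tied
#' absolute differences receive mean ranks, and the two-sided p-value is
#' exact, obtained by enumerating all sign assignments of the nonzero
#' differences. All-zero difference vectors give p = 1.
#'
#' @param x,y Paired numeric vectors of equal length (at most 25 nonzero
#'   differences).
#' @return The exact two-sided p-value.
#' @export
wilcoxon_paired <- function(x, y) {
  stop_if(length(x) != length(y), "paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  wilcoxon_exact_p(r, w)
}

#' Holm step-down adjustment
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  stop_if(any(p <= 0 | p > 1), "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Compare methods against a baseline across outer folds
#'
#' For each non-baseline method and each metric, runs an exact two-sided
#' paired Wilcoxon signed-rank test on the per-fold metric values against
#' the baseline, then applies the Holm adjustment. By default the Holm
#' family is all method x metric comparisons jointly; `"per_metric"`
#' restricts each family to one metric.
#'
#' @param records Prediction table from [run_experiment()].
#' @param baseline Baseline method name.
#' @param metrics Metric names from the fold-cell table.
#' @param holm_family `"all"` (default) or `"per_metric"`.
#' @return data.frame with `comparison`, `metric`, `p_raw`, `p_holm`.
#' @export
compare_methods <- function(records, baseline = "audio_only",
                            metrics = c("auc", "f1", "accuracy"),
                            holm_family = c("all", "per_metric")) {
  holm_family <- match.arg(holm_family)
  cells <- fold_cell_metrics(records)
  stop_if(!baseline %in% cells$method,
          paste("baseline", baseline, "not present"))
  others <- setdiff(unique(cells$method), baseline)
  base <- cells[cells$method == baseline, ]
  base <- base[order(base$fold), ]
  rows <- list()
  for (method in others) {
    mc <- cells[cells$method == method, ]
    mc <- mc[order(mc$fold), ]
    common <- intersect(mc$fold, base$fold)
    for (metric in metrics) {
      p <- wilcoxon_paired(mc[[metric]][mc$fold %in% common],
                           base[[metric]][base$fold %in% common])
      rows[[length(rows) + 1]] <- data.frame(
        comparison = paste(method, "vs.", baseline), metric = metric,
        p_raw = p)
    }
  }
  out <- do.call(rbind, rows)
  if (holm_family == "all") {
    out$p_holm <- holm_adjust(out$p_raw)
  } else {
    out$p_holm <- NA_real_
    for (metric in unique(out$metric)) {
      sel <- out$metric == metric
      out$p_holm[sel] <- holm_adjust(out$p_raw[sel])
    }
  }
  rownames(out) <- NULL
  out
}
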