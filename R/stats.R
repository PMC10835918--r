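#' Two-sided paired t-test (closed form)
#'
#' Computes the paired t statistic and p-value on the differences
#' `injected - control` from the closed-form t formula with n - 1 degrees of
#' freedom. Identical samples give t = 0, p = 1; zero-variance differences
#' with a nonzero mean give an undefined p and a flagged result.
#'
#' @param injected,control Equal-length paired numeric vectors, n >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff` and `flagged` (TRUE when
#'   the p-value is undefined).
#' @export
paired_t <- function(injected, control) {
  if (length(injected) != length(control)) stop("paired samples must have equal length")
  n <- length(injected)
  if (n < 2L) stop("need at least 2 pairs")
  d <- injected - control
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0, flagged = FALSE))
    return(list(t = sign(md) * Inf, p = NA_real_, df = n - 1L,
                mean_diff = md, flagged = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1L), df = n - 1L,
       mean_diff = md, flagged = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment: for sorted p-values, adjusted p_(i) is the minimum
#' over j >= i of m * p_(j) / j, clipped to 1. Rejections are made at level
#' `q` on the adjusted values, so downstream code can use
#' "corrected p < threshold" directly.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NAs are carried through and
#'   never rejected).
#' @param q FDR level (default 0.1).
#' @return List with `p_adj` (same order as input) and `reject` (logical).
#' @export
fdr_correct <- function(pvals, q = 0.1) {
  p <- as.numeric(pvals)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- rep(NA_real_, length(p))
  if (any(ok)) {
    pp <- p[ok]
    m <- length(pp)
    o <- order(pp)
    ranked <- pp[o] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    p_adj[ok] <- out
  }
  reject <- !is.na(p_adj) & p_adj <= q
  list(p_adj = p_adj, reject = reject)
}

#' Percent change of the injected eye relative to the control eye
#'
#' `100 * (injected - control) / control`; negative values indicate
#' thinning of the injected eye.
#'
#' @param mean_injected,mean_control Group means (control must be > 0).
#' @return Percent change.
#' @export
percent_change <- function(mean_injected, mean_control) {
  if (any(mean_control <= 0)) stop("mean_control must be positive")
  100 * (mean_injected - mean_control) / mean_control
}

#' Longitudinal paired-eye analysis of a cohort thickness table
#'
#' Runs one paired t-test per (measure, region, day) comparing injected vs
#' control eyes across subjects, applies Benjamini-Hochberg FDR correction
#' within the chosen family (default: each measure x region panel, i.e. the
#' set of days shown together in one subplot; `"global"` corrects across
#' all records), and reports percent changes. Subjects missing either eye
#' at a (measure, region, day) are dropped from that comparison with a
#' message.
#'
#' @param thickness_table Data frame with columns `subject`, `eye`
#'   (injected/control), `day`, `measure`, `region`, `mean_um`.
#' @param fdr_q FDR level (default 0.1).
#' @param family `"panel"` or `"global"` correction family.
#' @param alpha Significance threshold on the corrected p-values.
#' @return Data frame of comparison records: one row per
#'   (measure, region, day) with columns `measure`, `region`, `day`, `n`,
#'   `mean_injected`, `mean_control`, `percent_change`, `t`, `p`, `p_fdr`,
#'   `significant`, `flagged`.
#' @export
longitudinal_analysis <- function(thickness_table, fdr_q = 0.1,
                                  family = c("panel", "global"), alpha = 0.05) {
  family <- match.arg(family)
  tt <- thickness_table
  need <- c("subject", "eye", "day", "measure", "region", "mean_um")
  if (!all(need %in% names(tt))) stop("thickness_table missing columns: ",
                                      paste(setdiff(need, names(tt)), collapse = ", "))
  combos <- unique(tt[, c("measure", "region", "day")])
  combos <- combos[order(combos$measure, combos$region, combos$day), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    sub <- tt[tt$measure == cm$measure & tt$region == cm$region & tt$day == cm$day, ]
    inj <- sub[sub$eye == "injected", c("subject", "mean_um")]
    ctl <- sub[sub$eye == "control", c("subject", "mean_um")]
    common <- intersect(inj$subject, ctl$subject)
    dropped <- setdiff(union(inj$subject, ctl$subject), common)
    if (length(dropped))
      message(sprintf("dropping subject(s) %s from %s/%s day %s (missing eye)",
                      paste(dropped, collapse = ","), cm$measure, cm$region, cm$day))
    x <- inj$mean_um[match(common, inj$subject)]
    y <- ctl$mean_um[match(common, ctl$subject)]
    tst <- paired_t(x, y)
    data.frame(measure = cm$measure, region = cm$region, day = cm$day,
               n = length(common), mean_injected = mean(x), mean_control = mean(y),
               percent_change = percent_change(mean(x), mean(y)),
               t = tst$t, p = tst$p, flagged = tst$flagged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- NA_real_
  res$significant <- FALSE
  fam_key <- if (family == "panel") paste(res$measure, res$region) else
    rep("all", nrow(res))
  for (k in unique(fam_key)) {
    idx <- which(fam_key == k)
    fc <- fdr_correct(res$p[idx], q = fdr_q)
    res$p_fdr[idx] <- fc$p_adj
  }
  res$significant <- !is.na(res$p_fdr) & res$p_fdr < alpha
  res[, c("measure", "region", "day", "n", "mean_injected", "mean_control",
          "percent_change", "t", "p", "p_fdr", "significant", "flagged")]
}
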