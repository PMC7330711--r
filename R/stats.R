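# Group and symptom statistics: pooled-variance t tests (including the
# summary-statistic form that reproduces printed demographic tables),
# edgewise group comparison over the 105 community measures, and Spearman
# rank correlations with clinical scales. No multiple-comparison correction
# is applied by default (an opt-in Benjamini-Hochberg column is available
# and clearly marked as beyond the reference analysis).

#' Student's pooled-variance two-sample t test
#'
#' Classical independent-samples t with pooled variance and
#' `df = n_a + n_b - 2`, two-sided p from the t distribution.
#'
#' @param a,b Numeric sample vectors (each of length >= 2, finite).
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' ttest_ind_pooled(c(1, 2, 3), c(1, 2, 3, 4))
ttest_ind_pooled <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("samples must be finite", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (sp2 <= 0) {
    stop("pooled variance is zero; t statistic undefined", call. = FALSE)
  }
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pooled t statistic from printed summary statistics
#'
#' `t = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))` with
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`. Lets published
#' group-comparison tables (mean, SD, n per group) be re-derived without
#' raw data.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' # age row of a 22-control / 17-patient demographic table
#' ttest_from_summary(44.5, 5, 22, 47.1, 6.1, 17)$t  # ~ -1.463
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    stop("both SDs are zero; t statistic undefined", call. = FALSE)
  }
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Edgewise group comparison of community edge counts
#'
#' One pooled-variance t test per community measure (14 intra + 91 inter =
#' 105 per band), comparing the two groups. The sign convention is
#' `t = mean(group_order[1]) - mean(group_order[2])` with default order
#' `c("HC", "BD")`, so a negative `t` means the patient group has more
#' edges; `t_patient_minus_control = -t` is included to remove any
#' ambiguity. Measures whose pooled variance is zero get `t = NA` and
#' `undefined = TRUE` instead of a silent infinity. No multiplicity
#' correction is applied unless `fdr = TRUE` adds a Benjamini-Hochberg
#' column (beyond the reference analysis).
#'
#' @param counts List of `community_edge_counts`, one per subject (same
#'   band/density).
#' @param groups Character vector of group labels aligned with `counts`.
#' @param group_order Length-2 character: which label is "group 1".
#' @param fdr Add a `p_bh` column? Default `FALSE`.
#' @return Data frame with one row per measure: `measure`, `type`, `band`,
#'   `mean_g1`, `mean_g2`, `t`, `t_patient_minus_control`, `p`, `sig05`,
#'   `sig01`, `undefined` (+ `p_bh` if requested).
#' @export
edgewise_group_comparison <- function(counts, groups,
                                      group_order = c("HC", "BD"),
                                      fdr = FALSE) {
  stopifnot(length(counts) == length(groups), length(group_order) == 2L)
  miss <- setdiff(group_order, unique(groups))
  if (length(miss)) {
    stop("group label(s) absent from 'groups': ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  i1 <- which(groups == group_order[1L])
  i2 <- which(groups == group_order[2L])
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  M <- vapply(counts, measure_vector, numeric(105L))
  band <- counts[[1L]]$band
  bname <- if (is.null(band)) NA_character_ else band$name
  rows <- lapply(seq_len(nrow(M)), function(k) {
    a <- M[k, i1]; b <- M[k, i2]
    tt <- tryCatch(ttest_ind_pooled(a, b), error = function(e) NULL)
    data.frame(
      measure = rownames(M)[k],
      type = sub(":.*", "", rownames(M)[k]),
      band = bname,
      mean_g1 = mean(a), mean_g2 = mean(b),
      t = if (is.null(tt)) NA_real_ else tt$t,
      p = if (is.null(tt)) NA_real_ else tt$p,
      undefined = is.null(tt),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$t_patient_minus_control <-
    if (identical(group_order, c("HC", "BD"))) -out$t else NA_real_
  out$sig05 <- !is.na(out$p) & out$p < 0.05
  out$sig01 <- !is.na(out$p) & out$p < 0.01
  if (fdr) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties get mean rank), with a
#' two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_rank(1:8, (1:8)^3)$rho  # 1: invariant under monotone transforms
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (var(x) == 0 || var(y) == 0) {
    stop("correlation undefined for a constant input vector", call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Correlate graph measures with clinical scales within the patient group
#'
#' Mirrors the within-patients symptom analysis: for each selected measure
#' and each clinical scale, the Spearman rank correlation between the
#' per-subject edge count and the scale score, restricted to the patient
#' group (rows of `scores` whose `group` matches `group`) with non-missing
#' scores.
#'
#' @param counts List of `community_edge_counts` aligned with the cohort.
#' @param scores Data frame with columns `subject_id`, `group` and the
#'   scale columns (default scales `bdi`, `hamd`, `asrm`, `ymrs`).
#' @param measures Character vector of measure names (as in
#'   [measure_vector()]), e.g. `"intra:LM_L"`.
#' @param scales Scale column names to use.
#' @param group Patient-group label (default `"BD"`).
#' @param strict If `TRUE` (default) a constant score or count vector is
#'   an error (the correlation is undefined); with `FALSE` such
#'   combinations yield a row with `rho = NA` and a `note`, letting batch
#'   runs continue.
#' @return Data frame: `measure`, `scale`, `rho`, `p`, `n` (and `note`
#'   when `strict = FALSE`).
#' @export
symptom_correlations <- function(counts, scores, measures,
                                 scales = c("bdi", "hamd", "asrm", "ymrs"),
                                 group = "BD", strict = TRUE) {
  stopifnot(length(counts) == nrow(scores))
  sel <- which(scores$group == group)
  if (length(sel) < 3L) {
    stop("fewer than 3 subjects in group '", group, "' with scores",
         call. = FALSE)
  }
  M <- vapply(counts, measure_vector, numeric(105L))
  rows <- list()
  for (m in measures) {
    if (!m %in% rownames(M)) stop("unknown measure '", m, "'", call. = FALSE)
    for (sc in scales) {
      if (!sc %in% names(scores)) next
      y <- scores[[sc]][sel]
      ok <- is.finite(y)
      if (sum(ok) < 3L) next
      if (strict) {
        r <- spearman_rank(M[m, sel][ok], y[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, scale = sc, rho = r$rho, p = r$p, n = r$n,
          stringsAsFactors = FALSE)
      } else {
        r <- tryCatch(spearman_rank(M[m, sel][ok], y[ok]),
                      error = function(e) conditionMessage(e))
        rows[[length(rows) + 1L]] <- if (is.character(r)) {
          data.frame(measure = m, scale = sc, rho = NA_real_, p = NA_real_,
                     n = sum(ok), note = r, stringsAsFactors = FALSE)
        } else {
          data.frame(measure = m, scale = sc, rho = r$rho, p = r$p,
                     n = r$n, note = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
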