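#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson r over listwise-complete pairs, with the two-sided
#' p-value from t = r * sqrt((n-2)/(1-r^2)). Zero variance in either
#' variable yields a missing result with a reason rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param label Analysis identifier carried into the result.
#' @return A one-row tibble: `label`, `n`, `r`, `p`, `reason` (NA unless
#'   the correlation is undefined).
#' @export
pearson <- function(x, y, label = "pearson") {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    return(tibble::tibble(label = label, n = n, r = NA_real_, p = NA_real_,
                          reason = "n < 3 after listwise deletion"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(label = label, n = n, r = NA_real_, p = NA_real_,
                          reason = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(label = label, n = n, r = unname(ct$estimate),
                 p = ct$p.value, reason = NA_character_)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Computes D+ = sup_x (F_a(x) - F_b(x)), the one-sided statistic testing
#' whether group `a` is stochastically smaller than group `b` (for R1
#' values: more repressed), with the asymptotic p-value
#' exp(-2 * D+^2 * na*nb/(na+nb)). D+ is evaluated directly as the sup
#' over the pooled jump points.
#'
#' @param sample_a,sample_b Numeric samples (non-empty).
#' @return A list with `D` (D+), `p`, `n_a`, `n_b`, and `low_reliability`
#'   (TRUE when either group has fewer than 5 observations).
#' @export
ks_one_sided <- function(sample_a, sample_b) {
  a <- sample_a[is.finite(sample_a)]
  b <- sample_b[is.finite(sample_b)]
  stopifnot(length(a) > 0L, length(b) > 0L)
  jumps <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(jumps)
  Fb <- stats::ecdf(b)(jumps)
  D <- max(Fa - Fb)
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  p <- min(1, exp(-2 * n_eff * D^2))
  list(D = D, p = p, n_a = length(a), n_b = length(b),
       low_reliability = length(a) < 5L || length(b) < 5L)
}

#' Seed-type analysis of repression depth
#'
#' Summarizes R1 by seed type over confirmed single-MRE targets and runs
#' all pairwise one-sided K-S comparisons in the fixed direction
#' "stronger seed class stochastically more repressed (smaller R1)",
#' following the canonical seed hierarchy 8mer > 7mer-m8 > 7mer-A1 >
#' 6mer > else. Pairwise p-values are reported raw, with an optional Holm
#' column for reference.
#'
#' @param records Data frame with columns `seed_type`, `r1`, and
#'   (optionally) `confirmed` and `n_mres`; when present, only confirmed
#'   single-MRE records are analyzed.
#' @return A list with `groups` (per seed type: n, mean R1) and
#'   `comparisons` (stronger, weaker, D, p, p_holm, low_reliability);
#'   absent groups are skipped with a `skipped` attribute listing them.
#' @export
seed_type_analysis <- function(records) {
  rec <- as.data.frame(records)
  if ("confirmed" %in% names(rec)) rec <- rec[rec$confirmed %in% TRUE, ]
  if ("n_mres" %in% names(rec)) rec <- rec[rec$n_mres == 1L, ]
  rec <- rec[rec$seed_type %in% .SEED_TYPES & is.finite(rec$r1), ]
  present <- .SEED_TYPES[.SEED_TYPES %in% unique(rec$seed_type)]
  groups <- tibble::tibble(
    seed_type = present,
    n = vapply(present, function(t) sum(rec$seed_type == t), integer(1)),
    mean_r1 = vapply(present, function(t) mean(rec$r1[rec$seed_type == t]),
                     numeric(1))
  )
  pairs <- utils::combn(.SEED_TYPES, 2)
  rows <- list(); skipped <- character()
  for (k in seq_len(ncol(pairs))) {
    stronger <- pairs[1, k]; weaker <- pairs[2, k]
    if (!stronger %in% present || !weaker %in% present) {
      skipped <- c(skipped, paste(stronger, "vs", weaker))
      next
    }
    ks <- ks_one_sided(rec$r1[rec$seed_type == stronger],
                       rec$r1[rec$seed_type == weaker])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stronger = stronger, weaker = weaker, D = ks$D, p = ks$p,
      low_reliability = ks$low_reliability)
  }
  comparisons <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(stronger = character(), weaker = character(),
                   D = numeric(), p = numeric(), low_reliability = logical())
  comparisons$p_holm <- stats::p.adjust(comparisons$p, method = "holm")
  attr(comparisons, "skipped") <- skipped
  list(groups = groups, comparisons = comparisons)
}

#' Correlate repression depth with endogenous expression
#'
#' Joins confirmed-target R1 values with a gene-expression table on
#' `gene_id`, drops genes absent from the table or below the detection
#' threshold, and computes the Pearson correlation of R1 with (by
#' default log-transformed) abundance.
#'
#' @param r1_table Data frame with `gene_id`, `r1` (confirmed targets).
#' @param expr Data frame with `gene_id`, `abundance` (>= 0, FPKM-like).
#' @param min_expr Detection threshold; genes at or below it are
#'   considered not reliably detected and dropped (default 0.004).
#' @param log_transform Correlate against log(abundance) (default TRUE,
#'   the conventional scale for expression correlations).
#' @param label Analysis identifier.
#' @return A one-row tibble as [pearson()], with `n` the post-filter join
#'   size.
#' @export
correlate_with_expression <- function(r1_table, expr, min_expr = 0.004,
                                      log_transform = TRUE,
                                      label = "r1_vs_expression") {
  stopifnot(all(c("gene_id", "r1") %in% names(r1_table)),
            all(c("gene_id", "abundance") %in% names(expr)))
  expr <- expr[is.finite(expr$abundance) & expr$abundance > min_expr, ]
  j <- merge(as.data.frame(r1_table)[c("gene_id", "r1")],
             as.data.frame(expr)[c("gene_id", "abundance")], by = "gene_id")
  if (nrow(j) < 3L) {
    stop("expression join left n = ", nrow(j), " genes (r1_table: ",
         nrow(r1_table), ", detected in expr: ", nrow(expr), ")",
         call. = FALSE)
  }
  y <- if (log_transform) log(j$abundance) else j$abundance
  pearson(j$r1, y, label = label)
}

#' Post-transfection fold-change analysis
#'
#' Computes the per-gene mRNA fold change FC = abundance(miRNA
#' transfection) / abundance(control transfection) over genes detected in
#' both conditions, and the Pearson correlation of confirmed-target R1
#' with FC (all targets, whether or not their levels went down).
#'
#' @param r1_table Data frame with `gene_id`, `r1`.
#' @param expr_mir,expr_control Expression tables (`gene_id`,
#'   `abundance`) under miRNA and control transfection.
#' @param min_expr Detection threshold applied to both tables.
#' @param log_fc Correlate against log(FC) (default TRUE).
#' @return A list with `fold_changes` (gene_id, fc) and `correlation`
#'   (one-row tibble as [pearson()]).
#' @export
fold_change_analysis <- function(r1_table, expr_mir, expr_control,
                                 min_expr = 0.004, log_fc = TRUE) {
  filt <- function(e) e[is.finite(e$abundance) & e$abundance > min_expr, ]
  m <- filt(as.data.frame(expr_mir))
  ctl <- filt(as.data.frame(expr_control))
  fc <- merge(m, ctl, by = "gene_id", suffixes = c("_mir", "_control"))
  dropped <- fc$abundance_control == 0
  if (any(dropped)) {
    message(sum(dropped), " gene(s) dropped: zero control abundance")
    fc <- fc[!dropped, ]
  }
  fc$fc <- fc$abundance_mir / fc$abundance_control
  j <- merge(as.data.frame(r1_table)[c("gene_id", "r1")],
             fc[c("gene_id", "fc")], by = "gene_id")
  y <- if (log_fc) log(j$fc) else j$fc
  list(fold_changes = tibble::as_tibble(fc[c("gene_id", "fc")]),
       correlation = pearson(j$r1, y, label = "r1_vs_fold_change"))
}

#' Correlate repression depth with prediction scores
#'
#' Pearson correlation of confirmed-target R1 values against each
#' program's ranking score.
#'
#' @param r1_table Data frame with `gene_id`, `r1`.
#' @param annotations Data frame with `gene_id` and one score column per
#'   program (e.g. `score_TargetScan`, `score_miRanda`, `score_PicTar`;
#'   NA where the program did not predict the gene).
#' @param score_cols Score columns to analyze (default: all columns
#'   starting with `"score_"`).
#' @return A tibble with one row per program (label = column name).
#' @export
score_correlations <- function(r1_table, annotations,
                               score_cols = grep("^score_", names(annotations),
                                                 value = TRUE)) {
  j <- merge(as.data.frame(r1_table)[c("gene_id", "r1")],
             as.data.frame(annotations), by = "gene_id")
  do.call(rbind, lapply(score_cols, function(col) {
    pearson(j$r1, j[[col]], label = col)
  }))
}
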