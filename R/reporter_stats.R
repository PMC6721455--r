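#' Per-replicate and mean relative reporter expression (R0)
#'
#' R0 is the (firefly/Renilla) luminescence ratio under miRNA
#' co-transfection divided by the same ratio under the control
#' transfection; values below 1 indicate repression. Replicates are paired
#' by index (replicate i under `mir` against replicate i under `control`),
#' matching a batch-wise experimental design; an unpaired mode (ratio of
#' per-condition mean ratios) is available via `paired = FALSE`.
#'
#' @param measurements A data frame for one construct with columns
#'   `condition` ("mir"/"control"), `replicate` (integer), `firefly`,
#'   `renilla` (positive luminescence readings).
#' @param paired Pair replicates by index (default `TRUE`).
#' @return A list with `r0_replicates` (paired mode: one value per
#'   replicate; unpaired: the single ratio of means) and `r0_mean`.
#' @export
compute_r0 <- function(measurements, paired = TRUE) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("condition", "replicate", "firefly", "renilla") %in% names(m)))
  if (any(m$firefly <= 0) || any(m$renilla <= 0)) {
    stop("luminescence readings must be positive", call. = FALSE)
  }
  mir <- m[m$condition == "mir", ]
  ctl <- m[m$condition == "control", ]
  if (!paired) {
    r0 <- mean(mir$firefly / mir$renilla) / mean(ctl$firefly / ctl$renilla)
    return(list(r0_replicates = r0, r0_mean = r0))
  }
  mir <- mir[order(mir$replicate), ]
  ctl <- ctl[order(ctl$replicate), ]
  if (nrow(mir) != nrow(ctl) || !all(mir$replicate == ctl$replicate)) {
    stop("unmatched replicate indices between mir and control conditions",
         call. = FALSE)
  }
  r0 <- (mir$firefly / mir$renilla) / (ctl$firefly / ctl$renilla)
  list(r0_replicates = unname(r0), r0_mean = mean(r0))
}

#' Confirmation call for one reporter construct
#'
#' A predicted target is confirmed when its mean R0 is below 1 and a
#' two-sided one-sample Student t-test of the replicate R0 values against
#' 1 gives p < `alpha`. Fewer than `min_replicates` replicates makes the
#' construct uncallable (`confirmed = NA`). Zero-variance replicates give
#' p = 0 when the common value differs from 1 and p = 1 otherwise.
#'
#' @param r0_replicates Numeric vector of replicate R0 values.
#' @param alpha Significance level (default 0.05).
#' @param min_replicates Minimum replicates required to call (default 3).
#' @return A list with `confirmed` (TRUE/FALSE/NA), `p_value`, `r0_mean`
#'   and `callable`.
#' @export
call_target <- function(r0_replicates, alpha = 0.05, min_replicates = 3L) {
  r0 <- as.numeric(r0_replicates)
  m <- mean(r0)
  if (length(r0) < min_replicates) {
    return(list(confirmed = NA, p_value = NA_real_, r0_mean = m,
                callable = FALSE))
  }
  if (isTRUE(all.equal(stats::var(r0), 0)) || stats::var(r0) == 0) {
    p <- if (m == 1) 1 else 0
  } else {
    p <- stats::t.test(r0, mu = 1)$p.value
  }
  list(confirmed = (m < 1) && (p < alpha), p_value = p, r0_mean = m,
       callable = TRUE)
}

#' Normalized relative reporter expression (R1)
#'
#' R1 rescales a target's R0 by the R0 of the batch-matched positive
#' control (a reporter perfectly complementary to the miRNA), allowing
#' comparison across experiments performed on different days. Larger R1
#' means weaker inhibition; positive-control R0 is typically 0.1-0.2 and
#' target R0 0.5-0.95, putting most R1 values in the 3-7 band.
#'
#' @param r0_mean_target Mean R0 of the target reporter (> 0).
#' @param r0_mean_positive_control Mean R0 of the batch-matched positive
#'   control (> 0).
#' @return The unitless R1 ratio.
#' @export
compute_r1 <- function(r0_mean_target, r0_mean_positive_control) {
  if (length(r0_mean_positive_control) != 1L ||
      is.na(r0_mean_positive_control)) {
    stop("missing batch-matched positive control R0", call. = FALSE)
  }
  stopifnot(r0_mean_target > 0, r0_mean_positive_control > 0)
  r0_mean_target / r0_mean_positive_control
}

#' Percentage rounded half-up to one decimal
#'
#' Confirmation ratios are reported as `100 * confirmed / selected`,
#' rounded half-up to one decimal (so 81.25 prints as 81.3).
#'
#' @param confirmed,selected Counts.
#' @return Percentage, one decimal, half-up; `NA` when `selected` is 0.
#' @export
confirmation_ratio <- function(confirmed, selected) {
  ifelse(selected == 0, NA_real_,
         floor(1000 * confirmed / selected + 0.5) / 10)
}

.SUMMARY_CATEGORIES <- c("TargetScan", "miRanda", "PicTar",
                         "TargetScan only", "miRanda only", "PicTar only",
                         "All three", "miRTarBase",
                         "Single MRE", "Multiple MREs", "Total")

#' Tabulate confirmation results by prediction category
#'
#' Produces the per-category selected/confirmed/ratio summary of a
#' reporter screen: per program (TargetScan, miRanda, PicTar), per
#' exclusive membership ("X only", "All three"), miRTarBase-annotated,
#' single vs multiple MREs, and the total. Records lacking annotation are
#' tallied under a `"diagnostics: unannotated"` row, never dropped.
#'
#' @param records A data frame with one row per construct: `construct_id`,
#'   `confirmed` (logical), `programs` (semicolon-separated subset of
#'   "TargetScan;miRanda;PicTar", possibly empty), `mirtarbase` (logical),
#'   `n_mres` (integer >= 1).
#' @return A tibble with columns `category`, `selected`, `confirmed`,
#'   `ratio` (percentage, one decimal, half-up).
#' @export
summarize_confirmation <- function(records) {
  rec <- as.data.frame(records)
  needed <- c("confirmed", "programs", "mirtarbase", "n_mres")
  if (!all(needed %in% names(rec))) {
    stop("records must carry columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  missing_ann <- !stats::complete.cases(rec[c("programs", "mirtarbase", "n_mres")])
  unannotated <- rec[missing_ann, , drop = FALSE]
  rec <- rec[!missing_ann, , drop = FALSE]
  progs <- strsplit(ifelse(is.na(rec$programs), "", rec$programs), ";",
                    fixed = TRUE)
  has <- function(p) vapply(progs, function(x) p %in% x, logical(1))
  ts <- has("TargetScan"); mr <- has("miRanda"); pt <- has("PicTar")
  sel <- list(
    "TargetScan" = ts, "miRanda" = mr, "PicTar" = pt,
    "TargetScan only" = ts & !mr & !pt,
    "miRanda only" = mr & !ts & !pt,
    "PicTar only" = pt & !ts & !mr,
    "All three" = ts & mr & pt,
    "miRTarBase" = as.logical(rec$mirtarbase),
    "Single MRE" = rec$n_mres == 1L,
    "Multiple MREs" = rec$n_mres >= 2L,
    "Total" = rep(TRUE, nrow(rec))
  )
  out <- tibble::tibble(
    category = .SUMMARY_CATEGORIES,
    selected = unname(vapply(sel, sum, integer(1))),
    confirmed = unname(vapply(sel, function(i) sum(rec$confirmed[i] %in% TRUE),
                              integer(1)))
  )
  if (nrow(unannotated) > 0L) {
    out <- rbind(out, tibble::tibble(
      category = "diagnostics: unannotated",
      selected = nrow(unannotated),
      confirmed = sum(unannotated$confirmed %in% TRUE)))
  }
  out$ratio <- confirmation_ratio(out$confirmed, out$selected)
  out
}

#' Reconstruct a per-construct call table from category counts
#'
#' Builds a minimal records table (one row per construct, with program
#' membership, miRTarBase flag, MRE multiplicity and confirmation flag)
#' whose per-category tallies under [summarize_confirmation()] equal the
#' given counts. Useful for re-tabulating a published summary whose
#' underlying per-gene table is unavailable.
#'
#' @param region_selected,region_confirmed Named integer vectors over the
#'   seven exclusive program-membership regions: `TargetScan only`,
#'   `miRanda only`, `PicTar only`, `TargetScan+miRanda`,
#'   `TargetScan+PicTar`, `miRanda+PicTar`, `All three`.
#' @param mirtarbase,multi_mre Length-2 integer vectors
#'   `c(selected, confirmed)` for the miRTarBase and multiple-MRE
#'   categories (assigned disjointly, miRTarBase from the head and
#'   multi-MRE from the tail of the cohort).
#' @return A records tibble suitable for [summarize_confirmation()].
#' @export
cohort_from_counts <- function(region_selected, region_confirmed,
                               mirtarbase = c(0L, 0L),
                               multi_mre = c(0L, 0L)) {
  regions <- c("TargetScan only" = "TargetScan",
               "miRanda only" = "miRanda",
               "PicTar only" = "PicTar",
               "TargetScan+miRanda" = "TargetScan;miRanda",
               "TargetScan+PicTar" = "PicTar;TargetScan",
               "miRanda+PicTar" = "PicTar;miRanda",
               "All three" = "PicTar;TargetScan;miRanda")
  stopifnot(identical(sort(names(region_selected)), sort(names(regions))),
            identical(sort(names(region_confirmed)), sort(names(regions))),
            all(region_confirmed <= region_selected))
  rows <- lapply(names(regions), function(rg) {
    n <- region_selected[[rg]]
    if (n == 0L) return(NULL)
    tibble::tibble(programs = regions[[rg]],
                   confirmed = seq_len(n) <= region_confirmed[[rg]])
  })
  rec <- do.call(rbind, rows)
  rec <- rec[order(-rec$confirmed), ]  # confirmed first
  n <- nrow(rec)
  rec$construct_id <- sprintf("t%04d", seq_len(n))
  n_conf <- sum(rec$confirmed)
  # miRTarBase: confirmed entries from the head, unconfirmed right after it
  rec$mirtarbase <- FALSE
  stopifnot(mirtarbase[2] <= n_conf, mirtarbase[1] - mirtarbase[2] <= n - n_conf)
  rec$mirtarbase[seq_len(mirtarbase[2])] <- TRUE
  if (mirtarbase[1] > mirtarbase[2]) {
    rec$mirtarbase[n_conf + seq_len(mirtarbase[1] - mirtarbase[2])] <- TRUE
  }
  # multiple MREs: confirmed entries from the tail of the confirmed block,
  # unconfirmed from the tail of the cohort
  rec$n_mres <- 1L
  stopifnot(multi_mre[2] <= n_conf, multi_mre[1] - multi_mre[2] <= n - n_conf)
  if (multi_mre[2] > 0L) rec$n_mres[n_conf - seq_len(multi_mre[2]) + 1L] <- 2L
  extra <- multi_mre[1] - multi_mre[2]
  if (extra > 0L) rec$n_mres[n - seq_len(extra) + 1L] <- 2L
  rec[c("construct_id", "programs", "mirtarbase", "n_mres", "confirmed")]
}
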