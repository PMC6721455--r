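#' AU percentage around a seed-match site
#'
#' Computes the percentage of A/U residues in a window centered on the
#' match: for a numeric window `w`, the `w/2` nt immediately 5' and `w/2`
#' nt immediately 3' of the matched span (the match itself excluded),
#' clamped at the fragment ends with the denominator equal to the number
#' of residues actually included. `window = "whole"` uses the entire
#' fragment, match included.
#'
#' @param fragment_seq Insert sequence (5'->3').
#' @param site One site row (fragment coordinates, 0-based half-open), or
#'   `NULL` when `window = "whole"`.
#' @param window One of 50, 100, 200, 300 or `"whole"`.
#' @return Percentage in \[0, 100\].
#' @export
au_percent <- function(fragment_seq, site = NULL, window = "whole") {
  seq <- normalize_rna(fragment_seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (identical(window, "whole")) {
    return(100 * mean(chars %in% c("A", "U")))
  }
  w <- as.integer(window)
  stopifnot(!is.null(site), w > 0L, w %% 2L == 0L)
  s <- site$start[1]; e <- site$end[1]
  stopifnot(s >= 0L, e <= n, e > s)
  up <- seq_len(w %/% 2L)
  pos5 <- s - up          # 0-based, immediately 5'
  pos3 <- e + up - 1L     # immediately 3'
  pos <- c(pos5, pos3)
  pos <- pos[pos >= 0L & pos < n]
  if (length(pos) == 0L) return(NA_real_)
  100 * mean(chars[pos + 1L] %in% c("A", "U"))
}

#' Distance-weighted local AU content of a site
#'
#' Scores the 30-nt windows flanking the matched site: each flanking
#' residue contributes weight 1/d (d = 1-based distance from the site
#' boundary), counting 1 if the residue is A or U and 0 otherwise; the
#' score is the weighted AU fraction over the positions actually present
#' (clamped windows renormalize over included weights). For 8mer and
#' 7mer-A1 sites the matched span already contains the A opposite miRNA
#' position 1, so the downstream window naturally starts after it. A
#' proxy for site accessibility: 1 is maximally AU-rich context, 0
#' maximally GC.
#'
#' @param fragment_seq Insert sequence.
#' @param site One site row (fragment coordinates).
#' @param seed_type The site's seed type; `"else"` returns `NA`.
#' @param flank Window length on each side in nt (default 30).
#' @return Score in \[0, 1\], or `NA` for non-canonical sites.
#' @export
local_au <- function(fragment_seq, site, seed_type = site$seed_type[1],
                     flank = 30L) {
  if (is.na(seed_type) || !seed_type %in% c("8mer", "7mer-m8", "7mer-A1", "6mer")) {
    return(NA_real_)
  }
  seq <- normalize_rna(fragment_seq)
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  s <- site$start[1]; e <- site$end[1]
  d <- seq_len(flank)
  pos <- c(s - d, e + d - 1L)
  wt <- c(1 / d, 1 / d)
  keep <- pos >= 0L & pos < n
  if (!any(keep)) return(NA_real_)
  au <- chars[pos[keep] + 1L] %in% c("A", "U")
  sum(wt[keep] * au) / sum(wt[keep])
}

# ---- free-energy operators ------------------------------------------------

#' Minimum free energy of RNA secondary structure
#'
#' Folds a single strand under the package's nearest-neighbor model
#' (see [thermo_params()]): Watson-Crick + GU stacks, hairpin loops of at
#' least 3 nt with tabulated initiation, affine bulge/internal penalties
#' and a linear multibranch penalty; pseudoknot-free, dangles ignored.
#' The open chain scores 0, so the result is always <= 0. Sequences too
#' short to close a hairpin (under 7 nt) return 0.
#'
#' For users with an external folding tool, [attach_external_dg()] swaps
#' in externally computed energies downstream; this function is the
#' package's self-contained model.
#'
#' @param seq RNA sequence.
#' @param par Parameter block from [thermo_params()].
#' @return MFE in kcal/mol (<= 0).
#' @export
structure_dg <- function(seq, par = thermo_params()) {
  b <- .base_idx(seq)
  if (length(b) < par$min_hairpin + 4L) return(0)
  .structure_mfe_c(b, as.numeric(par$stack), as.integer(par$pairable),
                   par$hairpin, par$hairpin_lnslope, par$bulge_a, par$bulge_b,
                   par$ml_init, par$ml_branch, as.integer(par$min_hairpin),
                   as.integer(par$max_loop))
}

# energy of one explicit duplex matching; pairs: matrix cols (i, j), i
# ascending / j descending, 1-based. Shared scorer for the enumeration
# oracle; independent of the DP recurrences.
.score_duplex <- function(a, b, pairs, par) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  term <- function(r) {
    if (.is_au_gu(a[pairs[r, 1]], b[pairs[r, 2]])) par$terminal_au else 0
  }
  e <- par$duplex_init + term(1L) + term(nrow(pairs))
  if (nrow(pairs) > 1L) {
    for (r in seq_len(nrow(pairs) - 1L)) {
      i1 <- pairs[r, 1]; j1 <- pairs[r, 2]
      i2 <- pairs[r + 1L, 1]; j2 <- pairs[r + 1L, 2]
      if (i2 == i1 + 1L && j2 == j1 - 1L) {
        e <- e + par$stack[a[i1], b[j1], a[i2], b[j2]]
      } else {
        e <- e + par$bulge_a + par$bulge_b * ((i2 - i1 - 1L) + (j1 - j2 - 1L))
      }
    }
  }
  e
}

#' Hybridization free energy of a miRNA:MRE duplex
#'
#' Minimum free energy over intermolecular duplexes (no intramolecular
#' pairs) between the miRNA (5'->3') and a target region (5'->3'), by
#' dynamic programming: Watson-Crick + GU pairs, nearest-neighbor stacks,
#' affine bulge/internal penalties, duplex initiation +4.09 kcal/mol and a
#' +0.45 terminal penalty per AU/GU duplex end; dangling ends are free.
#' If no favorable duplex exists the result is 0 (no duplex formed).
#'
#' @param mirna A `mirna_spec` or sequence string.
#' @param mre_region Target region sequence.
#' @param par Parameter block from [thermo_params()].
#' @return Duplex MFE in kcal/mol (<= 0).
#' @export
duplex_dg <- function(mirna, mre_region, par = thermo_params()) {
  a <- .base_idx(if (inherits(mirna, "mirna_spec")) mirna$sequence else mirna)
  b <- .base_idx(mre_region)
  n <- length(a); m <- length(b)
  ok <- outer(a, b, function(x, y) par$pairable[cbind(x, y)])
  if (!any(ok)) return(0)
  termpen <- outer(a, b, function(x, y) ifelse(.is_au_gu(x, y),
                                               par$terminal_au, 0))
  bb <- par$bulge_b
  # f[i, j]: best energy of a duplex whose 3'-most (on the miRNA) pair is
  # (i, j), including initiation and the first-end terminal penalty.
  # Affine interior gaps are separable, so extension from any earlier pair
  # reduces to a running minimum of g = f + bb*j2 - bb*i2; the adjacent
  # predecessor additionally offers its stack term (always better than a
  # zero-length "gap", since bulge_a exceeds every stack energy).
  f <- matrix(Inf, n, m)
  gap_min <- rep(Inf, m + 1L)  # over rows < i: min_{j2 >= j} g[i2, j2]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (!ok[i, j]) next
      best <- par$duplex_init + termpen[i, j]
      if (i > 1L) {
        if (j < m && is.finite(f[i - 1L, j + 1L])) {
          cand <- f[i - 1L, j + 1L] + par$stack[a[i - 1L], b[j + 1L], a[i], b[j]]
          if (cand < best) best <- cand
        }
        if (j < m && is.finite(gap_min[j + 1L])) {
          cand <- gap_min[j + 1L] + par$bulge_a - 2 * bb + bb * i - bb * j
          if (cand < best) best <- cand
        }
      }
      f[i, j] <- best
    }
    g <- f[i, ] + bb * seq_len(m) - bb * i
    suf <- rev(cummin(rev(g)))
    gap_min[seq_len(m)] <- pmin(gap_min[seq_len(m)], suf)
  }
  fin <- f + termpen
  min(0, min(fin[is.finite(f)]))
}

#' Reference duplex energy by exhaustive enumeration
#'
#' Enumerates every monotone co-pairing between the two strands (each
#' position used at most once, pairs non-crossing in the antiparallel
#' duplex sense), scores each with the model's loop/stack rules and
#' returns the minimum (or 0 for no duplex). Exponential; intended for
#' validating [duplex_dg()] on short sequences.
#'
#' @inheritParams duplex_dg
#' @return Duplex MFE in kcal/mol.
#' @export
duplex_dg_enum <- function(mirna, mre_region, par = thermo_params()) {
  a <- .base_idx(if (inherits(mirna, "mirna_spec")) mirna$sequence else mirna)
  b <- .base_idx(mre_region)
  n <- length(a); m <- length(b)
  best <- 0
  # depth-first over pairs (i, j): next pair must have larger i, smaller j
  rec <- function(pairs, i_min, j_max) {
    if (nrow(pairs) > 0L) {
      e <- .score_duplex(a, b, pairs, par)
      if (e < best) best <<- e
    }
    if (i_min > n || j_max < 1L) return(invisible())
    for (i in i_min:n) {
      for (j in seq_len(j_max)) {
        if (par$pairable[a[i], b[j]]) {
          rec(rbind(pairs, c(i, j)), i + 1L, j - 1L)
        }
      }
    }
  }
  rec(matrix(integer(), 0L, 2L), 1L, m)
  best
}

# all legal pair sets (non-crossing, hairpin >= min loop) on s[from..to]
.enum_pairsets <- function(bidx, from, to, pairable, min_hairpin) {
  if (from >= to) return(list(matrix(integer(), 0L, 2L)))
  # structures where `from` is unpaired
  out <- .enum_pairsets(bidx, from + 1L, to, pairable, min_hairpin)
  for (k in (from + min_hairpin + 1L):to) {
    if (k > to) break
    if (!pairable[bidx[from], bidx[k]]) next
    inner <- .enum_pairsets(bidx, from + 1L, k - 1L, pairable, min_hairpin)
    outer_ <- .enum_pairsets(bidx, k + 1L, to, pairable, min_hairpin)
    for (x in inner) for (y in outer_) {
      out[[length(out) + 1L]] <- rbind(c(from, k), x, y)
    }
  }
  out
}

# energy of one explicit secondary structure (pair set) under the model;
# loop decomposition computed from scratch, independent of the DP.
.score_structure <- function(bidx, pairs, par) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(0)
  ord <- order(pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  np <- nrow(pairs)
  # parent of each pair = innermost enclosing pair
  parent <- rep(0L, np)
  for (p in seq_len(np)) {
    enclosing <- which(pairs[, 1] < pairs[p, 1] & pairs[, 2] > pairs[p, 2])
    if (length(enclosing)) {
      parent[p] <- enclosing[which.max(pairs[enclosing, 1])]
    }
  }
  e <- 0
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    kids <- which(parent == p)
    if (length(kids) == 0L) {
      e <- e + .hairpin_e(j - i - 1L, par)
    } else if (length(kids) == 1L) {
      k <- pairs[kids, 1]; l <- pairs[kids, 2]
      if (k == i + 1L && l == j - 1L) {
        e <- e + par$stack[bidx[i], bidx[j], bidx[k], bidx[l]]
      } else {
        e <- e + par$bulge_a + par$bulge_b * ((k - i - 1L) + (j - l - 1L))
      }
    } else {
      e <- e + par$ml_init + par$ml_branch * (length(kids) + 1L)
    }
  }
  e
}

#' Reference folding energy by exhaustive structure enumeration
#'
#' Enumerates every pseudoknot-free structure respecting the minimum
#' hairpin loop, scores each by its loop decomposition under the model,
#' and returns the minimum (open chain = 0). Exponential; intended for
#' validating [structure_dg()] on short sequences.
#'
#' @inheritParams structure_dg
#' @return MFE in kcal/mol.
#' @export
structure_dg_enum <- function(seq, par = thermo_params()) {
  bidx <- .base_idx(seq)
  n <- length(bidx)
  if (n < par$min_hairpin + 2L) return(0)
  sets <- .enum_pairsets(bidx, 1L, n, par$pairable, par$min_hairpin)
  min(0, vapply(sets, function(p) .score_structure(bidx, p, par), numeric(1)))
}

#' Seed-pairing stability of a miRNA
#'
#' The duplex free energy of the 7-nt seed (miRNA nt 2-8) hybridized to
#' its perfect RNA complement, initiation and terminal penalties included;
#' more negative means a more stable seed duplex.
#'
#' @param mirna A `mirna_spec` or miRNA sequence.
#' @param par Parameter block from [thermo_params()].
#' @return SPS in kcal/mol.
#' @export
seed_pairing_stability <- function(mirna, par = thermo_params()) {
  seed <- if (inherits(mirna, "mirna_spec")) mirna$seed else derive_seed(mirna)
  duplex_dg(seed, reverse_complement(seed), par = par)
}

# ---- per-construct feature vectors ----------------------------------------

.AU_WINDOWS <- c("50", "100", "200", "300", "whole")

#' Sequence and thermodynamic features of reporter constructs
#'
#' Computes, for each construct, the windowed AU percentages, the
#' distance-weighted local AU content, the secondary-structure MFE of each
#' AU window and of the whole insert, the miRNA:MRE hybridization energy,
#' and the miRNA's seed-pairing stability. Multi-site constructs average
#' site-level features over their sites; the construct's seed type is the
#' highest-precedence type among its sites. Structure energies for the
#' numeric windows are folded on the same windowed subsequences used for
#' AU% (match included between the flanks).
#'
#' @param constructs List of `reporter_construct` objects (each with a
#'   `sites` tibble in fragment coordinates).
#' @param mirna A `mirna_spec`.
#' @param par Parameter block from [thermo_params()].
#' @param windows AU/structure window sizes (default 50/100/200/300/whole).
#' @param external_dg Optional data frame (construct_id, dg_structure)
#'   replacing the whole-insert folding energy with externally computed
#'   values (see [attach_external_dg()]).
#' @return A tibble, one row per construct: `construct_id`, `au_pct_50` ..
#'   `au_pct_whole`, `local_au`, `dg_structure_50` .. `dg_structure_whole`,
#'   `dg_duplex`, `sps`, `seed_type`.
#' @export
compute_features <- function(constructs, mirna, par = thermo_params(),
                             windows = .AU_WINDOWS, external_dg = NULL) {
  sps <- seed_pairing_stability(mirna, par = par)
  rows <- lapply(constructs, function(con) {
    frag <- con$fragment_seq
    sites <- con$sites
    canonical <- sites[sites$seed_type %in% c("8mer", "7mer-m8", "7mer-A1", "6mer"), ,
                       drop = FALSE]
    one_site <- function(fun) {
      if (nrow(canonical) == 0L) return(NA_real_)
      mean(vapply(seq_len(nrow(canonical)), function(k) fun(canonical[k, ]),
                  numeric(1)), na.rm = TRUE)
    }
    au <- vapply(windows, function(w) {
      if (identical(w, "whole")) au_percent(frag, window = "whole")
      else one_site(function(s) au_percent(frag, s, window = w))
    }, numeric(1))
    dg_str <- vapply(windows, function(w) {
      if (identical(w, "whole")) structure_dg(frag, par = par)
      else one_site(function(s) {
        structure_dg(.window_seq(frag, s, as.integer(w)), par = par)
      })
    }, numeric(1))
    lau <- one_site(function(s) local_au(frag, s, s$seed_type[1]))
    dgd <- one_site(function(s) {
      duplex_dg(mirna, .mre_context(frag, s), par = par)
    })
    seed_type <- if (nrow(canonical)) {
      .SEED_TYPES[min(match(canonical$seed_type, .SEED_TYPES))]
    } else "else"
    c(list(construct_id = con$gene_id),
      setNames(as.list(au), paste0("au_pct_", windows)),
      list(local_au = lau),
      setNames(as.list(dg_str), paste0("dg_structure_", windows)),
      list(dg_duplex = dgd, sps = sps, seed_type = seed_type))
  })
  out <- tibble::as_tibble(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))))
  if (!is.null(external_dg)) out <- attach_external_dg(out, external_dg)
  out
}

# the w/2-flanked subsequence around a site (match included), clamped
.window_seq <- function(frag, site, w) {
  n <- nchar(frag)
  s <- max(0L, site$start[1] - w %/% 2L)
  e <- min(n, site$end[1] + w %/% 2L)
  substr(frag, s + 1L, e)
}

# MRE plus a short flank, the region offered to the hybridization DP
.mre_context <- function(frag, site, flank = 10L) {
  n <- nchar(frag)
  s <- max(0L, site$start[1] - flank)
  e <- min(n, site$end[1] + flank)
  substr(frag, s + 1L, e)
}

#' Attach externally computed folding energies
#'
#' Replaces the whole-insert `dg_structure_whole` column of a feature
#' table with values from an external folding tool, for users who prefer
#' a full-parameter implementation over the embedded model.
#'
#' @param features Feature tibble from [compute_features()].
#' @param external_dg Data frame with columns `construct_id`,
#'   `dg_structure`.
#' @return The feature tibble with substituted energies (constructs absent
#'   from `external_dg` keep the embedded model's value).
#' @export
attach_external_dg <- function(features, external_dg) {
  stopifnot(all(c("construct_id", "dg_structure") %in% names(external_dg)))
  i <- match(features$construct_id, external_dg$construct_id)
  repl <- !is.na(i)
  features$dg_structure_whole[repl] <- external_dg$dg_structure[i[repl]]
  features
}
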