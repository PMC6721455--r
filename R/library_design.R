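#' Group nearby seed sites into clusters
#'
#' Reporter inserts are designed around a single miRNA response element
#' (MRE), except when all predicted sites fall close together, in which
#' case one insert carries the whole cluster. Sites (sorted by start) are
#' grouped greedily left to right; a site joins the open group as long as
#' the group's span (last end minus first start) stays within `max_span`.
#'
#' @param sites A site tibble (columns `start`, `end`), sorted by `start`.
#' @param max_span Maximum cluster span in nt (default 300).
#' @return A list of site tibbles, one per group.
#' @export
cluster_sites <- function(sites, max_span = 300L) {
  if (nrow(sites) == 0L) return(list())
  if (is.unsorted(sites$start)) {
    stop("sites must be sorted by start", call. = FALSE)
  }
  groups <- list()
  first_start <- sites$start[1]
  open <- 1L
  for (i in seq_len(nrow(sites))[-1]) {
    if (sites$end[i] - first_start <= max_span) {
      open <- c(open, i)
    } else {
      groups[[length(groups) + 1L]] <- sites[open, ]
      open <- i
      first_start <- sites$start[i]
    }
  }
  groups[[length(groups) + 1L]] <- sites[open, ]
  groups
}

#' Select the reporter insert for a site group
#'
#' A singleton group yields a window of `target_len` nt with the site in
#' the middle (even flanks, floor/ceil split around the site). A
#' multi-site group yields the window from `cluster_flank` nt 5' of the
#' first site to `cluster_flank` nt 3' of the last site. Windows
#' overhanging the UTR are shifted to fit where possible, then truncated
#' to the UTR; the fragment always contains every site of the group.
#'
#' @param utr UTR sequence (5'->3').
#' @param group A site tibble (one cluster from [cluster_sites()]).
#' @param target_len Singleton insert length in nt (default 500).
#' @param cluster_flank Flank for multi-site clusters in nt (default 240).
#' @param gene_id,utr_id Identifiers carried into the construct.
#' @return A list of class `reporter_construct` with fields `gene_id`,
#'   `utr_id`, `fragment_start`, `fragment_end` (0-based half-open on the
#'   UTR), `fragment_seq`, and `sites` (coordinates relative to the
#'   fragment).
#' @export
select_fragment <- function(utr, group, target_len = 500L, cluster_flank = 240L,
                            gene_id = "gene", utr_id = "utr") {
  utr <- normalize_rna(utr)
  n <- nchar(utr)
  if (is.null(group) || nrow(group) == 0L) {
    stop("empty site group", call. = FALSE)
  }
  if (nrow(group) == 1L) {
    site_len <- group$end[1] - group$start[1]
    start <- group$start[1] - (target_len - site_len) %/% 2L
    start <- min(start, n - target_len)
    start <- max(start, 0L)
    end <- min(start + target_len, n)
  } else {
    start <- max(group$start[1] - cluster_flank, 0L)
    end <- min(group$end[nrow(group)] + cluster_flank, n)
  }
  start <- as.integer(start); end <- as.integer(end)
  frag_sites <- group
  frag_sites$start <- group$start - start
  frag_sites$end <- group$end - start
  stopifnot(all(frag_sites$start >= 0L), all(frag_sites$end <= end - start))
  structure(
    list(gene_id = gene_id, utr_id = utr_id,
         fragment_start = as.integer(start), fragment_end = as.integer(end),
         fragment_seq = substr(utr, start + 1L, end),
         sites = frag_sites),
    class = "reporter_construct"
  )
}

#' @export
print.reporter_construct <- function(x, ...) {
  cat("<reporter_construct> ", x$gene_id, " [", x$fragment_start, ",",
      x$fragment_end, ") ", nrow(x$sites), " site(s)\n", sep = "")
  invisible(x)
}

#' Screen an insert for internal NheI/XhoI recognition sites
#'
#' Inserts are cloned via NheI and XhoI, so fragments whose DNA rendering
#' contains an internal GCTAGC (NheI) or CTCGAG (XhoI) are excluded from
#' the library.
#'
#' @param fragment_seq Insert sequence (RNA or DNA letters).
#' @return A list with `pass` (logical) and `hits` (0-based offsets of
#'   recognition-site matches, named by enzyme).
#' @export
#' @examples
#' screen_restriction("AAAAAA")$pass          # TRUE
#' screen_restriction("AACUCGAGAA")$pass      # FALSE (XhoI, RNA rendering)
screen_restriction <- function(fragment_seq) {
  dna <- chartr("U", "T", normalize_rna(fragment_seq))
  find_all <- function(pat) {
    out <- integer(); from <- 1L
    repeat {
      i <- regexpr(pat, substr(dna, from, nchar(dna)), fixed = TRUE)
      if (i < 0L) break
      out <- c(out, from + i - 2L)  # 0-based
      from <- from + i
    }
    out
  }
  hits <- c(setNames(find_all("GCTAGC"), rep("NheI", length(find_all("GCTAGC")))),
            setNames(find_all("CTCGAG"), rep("XhoI", length(find_all("CTCGAG")))))
  list(pass = length(hits) == 0L, hits = hits)
}

#' Design reporter constructs for one UTR
#'
#' Scans the UTR for seed sites, clusters them, selects one insert per
#' cluster and applies the restriction screen. Constructs failing the
#' screen are returned with `pass_restriction = FALSE` and must not enter
#' downstream stages.
#'
#' @inheritParams select_fragment
#' @param mirna A `mirna_spec`.
#' @param max_span Cluster span limit passed to [cluster_sites()].
#' @return A list of `reporter_construct` objects, each with an added
#'   `pass_restriction` flag.
#' @export
design_constructs <- function(utr, mirna, gene_id = "gene", utr_id = "utr",
                              target_len = 500L, cluster_flank = 240L,
                              max_span = 300L) {
  sites <- find_seed_sites(utr, mirna, utr_id = utr_id)
  groups <- cluster_sites(sites, max_span = max_span)
  lapply(seq_along(groups), function(k) {
    con <- select_fragment(utr, groups[[k]], target_len = target_len,
                           cluster_flank = cluster_flank,
                           gene_id = if (length(groups) > 1L)
                             paste0(gene_id, ".", k) else gene_id,
                           utr_id = utr_id)
    con$pass_restriction <- screen_restriction(con$fragment_seq)$pass
    con
  })
}

#' Construct manifest table
#'
#' @param constructs List of `reporter_construct` objects.
#' @return A tibble (gene_id, utr_id, start, end, n_sites, pass_restriction).
#' @export
construct_manifest <- function(constructs) {
  tibble::tibble(
    gene_id = vapply(constructs, `[[`, character(1), "gene_id"),
    utr_id = vapply(constructs, `[[`, character(1), "utr_id"),
    start = vapply(constructs, `[[`, integer(1), "fragment_start"),
    end = vapply(constructs, `[[`, integer(1), "fragment_end"),
    n_sites = vapply(constructs, function(x) nrow(x$sites), integer(1)),
    pass_restriction = vapply(constructs, function(x)
      isTRUE(x$pass_restriction), logical(1))
  )
}
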