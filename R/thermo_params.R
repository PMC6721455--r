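## Nearest-neighbor free-energy parameters (kcal/mol, 37 C).
##
## One embedded Turner-style table: Watson-Crick and wobble (GU) stacks,
## tabulated hairpin-loop initiation with logarithmic extrapolation, affine
## bulge/internal-loop penalties, a linear multibranch penalty, duplex
## initiation and terminal AU/GU penalties. The two free-energy operators
## (structure_dg, duplex_dg) are self-consistent approximations under this
## one parameter block; exact parity with any external folding tool is not
## promised, and an external-energy adapter is provided for users who have
## one.

.BASES <- c("A", "C", "G", "U")

# Independent stack motifs 5'x1x2/3'y1y2, pairs p = x1:y1, q = x2:y2.
# Remaining entries are filled by the duplex rotational symmetry
# E(p, q) = E(rev(q), rev(p)).
.STACK_MOTIFS <- list(
  # Watson-Crick / Watson-Crick
  c("AU", "AU", -0.93), c("AU", "UA", -1.10), c("AU", "CG", -2.24),
  c("AU", "GC", -2.08), c("UA", "AU", -1.33), c("UA", "CG", -2.35),
  c("UA", "GC", -2.11), c("CG", "AU", -2.11), c("CG", "CG", -3.26),
  c("CG", "GC", -2.36), c("GC", "AU", -2.35), c("GC", "CG", -3.42),
  # wobble-containing
  c("AU", "GU", -0.55), c("AU", "UG", -1.36), c("CG", "GU", -1.41),
  c("CG", "UG", -2.11), c("GC", "GU", -1.53), c("GC", "UG", -2.51),
  c("UA", "GU", -1.00), c("GU", "AU", -1.27), c("GU", "GU", -0.50),
  c("GU", "UG", -0.55), c("UG", "GU", +0.47)
)

.build_stack_array <- function() {
  arr <- array(Inf, dim = c(4, 4, 4, 4),
               dimnames = list(.BASES, .BASES, .BASES, .BASES))
  put <- function(p, q, e) {
    x1 <- substr(p, 1, 1); y1 <- substr(p, 2, 2)
    x2 <- substr(q, 1, 1); y2 <- substr(q, 2, 2)
    old <- arr[x1, y1, x2, y2]
    if (is.finite(old) && abs(old - e) > 1e-9) {
      stop("inconsistent stack table at ", p, "/", q)
    }
    arr[x1, y1, x2, y2] <<- e
  }
  rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (m in .STACK_MOTIFS) {
    e <- as.numeric(m[3])
    put(m[1], m[2], e)
    put(rev_pair(m[2]), rev_pair(m[1]), e)
  }
  arr
}

.PAIRABLE <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(.BASES, .BASES))
  for (p in c("AU", "UA", "CG", "GC", "GU", "UG")) {
    m[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  }
  m
})

#' Nearest-neighbor energy parameters
#'
#' Returns the package's embedded 37 C free-energy parameter block used by
#' [structure_dg()], [duplex_dg()] and [seed_pairing_stability()]. Fields
#' can be overridden for sensitivity analyses, but the defaults are the
#' documented model.
#'
#' @param ... Named overrides of individual parameters.
#' @return A list with components `stack` (4x4x4x4 array of stack free
#'   energies, Inf where either pair is not AU/UA/CG/GC/GU/UG), `pairable`
#'   (4x4 logical), `hairpin` (initiation for loop sizes 3-9),
#'   `hairpin_lnslope` (log-extrapolation slope beyond size 9),
#'   `bulge_a`/`bulge_b` (affine bulge/internal penalty a + b * unpaired),
#'   `ml_init`/`ml_branch` (multibranch offset and per-helix term),
#'   `duplex_init` (+4.09 duplex initiation), `terminal_au` (+0.45 per
#'   AU/GU helix end of a duplex), `min_hairpin` (3) and `max_loop`
#'   (internal-loop size cap for the folding DP, 30).
#' @export
thermo_params <- function(...) {
  par <- list(
    stack = .build_stack_array(),
    pairable = .PAIRABLE,
    hairpin = c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4),  # sizes 3..9
    hairpin_lnslope = 1.0785,
    bulge_a = 3.0, bulge_b = 0.5,
    ml_init = 3.4, ml_branch = 0.4,
    duplex_init = 4.09, terminal_au = 0.45,
    min_hairpin = 3L, max_loop = 30L
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(all(names(dots) %in% names(par)))
    par[names(dots)] <- dots
  }
  par
}

# sequence string -> 1..4 base indices
.base_idx <- function(seq) {
  match(strsplit(normalize_rna(seq), "", fixed = TRUE)[[1]], .BASES)
}

.hairpin_e <- function(size, par) {
  if (size < par$min_hairpin) return(Inf)
  if (size <= 9L) return(par$hairpin[size - 2L])
  par$hairpin[7L] + par$hairpin_lnslope * log(size / 9)
}

.is_au_gu <- function(x, y) {
  (x == 1L & y == 4L) | (x == 4L & y == 1L) |
    (x == 3L & y == 4L) | (x == 4L & y == 3L)
}
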