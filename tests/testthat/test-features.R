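one_site <- function(start, end, type = "7mer-m8") {
  tibble::tibble(utr_id = "u", start = as.integer(start),
                 end = as.integer(end), seed_type = type,
                 matched_seq = NA_character_)
}

test_that("AU percentage windows exclude the match and clamp denominators", {
  frag <- strrep("A", 200)
  expect_equal(au_percent(frag, window = "whole"), 100)
  expect_equal(au_percent(frag, one_site(96, 103), window = 50), 100)
  # 25 nt of A 5' and 25 nt of G 3' around an 8-nt site
  frag2 <- paste0(strrep("G", 50), strrep("A", 25), strrep("C", 8),
                  strrep("G", 25), strrep("G", 50))
  expect_equal(au_percent(frag2, one_site(75, 83), window = 50), 50)
  # site at offset 10: only 10 nt exist 5', denominator 10 + 25 = 35
  frag3 <- paste0(strrep("A", 10), strrep("C", 8), strrep("G", 482))
  expect_equal(au_percent(frag3, one_site(10, 18), window = 50), 100 * 10 / 35)
  # whole-window value is the plain AU fraction
  set.seed(3)
  frag4 <- rand_rna(120)
  chars <- strsplit(frag4, "")[[1]]
  expect_equal(au_percent(frag4, window = "whole"),
               100 * mean(chars %in% c("A", "U")))
})

test_that("replacing flank AU with GC never increases AU features", {
  set.seed(14)
  for (k in 1:10) {
    frag <- rand_rna(150)
    site <- one_site(70, 77)
    chars <- strsplit(frag, "")[[1]]
    au_pos <- which(chars %in% c("A", "U") & (seq_along(chars) < 71 |
                                                seq_along(chars) > 77))
    if (length(au_pos) == 0) next
    chars[sample(au_pos, 1)] <- "G"
    frag2 <- paste(chars, collapse = "")
    for (w in c(50, 100, "whole")) {
      expect_lte(au_percent(frag2, site, window = w),
                 au_percent(frag, site, window = w))
    }
    expect_lte(local_au(frag2, site), local_au(frag, site))
  }
})

test_that("local AU content is the 1/d-weighted flank score", {
  # all-AU flanks -> 1, all-GC flanks -> 0
  fragAU <- paste0(strrep("U", 40), strrep("C", 7), strrep("A", 40))
  expect_equal(local_au(fragAU, one_site(40, 47)), 1)
  fragGC <- paste0(strrep("G", 40), strrep("A", 7), strrep("C", 40))
  expect_equal(local_au(fragGC, one_site(40, 47)), 0)
  # a single U at distance 1 upstream, G elsewhere: 1 / (2 * H_30)
  chars <- rep("G", 100)
  chars[40] <- "U"  # 0-based position 39 = distance 1 from site start 40
  frag <- paste(chars, collapse = "")
  h30 <- sum(1 / (1:30))
  expect_equal(local_au(frag, one_site(40, 47)), 1 / (2 * h30),
               tolerance = 1e-12)
  expect_equal(1 / (2 * h30), 0.1251568, tolerance = 1e-6)
  # undefined for non-canonical sites
  expect_true(is.na(local_au(frag, one_site(40, 47, type = "else"))))
})

test_that("folding returns 0 for unpairable or too-short sequences", {
  expect_equal(structure_dg("AAAAAAAAAA"), 0)
  expect_equal(structure_dg("ACGUAC"), 0)   # < 7 nt cannot close a hairpin
  expect_lt(structure_dg("GGGGGAAAACCCCC"), 0)
})

test_that("folding DP equals exhaustive structure enumeration", {
  set.seed(21)
  for (k in 1:60) {
    s <- rand_rna(sample(4:11, 1))
    expect_equal(structure_dg(s), structure_dg_enum(s), tolerance = 1e-9)
  }
})

test_that("folding energy never increases when the sequence is extended", {
  set.seed(22)
  for (k in 1:15) {
    x <- rand_rna(sample(10:40, 1))
    y <- paste0(x, rand_rna(5))
    expect_lte(structure_dg(y), structure_dg(x) + 1e-9)
  }
})

test_that("duplex DP equals exhaustive co-pairing enumeration", {
  set.seed(23)
  for (k in 1:120) {
    a <- rand_rna(sample(1:7, 1))
    b <- rand_rna(sample(1:7, 1))
    expect_equal(duplex_dg(a, b), duplex_dg_enum(a, b), tolerance = 1e-9)
  }
})

test_that("duplex energy is zero without complementarity and minimal at full pairing", {
  expect_equal(duplex_dg("GGGG", "AAAA"), 0)
  set.seed(24)
  for (k in 1:10) {
    a <- rand_rna(7)
    opt <- duplex_dg(a, reverse_complement(a))
    for (j in 1:15) {
      expect_lte(opt, duplex_dg(a, rand_rna(7)) + 1e-9)
    }
  }
})

test_that("duplex energy is symmetric under strand role exchange", {
  set.seed(25)
  for (k in 1:20) {
    a <- rand_rna(sample(3:8, 1)); b <- rand_rna(sample(3:8, 1))
    # swapping which strand is "top" re-reads the same duplex rotated 180
    # degrees; the rotational symmetry of the stack table makes it exact
    expect_equal(duplex_dg(a, b), duplex_dg(b, a), tolerance = 1e-9)
  }
})

test_that("seed-pairing stability is the seed:complement duplex energy", {
  set.seed(26)
  for (k in 1:10) {
    m <- gen_mirna()
    expect_equal(seed_pairing_stability(m),
                 duplex_dg(m$seed, reverse_complement(m$seed)))
  }
  # maximal stacking: poly-G seed is the most stable 7-mer seed we can draw
  polyg <- seed_pairing_stability(mirna_spec("pg", paste0("A", strrep("G", 7),
                                                          strrep("A", 14))))
  for (k in 1:20) {
    expect_lte(polyg, seed_pairing_stability(gen_mirna()) + 1e-9)
  }
})

test_that("per-construct feature vectors assemble and average over sites", {
  set.seed(27)
  m <- mir1()
  g <- gen_utr_with_sites(m, c("8mer", "7mer-m8"), positions = c(600, 700))
  con <- select_fragment(g$utr, g$sites, gene_id = "G1")
  con$pass_restriction <- TRUE
  f <- compute_features(list(con), m)
  expect_identical(nrow(f), 1L)
  expect_identical(f$seed_type, "8mer")  # highest precedence among sites
  expect_true(all(c("au_pct_50", "au_pct_whole", "local_au",
                    "dg_structure_whole", "dg_duplex", "sps") %in% names(f)))
  expect_equal(f$sps, seed_pairing_stability(m))
  manual <- mean(c(au_percent(con$fragment_seq, con$sites[1, ], 50),
                   au_percent(con$fragment_seq, con$sites[2, ], 50)))
  expect_equal(f$au_pct_50, manual)
  expect_lte(f$dg_structure_whole, 0)
  # external energies substitute the whole-insert fold
  f2 <- attach_external_dg(f, data.frame(construct_id = "G1",
                                         dg_structure = -123.4))
  expect_equal(f2$dg_structure_whole, -123.4)
})
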