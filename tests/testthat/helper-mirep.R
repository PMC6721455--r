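# shared helpers for the mirep test suite

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

mir1 <- function() mirna_spec("miR-1", "UGGAAUGUAAAGAAGUAUGUAU")
mir122 <- function() mirna_spec("miR-122", "UGGAGUGUGACAAUGGUGUUUG")
mir124 <- function() mirna_spec("miR-124", "UAAGGCACGCGGUGAAUGCCA")

# Published confirmation-summary counts (selected, confirmed, printed ratio)
# for the three miRNA screens, as printed; plus the exclusive-region Venn
# solution implied by the marginals where one exists.
table1_printed <- list(
  "miR-1" = data.frame(
    category = c("TargetScan", "miRanda", "PicTar", "TargetScan only",
                 "miRanda only", "PicTar only", "All three", "miRTarBase",
                 "Single MRE", "Multiple MREs", "Total"),
    selected = c(165, 159, 84, 19, 28, 1, 64, 10, 171, 25, 196),
    confirmed = c(140, 129, 70, 17, 19, 1, 52, 10, 140, 22, 162),
    ratio = c(84.8, 81.1, 83.3, 89.5, 67.9, 100.0, 81.3, 100.0, 81.9, 88.0, 82.7)),
  "miR-122" = data.frame(
    category = c("TargetScan", "miRanda", "PicTar", "TargetScan only",
                 "miRanda only", "PicTar only", "All three", "miRTarBase",
                 "Single MRE", "Multiple MREs", "Total"),
    selected = c(149, 162, 57, 19, 42, 2, 43, 14, 181, 13, 194),
    confirmed = c(124, 134, 47, 17, 34, 2, 33, 13, 152, 11, 163),
    ratio = c(83.2, 82.7, 82.5, 89.5, 84.0, 100.0, 76.7, 92.9, 84.0, 84.6, 84.0)),
  "miR-124" = data.frame(
    category = c("TargetScan", "miRanda", "PicTar", "TargetScan only",
                 "miRanda only", "PicTar only", "All three", "miRTarBase",
                 "Single MRE", "Multiple MREs", "Total"),
    selected = c(174, 151, 104, 13, 9, 8, 67, 5, 166, 30, 196),
    confirmed = c(128, 109, 76, 11, 8, 6, 48, 5, 117, 28, 145),
    ratio = c(73.6, 72.2, 73.1, 84.6, 88.9, 75.0, 71.6, 100.0, 70.5, 93.3, 74.0))
)

# exclusive program-membership regions solving the printed marginals
table1_regions <- list(
  "miR-1" = list(
    selected = c("TargetScan only" = 19, "miRanda only" = 28, "PicTar only" = 1,
                 "TargetScan+miRanda" = 65, "TargetScan+PicTar" = 17,
                 "miRanda+PicTar" = 2, "All three" = 64),
    confirmed = c("TargetScan only" = 17, "miRanda only" = 19, "PicTar only" = 1,
                  "TargetScan+miRanda" = 56, "TargetScan+PicTar" = 15,
                  "miRanda+PicTar" = 2, "All three" = 52),
    mirtarbase = c(10L, 10L), multi_mre = c(25L, 22L)),
  "miR-122" = list(  # confirmed side infeasible; selected side only
    selected = c("TargetScan only" = 19, "miRanda only" = 42, "PicTar only" = 2,
                 "TargetScan+miRanda" = 76, "TargetScan+PicTar" = 11,
                 "miRanda+PicTar" = 1, "All three" = 43),
    mirtarbase = c(14L, 13L), multi_mre = c(13L, 11L)),
  "miR-124" = list(
    selected = c("TargetScan only" = 13, "miRanda only" = 9, "PicTar only" = 8,
                 "TargetScan+miRanda" = 70, "TargetScan+PicTar" = 24,
                 "miRanda+PicTar" = 5, "All three" = 67),
    confirmed = c("TargetScan only" = 11, "miRanda only" = 8, "PicTar only" = 6,
                  "TargetScan+miRanda" = 50, "TargetScan+PicTar" = 19,
                  "miRanda+PicTar" = 3, "All three" = 48),
    mirtarbase = c(5L, 5L), multi_mre = c(30L, 28L))
)
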