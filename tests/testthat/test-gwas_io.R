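# summary-stat IO, instrument selection, harmonisation

test_that("summary stats survive a write/read round trip field by field", {
  ss <- toy_ss(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_label = "EA")
  attr(back, "rejected") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(ss), tolerance = 1e-12)
  # fixed point: a second write/read changes nothing
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid rows are rejected with per-row reasons", {
  rec <- toy_records(6)
  rec$se[2] <- 0
  rec$pval[3] <- 0
  rec$ea[4] <- "AT"          # indel-like
  rec$snp[5] <- rec$snp[1]   # duplicate
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(ss <- read_summary_stats(path, trait_label = "EA"),
                 "dropped 4 row")
  expect_equal(nrow(ss), 2L)
  rej <- attr(ss, "rejected")
  expect_setequal(rej$reason,
                  c("nonpositive SE", "p-value outside (0,1]",
                    "invalid alleles (indel/multi-allelic or non-ACGT)",
                    "duplicate SNP id"))
  # the strict constructor refuses the same data outright
  expect_error(summary_stats(rec, "EA"), class = "twostepmr_input_error")
})

test_that("read handles column maps, csv, and error paths", {
  rec <- toy_records(3)
  names(rec) <- c("MarkerName", "CHR", "BP", "A1", "A2", "FRQ", "B", "SE",
                  "P", "N")
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(rec, path, sep = ",", quote = FALSE, row.names = FALSE)
  cm <- c(snp = "MarkerName", chr = "CHR", pos = "BP", ea = "A1", oa = "A2",
          eaf = "FRQ", beta = "B", se = "SE", pval = "P", n = "N")
  ss <- read_summary_stats(path, cm, trait_label = "EA")
  expect_equal(nrow(ss), 3L)
  expect_error(read_summary_stats(path, c(snp = "nope"), trait_label = "EA"),
               class = "twostepmr_config_error")
  # header-only file from an empty record set
  empty <- toy_ss(3)[0, ]
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(empty, p2)
  expect_length(readLines(p2), 1L)
  expect_error(read_summary_stats(p2, trait_label = "EA"),
               class = "twostepmr_input_error")
})

test_that("a large synthetic exposure-scale file survives intact", {
  ss <- toy_ss(1271, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_label = "EA")
  expect_equal(nrow(back), 1271L)
  expect_equal(back$beta, ss$beta, tolerance = 1e-12)
})

test_that("instrument selection filters by p and prunes greedily", {
  ss <- toy_ss(5)
  # independent SNPs, all significant: nothing pruned
  out <- select_instruments(ss, 5e-8, ld = NULL)
  expect_setequal(out$snp, ss$snp)
  # two correlated SNPs: only the smaller p survives
  rec <- toy_records(2)
  rec$pval <- c(1e-10, 1e-9)
  ss2 <- summary_stats(rec, "EA")
  ld <- ld_info(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  out2 <- select_instruments(ss2, 5e-8, ld, r2_threshold = 0.1)
  expect_identical(out2$snp, "rs1")
  # window: same pair farther apart than the window is kept
  rec$pos <- c(1, 5e6)
  ss3 <- summary_stats(rec, "EA")
  expect_setequal(select_instruments(ss3, 5e-8, ld, 0.1, window = 1e6)$snp,
                  c("rs1", "rs2"))
  expect_error(select_instruments(ss, 1e-20), class = "twostepmr_input_error")
})

test_that("greedy clumping matches the brute-force oracle and ignores row order", {
  for (seed in 1:5) {
    n <- 12L
    rec <- withr::with_seed(seed, {
      r <- toy_records(n, seed)
      r$pval <- 10^runif(n, -12, -6)   # some above threshold
      r
    })
    r2mat <- withr::with_seed(seed + 100, {
      m <- matrix(0, n, n, dimnames = list(rec$snp, rec$snp))
      idx <- which(upper.tri(m), arr.ind = TRUE)
      vals <- ifelse(runif(nrow(idx)) < 0.4, runif(nrow(idx)), 0)
      m[idx] <- vals; m[idx[, 2:1]] <- vals; diag(m) <- 1
      m
    })
    ld <- ld_info(r2mat, window = 1e6)
    got <- select_instruments(summary_stats(rec, "EA"), 5e-8, ld, 0.1)
    want <- oracle_greedy_clump(rec$snp, rec$pval, rec$pos, r2mat,
                                5e-8, 0.1, 1e6)
    expect_setequal(got$snp, want)
    shuffled <- withr::with_seed(seed, rec[sample.int(n), ])
    got2 <- select_instruments(summary_stats(shuffled, "EA"), 5e-8, ld, 0.1)
    expect_identical(got2$snp, got$snp)
  }
})

test_that("allele swaps flip the outcome beta and EAF", {
  exp_rec <- toy_records(1)
  exp_rec$ea <- "A"; exp_rec$oa <- "G"; exp_rec$beta <- 0.1; exp_rec$eaf <- 0.2
  out_rec <- exp_rec
  out_rec$ea <- "G"; out_rec$oa <- "A"; out_rec$beta <- 0.2; out_rec$eaf <- 0.8
  h <- harmonise(summary_stats(exp_rec, "EA"),
                 summary_stats(out_rec, "T2D"))
  expect_equal(h$outcome_beta, -0.2)
  expect_equal(h$outcome_eaf, 0.2)
  expect_equal(nrow(h$dropped), 0L)
  # complementary-strand swap behaves the same
  out_rec$ea <- "C"; out_rec$oa <- "T"
  h2 <- harmonise(summary_stats(exp_rec, "EA"), summary_stats(out_rec, "T2D"))
  expect_equal(h2$outcome_beta, -0.2)
})

test_that("palindromic SNPs are resolved by frequency or dropped", {
  base <- toy_records(2)
  base$ea <- c("A", "A"); base$oa <- c("T", "G")  # rs1 palindromic, rs2 not
  # ambiguous frequency in the closed [0.3, 0.7] (either trait): dropped
  for (f_out in c(0.45, 0.3, 0.7)) {
    e <- base; e$eaf <- c(0.1, 0.2)
    o <- base; o$eaf <- c(f_out, 0.2); o$beta <- c(0.2, 0.3)
    h <- harmonise(summary_stats(e, "EA"), summary_stats(o, "T2D"))
    expect_equal(h$dropped,
                 data.frame(snp = "rs1", reason = "ambiguous palindromic",
                            stringsAsFactors = FALSE))
    expect_identical(h$snp, "rs2")
  }
  # opposite-strand inference: frequencies on opposite sides of 0.5 flip
  e <- base[1, ]; e$ea <- "C"; e$oa <- "G"; e$eaf <- 0.10; e$beta <- 0.1
  o <- e; o$eaf <- 0.88; o$beta <- 0.2
  h <- harmonise(summary_stats(e, "EA"), summary_stats(o, "T2D"))
  expect_equal(h$outcome_beta, -0.2)
  expect_equal(h$outcome_eaf, 0.12)
  # same side of 0.5: kept as is
  o2 <- e; o2$eaf <- 0.12; o2$beta <- 0.2
  h2 <- harmonise(summary_stats(e, "EA"), summary_stats(o2, "T2D"))
  expect_equal(h2$outcome_beta, 0.2)
  # missing EAF on a palindromic SNP: cannot infer strand, dropped
  e3 <- base; e3$eaf <- c(0.1, 0.2)
  o3 <- base; o3$eaf <- c(NA, 0.2); o3$beta <- c(0.2, 0.3)
  h3 <- harmonise(summary_stats(e3, "EA"), summary_stats(o3, "T2D"))
  expect_equal(h3$dropped$reason, "ambiguous palindromic")
})

test_that("the frequency-agreement rule picks the |EAF| -minimising configuration", {
  # enumerate all strand/label configurations of a palindromic SNP: the
  # aligned outcome EAF must always be the one closest to the exposure EAF
  e <- toy_records(1); e$ea <- "A"; e$oa <- "T"; e$eaf <- 0.10; e$beta <- 0.1
  for (cfg in list(list(ea = "A", oa = "T", eaf = 0.12, flip = FALSE),
                   list(ea = "T", oa = "A", eaf = 0.88, flip = TRUE),
                   list(ea = "A", oa = "T", eaf = 0.89, flip = TRUE),
                   list(ea = "T", oa = "A", eaf = 0.11, flip = FALSE))) {
    o <- e; o$ea <- cfg$ea; o$oa <- cfg$oa; o$eaf <- cfg$eaf; o$beta <- 0.2
    h <- harmonise(summary_stats(e, "EA"), summary_stats(o, "T2D"))
    aligned_eaf <- h$outcome_eaf
    expect_lt(abs(aligned_eaf - 0.10), abs((1 - aligned_eaf) - 0.10))
    expect_equal(h$outcome_beta, if (cfg$flip) -0.2 else 0.2)
  }
})

test_that("irreconcilable allele pairs are dropped with a reason", {
  e <- toy_records(2); e$ea <- c("A", "A"); e$oa <- c("G", "G")
  o <- e; o$ea <- c("A", "A"); o$oa <- c("C", "G"); o$beta <- c(0.5, 0.2)
  h <- harmonise(summary_stats(e, "EA"), summary_stats(o, "T2D"))
  expect_equal(h$dropped$reason, "incompatible alleles")
  expect_identical(h$snp, "rs2")
})

test_that("harmonisation is idempotent on already-aligned inputs", {
  e <- toy_records(6, seed = 3)
  o <- toy_records(6, seed = 4)
  o$ea <- e$ea; o$oa <- e$oa; o$eaf <- e$eaf + 0.02
  h1 <- harmonise(summary_stats(e, "EA"), summary_stats(o, "T2D"))
  # rebuild summary stats from the harmonised output and re-harmonise
  rebuild <- function(beta, se, eaf, label) {
    summary_stats(data.frame(snp = h1$snp, ea = h1$effect_allele,
                             oa = h1$other_allele, eaf = eaf, beta = beta,
                             se = se, pval = 0.5, stringsAsFactors = FALSE),
                  label)
  }
  e2 <- rebuild(h1$exposure_beta[, 1], h1$exposure_se[, 1],
                h1$exposure_eaf[, 1], "EA")
  o2 <- rebuild(h1$outcome_beta, h1$outcome_se, h1$outcome_eaf, "T2D")
  h2 <- harmonise(e2, o2)
  expect_equal(h2$outcome_beta, h1$outcome_beta)
  expect_equal(h2$exposure_beta, h1$exposure_beta, ignore_attr = TRUE)
  expect_equal(nrow(h2$dropped), 0L)
})

test_that("harmonisation commutes with global strand complement of the outcome", {
  e <- toy_records(8, seed = 5)
  e$ea <- rep(c("A", "C"), 4); e$oa <- rep(c("G", "T"), 4)  # non-palindromic
  o <- e; o$beta <- rnorm(8); o$eaf <- e$eaf
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  o_flip <- o; o_flip$ea <- comp[o$ea]; o_flip$oa <- comp[o$oa]
  h1 <- harmonise(summary_stats(e, "EA"), summary_stats(o, "T2D"))
  h2 <- harmonise(summary_stats(e, "EA"), summary_stats(o_flip, "T2D"))
  expect_equal(h2$outcome_beta, h1$outcome_beta)
})

test_that("disjoint SNP sets raise a no-overlap error", {
  e <- toy_ss(3)
  o_rec <- toy_records(3); o_rec$snp <- paste0("rs", 100:102)
  expect_error(harmonise(e, summary_stats(o_rec, "T2D")),
               class = "twostepmr_no_overlap_error")
})

test_that("LD lookups are symmetric with unit diagonal", {
  ld <- ld_info(data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs3"),
                           r2 = c(0.5, 0.2)))
  expect_equal(ld_r2(ld, "rs1", c("rs1", "rs2", "rs3", "rs9")),
               c(1, 0.5, 0, 0))
  expect_equal(ld_r2(ld, "rs2", "rs1"), 0.5)
  # matrix input and file round trip
  m <- matrix(c(1, .3, .3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(snp = rownames(m), m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ld2 <- read_ld_info(path)
  expect_equal(ld_r2(ld2, "a", "b"), 0.3)
})
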