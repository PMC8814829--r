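# exhaustive per-offset site-scan oracle applying the class predicates
seed_site_oracle <- function(utr, mature) {
  core7 <- revcomp_dna(substr(mature, 2, 8))
  core6 <- revcomp_dna(substr(mature, 2, 7))
  m8c <- revcomp_dna(substr(mature, 8, 8))
  n <- nchar(utr)
  out <- list()
  for (p in seq_len(max(n - 6, 0))) {
    if (substr(utr, p, p + 6) == core7) {
      has_a <- p + 7 <= n && substr(utr, p + 7, p + 7) == "A"
      out[[length(out) + 1]] <- data.frame(
        start = p, end = if (has_a) p + 7 else p + 6,
        class = if (has_a) "8mer" else "7mer-m8")
    } else if (substr(utr, p, p + 5) == core6 &&
               substr(utr, p + 6, p + 6) == "A" &&
               !(p > 1 && substr(utr, p - 1, p - 1) == m8c)) {
      out[[length(out) + 1]] <- data.frame(start = p, end = p + 6,
                                           class = "7mer-A1")
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      class = character(0)))
  }
  do.call(rbind, out)
}

test_that("planted complements produce the expected site classes", {
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  core7 <- revcomp_dna(substr(mature, 2, 8))
  utr8 <- paste0(random_seq_fixed(30, 1), core7, "A", random_seq_fixed(30, 2))
  s8 <- find_seed_sites(utr8, mature)
  expect_identical(s8$class, "8mer")
  expect_equal(s8$start, 31)
  utr7 <- paste0(random_seq_fixed(30, 3), core7, "G", random_seq_fixed(30, 4))
  s7 <- find_seed_sites(utr7, mature)
  expect_identical(s7$class, "7mer-m8")
  # zero complementarity -> empty
  expect_equal(nrow(find_seed_sites(strrep("A", 100), "CCCCCCCCCCCCCCCCCCCCCC")),
               0L)
  expect_error(find_seed_sites("ACGTACGTAA", "ACGTACG"), ">= 8")
})

test_that("site scan equals the exhaustive offset oracle on random UTRs", {
  set.seed(111)
  for (k in 1:40) {
    mature <- random_seq(22)
    utr <- random_seq(sample(100:500, 1))
    # boost hit probability by splicing in seed complements
    if (k %% 2 == 0) {
      core <- revcomp_dna(substr(mature, 2, 8))
      pos <- sample(1:(nchar(utr) - 10), 1)
      substr(utr, pos, pos + 6) <- core
    }
    got <- find_seed_sites(utr, mature)
    want <- seed_site_oracle(utr, mature)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("duplex energy of a perfect helix equals direct stack summation", {
  pp <- nn_parameters()
  ptype <- function(a, b) {
    c(AT = "AU", TA = "UA", CG = "CG", GC = "GC", GT = "GU", TG = "UG")[
      paste0(a, b)]
  }
  endp <- function(pt) if (pt %in% c("AU", "UA", "GU", "UG")) pp$terminal_au else 0
  set.seed(2)
  for (k in 1:10) {
    n <- sample(8:22, 1)
    mir <- random_seq(n)
    tgt <- revcomp_dna(mir)
    mc <- strsplit(mir, "")[[1]]
    tc <- strsplit(tgt, "")[[1]]
    pts <- vapply(seq_len(n), function(i) ptype(mc[i], tc[n + 1 - i]), "")
    oracle <- pp$duplex_init + endp(pts[1]) + endp(pts[n]) +
      sum(vapply(seq_len(n - 1), function(i) pp$stack[pts[i], pts[i + 1]], 0))
    expect_equal(duplex_energy(mir, tgt), oracle, tolerance = 1e-9)
  }
})

test_that("duplex energy degenerate and symmetry properties", {
  pp <- nn_parameters()
  # single pair: no stack possible -> initiation only (GC pair, no end penalty)
  expect_equal(duplex_energy("G", "C"), pp$duplex_init)
  # AU pair carries the terminal penalty at both helix ends
  expect_equal(duplex_energy("A", "T"), pp$duplex_init + 2 * pp$terminal_au)
  # no canonical pair possible
  expect_true(is.na(duplex_energy("A", "A")))
  # strand-exchange symmetry of the physical duplex
  set.seed(4)
  for (k in 1:8) {
    a <- random_seq(15); b <- random_seq(15)
    e1 <- duplex_energy(a, b); e2 <- duplex_energy(b, a)
    expect_equal(e1, e2, tolerance = 1e-9)
  }
  expect_error(duplex_energy("ACGTN", "ACGT"), "ambiguous")
  expect_error(duplex_energy("", "ACGT"), "non-empty")
  expect_error(duplex_energy(random_seq(41), "ACGT"), "40 nt")
})

test_that("stable planted duplexes pass and weak sites fail the threshold", {
  set.seed(5)
  mature <- random_seq(22)
  # perfect 22-mer complement scores far below -20
  utr_good <- paste0(random_seq(40), revcomp_dna(mature), random_seq(40))
  utrs <- data.frame(gene = "gA", transcript = "tA", sequence = utr_good)
  hits <- predict_targets(c(mir1 = mature), utrs, dg_max = -20)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$dG < -20))
  # seed-only pairing in an otherwise non-complementary context fails
  core7 <- revcomp_dna(substr(mature, 2, 8))
  weak <- paste0(strrep("A", 40), core7, strrep("A", 40))
  weak_sites <- find_seed_sites(weak, mature)
  expect_gt(nrow(weak_sites), 0)
  win <- substr(weak, weak_sites$start[1] - 15, weak_sites$end[1])
  expect_gt(duplex_energy(mature, win), -20)
  utrs_weak <- data.frame(gene = "gB", transcript = "tB", sequence = weak)
  expect_equal(nrow(predict_targets(c(mir1 = mature), utrs_weak, -20)), 0L)
})

test_that("lowering the energy threshold never adds predictions", {
  fx <- e2e_fixture()
  matures <- fx$ref$matures[1:6, ]
  utrs <- fx$ref$utrs
  loose <- predict_targets(matures, utrs, dg_max = -15)
  strict <- predict_targets(matures, utrs, dg_max = -25)
  key <- function(df) paste(df$miRNA, df$transcript, df$start)
  expect_true(all(key(strict) %in% key(loose)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("planted perfect-complement UTR sites are recovered as targets", {
  fx <- e2e_fixture()
  planted <- fx$ref$planted_sites
  pred <- predict_targets(fx$ref$matures, fx$ref$utrs, dg_max = -20)
  for (k in seq_len(nrow(planted))) {
    expect_true(any(pred$miRNA == planted$mature[k] &
                      pred$gene == planted$gene[k]))
  }
})

test_that("target summaries count distinct pairs and conserve totals", {
  pred <- data.frame(
    miRNA = c("m1", "m1", "m2", "m3", "m3"),
    gene = c("gA", "gA", "gA", "gB", "gB"),
    transcript = c("t1", "t1", "t1", "t2", "t2"),
    start = c(5, 50, 9, 7, 90), end = c(11, 56, 15, 13, 96),
    class = "7mer-m8", dG = -25)
  s <- summarize_targets(pred)
  # duplicate (miRNA, gene) sites count once
  expect_equal(s$per_gene$n_mirnas[s$per_gene$gene == "gA"], 2L)
  expect_equal(s$per_gene$n_mirnas[s$per_gene$gene == "gB"], 1L)
  expect_equal(sum(s$per_gene$n_mirnas), sum(s$per_mirna$n_genes))
  expect_equal(sum(s$histogram$n_genes), nrow(s$per_gene))
  # planted top gene ranks first with its full miRNA count
  many <- data.frame(miRNA = sprintf("m%02d", 1:20), gene = "hub",
                     transcript = "tx", start = 1, end = 7,
                     class = "7mer-m8", dG = -25)
  s2 <- summarize_targets(rbind(pred, many))
  expect_identical(s2$per_gene$gene[1], "hub")
  expect_equal(s2$per_gene$n_mirnas[1], 20L)
})
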