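# naive alignment oracle: scan every hairpin (lexicographic) and offset
align_oracle <- function(read, hairpins) {
  for (h in sort(names(hairpins))) {
    hp <- hairpins[[h]]
    if (nchar(read) > nchar(hp)) next
    for (p in 1:(nchar(hp) - nchar(read) + 1)) {
      if (substr(hp, p, p + nchar(read) - 1) == read) {
        return(list(hairpin = h, start = p))
      }
    }
  }
  NULL
}

# brute-force window predicate with the stated disambiguation
count_oracle <- function(aln, matures) {
  counts <- setNames(rep(0L, nrow(matures)), matures$name)
  for (i in seq_len(nrow(aln))) {
    elig <- matures[matures$hairpin == aln$hairpin[i] &
                      aln$start[i] >= matures$x - 2 &
                      aln$end[i] <= matures$y + 5, , drop = FALSE]
    if (!nrow(elig)) next
    d <- abs(aln$start[i] - elig$x)
    elig <- elig[order(d, elig$x), , drop = FALSE]
    counts[elig$name[1]] <- counts[elig$name[1]] + aln$n_reads[i]
  }
  counts
}

test_that("exact substring alignment with deterministic tie-breaking", {
  hp <- c(mirB = paste0(strrep("C", 9), "ACGTAGGTCCATTAGCATGAAT", strrep("C", 10)))
  read <- "ACGTAGGTCCATTAGCATGAAT"
  aln <- align_reads(c(r1 = read), hp)
  expect_equal(aln$start, 10)
  expect_equal(aln$end, 31)
  # same embedded read in two hairpins -> lexicographically lowest wins
  hp2 <- c(hp, mirA = paste0("TT", read, "GG"))
  aln2 <- align_reads(c(r1 = read), hp2)
  expect_identical(aln2$hairpin, "mirA")
  expect_equal(aln2$start, 3)
})

test_that("alignment equals the exhaustive scan oracle on random input", {
  set.seed(52)
  hairpins <- setNames(vapply(1:20, function(i) random_seq(80), ""),
                       sprintf("hp%02d", sample(20)))
  reads <- vapply(1:500, function(i) {
    if (runif(1) < 0.8) {
      h <- sample(names(hairpins), 1)
      p <- sample(1:59, 1)
      substr(hairpins[[h]], p, p + sample(18:22, 1) - 1)
    } else random_seq(20)
  }, "")
  names(reads) <- sprintf("r%03d", seq_along(reads))
  aln <- align_reads(reads, hairpins)
  n_oracle_hit <- 0L
  for (r in unique(reads)) {
    o <- align_oracle(r, hairpins)
    row <- aln[aln$sequence == r, ]
    if (is.null(o)) {
      expect_equal(nrow(row), 0)
    } else {
      n_oracle_hit <- n_oracle_hit + 1L
      expect_equal(nrow(row), 1)
      expect_identical(row$hairpin, o$hairpin)
      expect_equal(row$start, o$start)
    }
  }
  expect_identical(attr(aln, "n_unique_aligned"), n_oracle_hit)
  expect_identical(attr(aln, "n_aligned") + attr(aln, "n_unaligned"),
                   length(reads))
})

test_that("window boundaries of the counting rule are exact", {
  matures <- data.frame(name = "m1", hairpin = "h1", x = 10, y = 31)
  mk <- function(s, e) data.frame(sequence = "X", hairpin = "h1",
                                  start = s, end = e, n_reads = 1L)
  count1 <- function(a) count_mature(a, matures)$counts["m1", 1]
  expect_equal(count1(mk(8, 31)), 1L)    # s = x - 2: counted
  expect_equal(count1(mk(7, 31)), 0L)    # s < x - 2: excluded
  expect_equal(count1(mk(10, 36)), 1L)   # e = y + 5: counted
  expect_equal(count1(mk(10, 37)), 0L)   # e > y + 5: excluded
})

test_that("counting equals the brute-force window predicate on random cases", {
  set.seed(61)
  hp_names <- sprintf("h%02d", 1:8)
  matures <- do.call(rbind, lapply(1:25, function(i) {
    x <- sample(5:60, 1)
    data.frame(name = sprintf("m%02d", i),
               hairpin = sample(hp_names, 1),
               x = x, y = x + sample(18:24, 1) - 1)
  }))
  aln <- do.call(rbind, lapply(1:1000, function(i) {
    s <- sample(1:70, 1)
    data.frame(sequence = sprintf("s%04d", i),
               hairpin = sample(hp_names, 1),
               start = s, end = s + sample(16:30, 1) - 1,
               n_reads = sample(1:5, 1))
  }))
  got <- count_mature(aln, matures)$counts[, 1]
  expect_identical(got[order(names(got))],
                   count_oracle(aln, matures)[order(names(got))])
})

test_that("multi-mature disambiguation prefers the nearest then lower x", {
  matures <- data.frame(name = c("mA", "mB"), hairpin = "h1",
                        x = c(10, 14), y = c(31, 35))
  # start 13: |13-10| = 3 > |13-14| = 1 -> mB
  a1 <- data.frame(sequence = "r", hairpin = "h1", start = 13, end = 33,
                   n_reads = 1L)
  expect_equal(count_mature(a1, matures)$counts[, 1], c(mA = 0L, mB = 1L))
  # start 12 is equidistant -> tie to lower x (mA)
  a2 <- data.frame(sequence = "r", hairpin = "h1", start = 12, end = 33,
                   n_reads = 1L)
  expect_equal(count_mature(a2, matures)$counts[, 1], c(mA = 1L, mB = 0L))
})

test_that("counting conserves aligned reads when all fall in windows", {
  cf <- e2e_counts_fixture()
  fx <- e2e_fixture()
  for (s in colnames(cf$counts$counts)) {
    expect_lte(sum(cf$counts$counts[, s]), cf$counts$lib_sizes[[s]])
  }
  # without stragglers every aligned read is counted
  ref <- fx$ref
  truth <- make_truth(ref, depth = 5000, straggler_fraction = 0,
                      junk_fractions = NULL, seed = 31)
  sim <- simulate_libraries(ref, truth, file.path(tempdir(), "exomir-nostrag"))
  qc <- clean_library(sim$manifest$path[1], truth$adapter)
  aln <- align_reads(qc$reads, ref)
  cm <- count_mature(aln, ref)
  expect_identical(sum(cm$counts), attr(aln, "n_aligned"))
})

test_that("mapping stats tabulate the census correctly", {
  matures <- data.frame(name = c("m1", "m2"), hairpin = c("h1", "h1"),
                        x = c(5, 40), y = c(26, 61))
  a <- data.frame(sequence = "r", hairpin = "h1", start = 5, end = 26,
                  n_reads = 1L)
  st <- mapping_stats(count_mature(a, matures))
  expect_equal(st$n_premirna, 1L)
  expect_equal(st$n_mature, 1L)
  expect_equal(st$unique_mapped, 1L)
  expect_equal(st$total_mapped, 1L)
  # empty alignment set -> all zeros
  st0 <- mapping_stats(count_mature(a[0, ], matures))
  expect_true(all(st0[, -1] == 0))
})

test_that("mature counts recover the truth census at adequate depth", {
  cf <- e2e_counts_fixture()
  fx <- e2e_fixture()
  tt <- fx$sim$truth_table
  t1 <- tt[tt$condition == "milk" & tt$replicate == 1, ]
  detected <- rownames(cf$counts$counts)[cf$counts$counts[, "milk_1"] > 0]
  well_covered <- t1$miRNA[t1$expected_in_window >= 20]
  expect_true(all(well_covered %in% detected))
  st <- mapping_stats(cf$counts)
  expect_equal(st$n_mature[st$sample == "milk_1"], length(detected))
  # mature referencing an unknown hairpin is a reference error
  bad <- fx$ref$matures
  bad$hairpin[1] <- "no-such-hairpin"
  expect_error(count_mature(cf$alignments[1], bad,
                            hairpins = fx$ref$hairpins$name),
               "unknown hairpin")
})

test_that("counting is invariant to read order", {
  fx <- small_sim_fixture()
  qc <- clean_library(fx$sim$manifest$path[1], fx$truth$adapter,
                      fx$ref$contaminants)
  aln1 <- align_reads(qc$reads, fx$ref)
  set.seed(7)
  aln2 <- align_reads(qc$reads[sample(length(qc$reads))], fx$ref)
  c1 <- count_mature(aln1, fx$ref)$counts
  c2 <- count_mature(aln2, fx$ref)$counts
  expect_identical(c1, c2)
})
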