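# consensus -> PWM conversion and intergenic scanning

REX <- "TTGTTAANNNNTTAACAA"

score_site <- function(model, site) {
  ch <- strsplit(site, "")[[1]]
  sum(vapply(seq_along(ch), function(j) model$pwm[ch[j], j], numeric(1)))
}

test_that("consensus-to-PWM conversion honours the epsilon scheme", {
  n <- consensus_to_pwm("N")
  expect_equal(unname(n$pwm[, 1]), rep(0, 4))
  expect_equal(colSums(n$prob), 1)
  a <- consensus_to_pwm("A")
  expect_gt(a$pwm["A", 1], 0)
  expect_lt(max(a$pwm[c("C", "G", "T"), 1]), -10)
  expect_equal(colSums(a$prob), 1, tolerance = 1e-12)
  rex <- consensus_to_pwm(REX)
  expect_equal(ncol(rex$pwm), 18)
  neutral <- which(apply(rex$pwm == 0, 2, all))
  expect_equal(neutral, 8:11)
  expect_true(rex$palindromic)
  expect_error(consensus_to_pwm("ACGTX"), "invalid IUPAC")
  expect_error(consensus_to_pwm(""), "nonempty")
  expect_error(consensus_to_pwm("A", epsilon = 0.3), "epsilon")
})

test_that("mismatch counting treats degenerate positions as wildcards", {
  expect_equal(hamming_to_consensus("TTGCTAAAACTTTAACAA", REX), 1)
  expect_equal(hamming_to_consensus("TTTTTAACCGCTTAATCA", REX), 3)
  expect_equal(hamming_to_consensus("TTGTTAAGGGGTTAACAA", REX), 0)
  expect_error(hamming_to_consensus("TTG", REX), "length")
})

test_that("consensus-conforming strings score the maximum; mismatches strictly lower it", {
  rex <- consensus_to_pwm(REX)
  conform <- "TTGTTAAGGGGTTAACAA"
  expect_equal(score_site(rex, conform), rex$max_score, tolerance = 1e-9)
  ch <- strsplit(conform, "")[[1]]
  informative <- setdiff(seq_len(18), 8:11)
  for (j in informative[c(1, 5, 9, 14)]) {
    mut <- ch
    mut[j] <- setdiff(c("A", "C", "G", "T"), ch[j])[1]
    expect_lt(score_site(rex, paste(mut, collapse = "")), rex$max_score)
  }
  # reported site pair: 1 mismatch must outscore 3 mismatches
  expect_gt(score_site(rex, "TTGCTAAAACTTTAACAA"),
            score_site(rex, "TTTTTAACCGCTTAATCA"))
})

test_that("intergenic extraction annotates downstream genes on both strands", {
  genome <- c(chr = strrep("ACGT", 100))   # 400 nt
  feats <- data.frame(
    seqid = "chr", start = c(0, 200), end = c(100, 300),
    strand = c("+", "+"), type = "CDS", gene_id = c("gA", "gB"),
    stringsAsFactors = FALSE)
  iv <- extract_intergenic(feats, genome)
  gap <- iv[iv$start == 100, ]
  expect_equal(gap$end, 200)
  expect_equal(gap$down_plus_gene, "gB")
  expect_equal(nchar(gap$seq), 100)
  # divergently transcribed pair shares one upstream interval
  feats2 <- data.frame(
    seqid = "chr", start = c(0, 200), end = c(100, 300),
    strand = c("-", "+"), type = "CDS", gene_id = c("larA", "lldP"),
    stringsAsFactors = FALSE)
  iv2 <- extract_intergenic(feats2, genome)
  gap2 <- iv2[iv2$start == 100, ]
  expect_equal(gap2$down_plus_gene, "lldP")
  expect_equal(gap2$down_minus_gene, "larA")
  # no genes: the whole sequence is one interval
  none <- extract_intergenic(feats[0, ], genome)
  expect_equal(nrow(none), 1)
  expect_equal(none$end - none$start, 400)
  bad <- feats ; bad$end[2] <- 1000
  expect_error(extract_intergenic(bad, genome), "malformed annotation")
})

test_that("a planted exact consensus instance yields exactly one hit at its offset", {
  set.seed(3)
  g <- gen_genome_with_sites(3, n_intergenic = 4, n_sites = 1,
                             mutation_rate = 0)
  iv <- extract_intergenic(g$features, g$genome, min_length = 18)
  hits <- scan_sequences(REX, iv, threshold = 0.95)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, g$truth$start)
  expect_equal(hits$offset, g$truth$offset)
  expect_lt(hits$offset, 0)   # 5'-UTR hits sit upstream
  # palindromic motif: the site is reported once, on the plus strand
  expect_equal(hits$strand, "+")
})

test_that("scanning is strand-symmetric for a non-palindromic motif", {
  set.seed(9)
  motif <- consensus_to_pwm("TGGTACNNAC")
  expect_false(motif$palindromic)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    iv_f <- extract_intergenic(data.frame(seqid = character(),
                                          start = numeric(), end = numeric(),
                                          strand = character(),
                                          type = character(),
                                          gene_id = character()),
                               c(chr = s))
    iv_r <- iv_f ; iv_r$seq <- reverse_complement(s)
    h_f <- scan_sequences(motif, iv_f, threshold = 0.6)
    h_r <- scan_sequences(motif, iv_r, threshold = 0.6)
    expect_equal(nrow(h_f), nrow(h_r))
    if (nrow(h_f)) {
      mapped <- sort(nchar(s) - h_r$end)
      expect_equal(sort(h_f$start), mapped)
      expect_equal(sort(h_f$score), sort(h_r$score), tolerance = 1e-9)
    }
  }
})

test_that("palindrome deduplication reports each window once", {
  set.seed(21)
  rex <- consensus_to_pwm(REX)
  for (i in 1:20) {
    g <- gen_genome_with_sites(1000 + i, n_intergenic = 3, n_sites = 2,
                               mutation_rate = 0.05)
    iv <- extract_intergenic(g$features, g$genome, min_length = 18)
    hits <- scan_sequences(rex, iv, threshold = 0.7)
    expect_false(any(duplicated(hits[, c("seqid", "start", "end")])))
    expect_true(all(hits$strand == "+"))
  }
})

test_that("site reports are sorted by score with stable ties and survive empty input", {
  hits <- data.frame(seqid = "chr", start = c(10, 5, 30), end = c(28, 23, 48),
                     strand = "+", site = c("s1", "s2", "s3"),
                     score = c(5, 9, 5), score_scaled = c(0.7, 0.9, 0.7),
                     downstream_gene = c("g1", "g2", "g3"),
                     offset = c(-40, -20, -5), stringsAsFactors = FALSE)
  rep <- site_report(hits)
  expect_equal(rep$operon_first_gene, c("g2", "g1", "g3"))
  expect_true(all(diff(rep$score) <= 0))
  empty <- scan_sequences(REX, extract_intergenic(
    data.frame(seqid = character(), start = numeric(), end = numeric(),
               strand = character(), type = character(),
               gene_id = character()),
    c(chr = strrep("A", 100))), threshold = 1)
  expect_equal(nrow(site_report(empty)), 0)
})

test_that("intervals shorter than the motif are skipped with a message", {
  iv <- data.frame(seqid = "chr", start = 0, end = 5, seq = "ACGTA",
                   down_plus_gene = NA, down_plus_start = NA,
                   down_minus_gene = NA, down_minus_end = NA,
                   stringsAsFactors = FALSE)
  expect_message(h <- scan_sequences(REX, iv), "shorter than the motif")
  expect_equal(nrow(h), 0)
})

test_that("site count matrices align reported sites", {
  m <- site_count_matrix(c("ACG", "ACT"))
  expect_equal(unname(m[1, "A"]), 2L)
  expect_equal(unname(m[3, "G"]), 1L)
  expect_equal(unname(m[3, "T"]), 1L)
  expect_equal(rowSums(m), c(2, 2, 2), ignore_attr = TRUE)
  expect_error(site_count_matrix(character(0)), "no sites")
  expect_error(site_count_matrix(c("AC", "ACG")), "same length")
})
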